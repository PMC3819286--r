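SCENE_CONDITIONS <- c("control", "heat", "DEM", "actinomycinD", "DRB")

#' Default channel layout of a synthetic scene
#'
#' Five channels emulating a typical nucleolar-marker experiment: a DAPI-like
#' nuclear stain, nucleolin as positive nucleolar marker, CAS and HuR as
#' negative markers, and an EU-like functional channel reporting nascent RNA
#' (strongly nucleolar in untreated cells).
#'
#' Per-channel fields: `role` (`nuclear_stain`, `marker` or `function`),
#' `polarity` with respect to nucleoli, `nucleoplasm_level` (mean intensity
#' inside the nucleus outside nucleoli, 16-bit grey levels), `contrast`
#' (nucleolus-vs-nucleoplasm; see [contrast_factor()]) and `effect`
#' (a multiplier on the planted nucleolar level, used to plant treatment
#' effect sizes; 1 = no effect).
#'
#' @return a named list of channel parameter lists.
#' @export
default_channels <- function() {
  list(
    DAPI      = list(role = "nuclear_stain", polarity = "unknown",
                     nucleoplasm_level = 3000, contrast = 0,    effect = 1),
    nucleolin = list(role = "marker",        polarity = "enriched",
                     nucleoplasm_level = 2000, contrast = 2.5,  effect = 1),
    CAS       = list(role = "marker",        polarity = "excluded",
                     nucleoplasm_level = 2000, contrast = -0.8, effect = 1),
    HuR       = list(role = "marker",        polarity = "excluded",
                     nucleoplasm_level = 2000, contrast = -0.8, effect = 1),
    EU        = list(role = "function",      polarity = "enriched",
                     nucleoplasm_level = 1500, contrast = 3,    effect = 1)
  )
}

#' Nucleolar contrast parametrization
#'
#' Converts a signed contrast `c` into the multiplicative factor applied to
#' the nucleoplasm level inside nucleoli: `c = 0` means no contrast
#' (factor 1); `c >= 1` is the enrichment ratio of a positive marker
#' (`c = 2` plants nucleoli at exactly twice the nucleoplasm level);
#' `-1 < c < 0` is the fractional depletion of a negative marker
#' (`c = -0.8` plants nucleoli at 0.2 x the nucleoplasm level, i.e. a
#' relative hole depth of 0.8). Values in `(0, 1)` or `<= -1` are invalid.
#'
#' @param contrast signed contrast value.
#' @return the nucleolus/nucleoplasm intensity ratio.
#' @export
contrast_factor <- function(contrast) {
  vapply(contrast, function(c1) {
    validate_contrast(c1)
    if (c1 == 0) 1 else if (c1 > 0) c1 else 1 + c1
  }, numeric(1))
}

validate_contrast <- function(c1) {
  if (!is.numeric(c1) || length(c1) != 1L || is.na(c1)) {
    stop("contrast must be a single number", call. = FALSE)
  }
  if ((c1 > 0 && c1 < 1) || c1 <= -1) {
    stop("contrast must be 0, >= 1 (enrichment ratio) or in (-1, 0) ",
         "(fractional depletion); got ", c1, call. = FALSE)
  }
  invisible(c1)
}

#' Parametric description of a synthetic fluorescence scene
#'
#' Describes a multi-channel field of cultured cells: elliptical (2D) or
#' ellipsoidal (3D) nuclei, each containing disjoint circular/spherical
#' nucleoli, one image per channel, with additive Gaussian noise (optionally
#' signal-scaled) and integer quantization. Rendering a spec with
#' [render_scene()] is deterministic given `seed`.
#'
#' @param field_shape image size in pixels, length 2 (2D) or 3 (3D,
#'   `c(nx, ny, nz)`).
#' @param pixel_size lateral pixel size, µm/pixel.
#' @param z_spacing slice spacing, µm (3D only; default 0.3 µm, a typical
#'   confocal z-step for nucleolar stacks).
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius_range in-plane nuclear semi-axis range, µm.
#' @param nucleoli_per_nucleus_range nucleolus count range per nucleus.
#' @param nucleolus_radius_range nucleolus radius range, µm.
#' @param background_level extracellular intensity (grey levels).
#' @param channels channel layout; see [default_channels()].
#' @param noise_sigma Gaussian noise standard deviation (grey levels).
#' @param poisson_scaling if `TRUE`, the noise variance grows with the
#'   signal (`sd = sqrt(noise_sigma^2 + value)`), emulating shot noise.
#' @param condition one of `"control"`, `"heat"`, `"DEM"`,
#'   `"actinomycinD"`, `"DRB"`. Phenotype defaults are applied by
#'   [apply_condition()], not here.
#' @param frag_split number of remnants each nucleolus fragments into
#'   (1 = intact).
#' @param frag_shrink remnant radius as a fraction of the original radius.
#' @param miss_prob probability that a nucleolus is "missed" by a negative
#'   marker (its depletion attenuated by `miss_attenuation`); the DRB
#'   condition plants disjoint per-marker miss sets with this probability.
#' @param miss_attenuation contrast attenuation factor for missed nucleoli.
#' @param nucleus_z_ratio axial-to-lateral nuclear semi-axis ratio (3D);
#'   adherent cells are flattened, hence < 1.
#' @param border_margin_um minimum distance from nucleus centre to the field
#'   border, µm; set small (or 0) to allow border-touching nuclei.
#' @param dtype rendered bit depth.
#' @param seed integer RNG seed.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(field_shape = c(256L, 256L),
                       pixel_size = 0.25,
                       z_spacing = 0.3,
                       n_nuclei = 4L,
                       nucleus_radius_range = c(5, 7),
                       nucleoli_per_nucleus_range = c(1L, 6L),
                       nucleolus_radius_range = c(0.8, 1.6),
                       background_level = 200,
                       channels = default_channels(),
                       noise_sigma = 100,
                       poisson_scaling = FALSE,
                       condition = "control",
                       frag_split = 1L,
                       frag_shrink = 1,
                       miss_prob = 0,
                       miss_attenuation = 0.05,
                       nucleus_z_ratio = 0.4,
                       border_margin_um = NULL,
                       dtype = "16bit",
                       seed = 1L) {
  spec <- structure(
    list(field_shape = as.integer(field_shape), pixel_size = pixel_size,
         z_spacing = z_spacing, n_nuclei = as.integer(n_nuclei),
         nucleus_radius_range = nucleus_radius_range,
         nucleoli_per_nucleus_range = as.integer(nucleoli_per_nucleus_range),
         nucleolus_radius_range = nucleolus_radius_range,
         background_level = background_level, channels = channels,
         noise_sigma = noise_sigma, poisson_scaling = poisson_scaling,
         condition = condition, frag_split = as.integer(frag_split),
         frag_shrink = frag_shrink, miss_prob = miss_prob,
         miss_attenuation = miss_attenuation,
         nucleus_z_ratio = nucleus_z_ratio,
         border_margin_um = border_margin_um %||% max(nucleus_radius_range),
         dtype = dtype, seed = as.integer(seed),
         condition_applied = FALSE),
    class = "scene_spec"
  )
  validate_scene_spec(spec)
}

validate_scene_spec <- function(spec) {
  with(spec, {
    if (!(length(field_shape) %in% c(2L, 3L)) || any(field_shape < 8L)) {
      stop("field_shape must be 2 or 3 positive dimensions (>= 8 px)",
           call. = FALSE)
    }
    if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
    if (length(field_shape) == 3L && z_spacing <= 0) {
      stop("z_spacing must be > 0 for 3D scenes", call. = FALSE)
    }
    if (any(nucleus_radius_range <= 0) || any(nucleolus_radius_range <= 0)) {
      stop("all radii must be strictly positive", call. = FALSE)
    }
    if (diff(nucleus_radius_range) < 0 || diff(nucleolus_radius_range) < 0) {
      stop("radius ranges must be ordered (min, max)", call. = FALSE)
    }
    if (max(nucleolus_radius_range) >= min(nucleus_radius_range)) {
      stop("nucleolus radius must be smaller than nucleus radius",
           call. = FALSE)
    }
    if (n_nuclei < 1L) stop("n_nuclei must be >= 1", call. = FALSE)
    if (any(nucleoli_per_nucleus_range < 1L) ||
        diff(nucleoli_per_nucleus_range) < 0) {
      stop("nucleoli_per_nucleus_range must be an ordered range >= 1",
           call. = FALSE)
    }
    if (!condition %in% SCENE_CONDITIONS) {
      stop("unknown condition '", condition, "'; must be one of: ",
           paste(SCENE_CONDITIONS, collapse = ", "), call. = FALSE)
    }
    if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
    if (frag_split < 1L) stop("frag_split must be >= 1", call. = FALSE)
    if (frag_shrink <= 0 || frag_shrink > 1) {
      stop("frag_shrink must be in (0, 1]", call. = FALSE)
    }
    if (miss_prob < 0 || miss_prob > 0.5) {
      stop("miss_prob must be in [0, 0.5]", call. = FALSE)
    }
  })
  roles <- vapply(spec$channels, `[[`, "", "role")
  if (sum(roles == "nuclear_stain") != 1L) {
    stop("channels must contain exactly one nuclear_stain", call. = FALSE)
  }
  for (ch in spec$channels) validate_contrast(ch$contrast)
  spec
}

#' Condition parameter table
#'
#' One editable table encoding the five emulated phenotypes as parameter
#' changes applied by [apply_condition()]:
#' \describe{
#'   \item{control}{no change.}
#'   \item{heat}{severe heat shock drives the negative markers (CAS, HuR)
#'     into nucleoli, collapsing their dark-hole contrast (x0.05); the
#'     positive marker (nucleolin) stays nucleolar.}
#'   \item{DEM}{oxidative stress: mild global intensity increase (x1.2),
#'     contrasts retained — all three markers remain usable.}
#'   \item{actinomycinD}{Pol I inhibition relocates the positive marker out
#'     of nucleoli so that it now forms dark holes: its enrichment ratio r is
#'     flipped to the depletion 1/r - 1. Nucleolar RNA synthesis (EU) drops
#'     sharply (effect 0.2).}
#'   \item{DRB}{transcription inhibition redistributes the positive marker
#'     throughout the nucleoplasm (contrast -> 0), fragments nucleoli
#'     (2 remnants at 0.7 x radius) and attenuates the negative markers
#'     (x0.5), with each negative marker additionally missing a disjoint
#'     random subset of nucleoli (probability 0.2 each); EU effect 0.6.}
#' }
#' The numeric values are the generator's encoding of qualitative phenotype
#' descriptions; they are deliberately kept in one place so they can be
#' audited and edited.
#'
#' @return a [tibble::tibble()] with one row per condition.
#' @export
condition_table <- function() {
  tibble::tibble(
    condition = SCENE_CONDITIONS,
    level_scale = c(1, 1, 1.2, 1, 1),
    positive_contrast = c("keep", "keep", "keep", "flip", "flatten"),
    negative_contrast_scale = c(1, 0.05, 1, 1, 0.5),
    frag_split = c(1L, 1L, 1L, 1L, 2L),
    frag_shrink = c(1, 1, 1, 1, 0.7),
    miss_prob = c(0, 0, 0, 0, 0.2),
    function_effect = c(1, 1, 0.6, 0.2, 0.6)
  )
}

#' Apply condition-specific phenotype defaults to a scene spec
#'
#' Rewrites the spec's channel contrasts, fragmentation and miss-set
#' parameters according to [condition_table()] for `spec$condition`.
#' Applying a condition twice is a no-op, and the control condition returns
#' the spec unchanged.
#'
#' @param spec a [scene_spec()].
#' @return the modified `scene_spec`.
#' @export
apply_condition <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!spec$condition %in% SCENE_CONDITIONS) {
    stop("unknown condition '", spec$condition, "'", call. = FALSE)
  }
  if (isTRUE(spec$condition_applied) || spec$condition == "control") {
    spec$condition_applied <- TRUE
    return(spec)
  }
  row <- condition_table()[condition_table()$condition == spec$condition, ]
  for (nm in names(spec$channels)) {
    ch <- spec$channels[[nm]]
    if (ch$role %in% c("marker", "function")) {
      ch$nucleoplasm_level <- ch$nucleoplasm_level * row$level_scale
    }
    if (ch$role == "marker" && ch$polarity == "enriched" && ch$contrast > 0) {
      if (row$positive_contrast == "flip") {
        # enrichment ratio r becomes the reciprocal depletion: dark holes
        ch$contrast <- 1 / ch$contrast - 1
        ch$polarity <- "excluded"
      } else if (row$positive_contrast == "flatten") {
        ch$contrast <- 0
        ch$polarity <- "unknown"
      }
    } else if (ch$role == "marker" && ch$polarity == "excluded") {
      ch$contrast <- ch$contrast * row$negative_contrast_scale
    }
    if (ch$role == "function") ch$effect <- ch$effect * row$function_effect
    spec$channels[[nm]] <- ch
  }
  spec$frag_split <- row$frag_split
  spec$frag_shrink <- row$frag_shrink
  spec$miss_prob <- row$miss_prob
  spec$condition_applied <- TRUE
  validate_scene_spec(spec)
}

#' Noise level for a target signal-to-noise ratio
#'
#' Returns the Gaussian `noise_sigma` that makes a channel's
#' nucleolus-vs-nucleoplasm amplitude equal `snr` standard deviations.
#'
#' @param spec a [scene_spec()].
#' @param snr desired amplitude / sigma ratio.
#' @param channel channel name (default: the first enriched marker).
#' @return sigma in grey levels.
#' @export
noise_sigma_for_snr <- function(spec, snr, channel = NULL) {
  chs <- spec$channels
  if (is.null(channel)) {
    pol <- vapply(chs, `[[`, "", "polarity")
    role <- vapply(chs, `[[`, "", "role")
    channel <- names(chs)[which(role == "marker" & pol == "enriched")[1]]
  }
  ch <- chs[[channel]]
  amp <- abs(contrast_factor(ch$contrast) - 1) * ch$nucleoplasm_level
  amp / snr
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "<scene_spec> %s field, %d nuclei, condition %s, seed %d\n",
    paste(x$field_shape, collapse = "x"), x$n_nuclei, x$condition, x$seed))
  invisible(x)
}
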