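# Independent brute-force oracles and small scene helpers used across tests.

# Small, fast default scene for unit tests (96x96 px = 24 µm field).
tiny_spec <- function(seed = 1L, ...) {
  defaults <- list(field_shape = c(96L, 96L), n_nuclei = 2L,
                   nucleus_radius_range = c(3.2, 4.2),
                   nucleoli_per_nucleus_range = c(1L, 3L),
                   nucleolus_radius_range = c(0.7, 1.2),
                   noise_sigma = 0, seed = seed)
  do.call(scene_spec, utils::modifyList(defaults, list(...)))
}

tiny_radius <- 1.25 * 1.2  # structuring radius for tiny_spec, µm

# Demarcation chain on one scene; mode "light", "dark" or "add".
demarcate <- function(scene, mode = "light", radius = NULL,
                      constraints = scoring_constraints(),
                      median_radius = 1L) {
  radius <- radius %||% 1.25 * max(scene$spec$nucleolus_radius_range)
  img <- switch(mode,
    light = scene$channels$nucleolin,
    dark = scene$channels$CAS,
    dark_hur = scene$channels$HuR,
    add = add_images(scene$channels$CAS, scene$channels$HuR))
  holes <- if (mode == "light") detect_light_holes(img, radius)
           else detect_dark_holes(img, radius)
  med <- median_denoise(holes, median_radius)
  nuclei <- segment_nuclei(scene$channels$DAPI)
  scorer <- if (is_stack(med$response)) score_nucleoli_3d else score_nucleoli
  segs <- scorer(med, nuclei, constraints)
  attr(segs, "nuclei") <- nuclei
  segs
}

is_stack <- function(x) length(dim(x)) == 3L

`%||%` <- function(a, b) if (is.null(a)) b else a

# 1-based symmetric reflection (edge repeated), matching the package's
# documented border policy but implemented independently.
reflect1 <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

disk_off_px <- function(r) {
  g <- expand.grid(dx = -floor(r):floor(r), dy = -floor(r):floor(r))
  g[g$dx^2 + g$dy^2 <= r^2 + 1e-9, ]
}

# Per-pixel brute-force neighborhood reduction with reflected borders.
oracle_neighborhood <- function(x, offs, f) {
  n1 <- nrow(x); n2 <- ncol(x)
  out <- x
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      ii <- reflect1(i + offs$dx, n1)
      jj <- reflect1(j + offs$dy, n2)
      out[i, j] <- f(x[cbind(ii, jj)])
    }
  }
  out
}

oracle_light_holes <- function(x, r_px) {
  x <- x + 0.0
  offs <- disk_off_px(r_px)
  x - oracle_neighborhood(oracle_neighborhood(x, offs, min), offs, max)
}

oracle_dark_holes <- function(x, r_px) {
  x <- x + 0.0
  offs <- disk_off_px(r_px)
  oracle_neighborhood(oracle_neighborhood(x, offs, max), offs, min) - x
}

# Masked means straight from ground-truth index sets.
truth_masked_means <- function(scene, channel) {
  px <- scene$channels[[channel]]$pixels
  lab <- scene$truth$nucleolus_labels
  vapply(seq_len(max(lab)), function(l) mean(px[lab == l]), numeric(1))
}

nucleoplasm_mean <- function(scene, channel) {
  px <- scene$channels[[channel]]$pixels
  sel <- scene$truth$nucleus_labels > 0 & scene$truth$nucleolus_labels == 0
  mean(px[sel])
}

# Wrap ground-truth nucleolus masks as segment labels, for measuring
# intensities over the true supports without running segmentation.
truth_as_segments <- function(truth) {
  n <- length(truth$parent_of)
  sizes <- tabulate(truth$nucleolus_labels[truth$nucleolus_labels > 0],
                    nbins = n)
  voxel <- truth$pixel_size^2 *
    (if (is.null(truth$z_spacing)) 1 else truth$z_spacing)
  st <- tibble::tibble(
    segment = seq_len(n), parent_nucleus = as.integer(truth$parent_of),
    n_pixels = sizes, size_um = sizes * voxel,
    mean_response = NA_real_, background_response = NA_real_,
    response_contrast = NA_real_,
    parent_on_border = as.integer(truth$parent_of) %in% truth$border_nuclei)
  structure(list(labels = truth$nucleolus_labels,
                 parent_of = truth$parent_of,
                 provenance = list(mode = "truth"), stats = st,
                 pixel_size = truth$pixel_size,
                 z_spacing = truth$z_spacing),
            class = "segment_labels")
}

# Replicate-structured synthetic measurement table (no imaging), for the
# statistics machinery: n_per replicate-level nucleolar means per condition.
synthetic_table <- function(conditions, n_reps = 3L, n_per = 30L,
                            mean_by_condition = NULL, sd = 300, seed = 1L) {
  withr::with_seed(seed, {
    rows <- list()
    for (cond in conditions) {
      m <- mean_by_condition[[cond]] %||% 2000
      for (r in seq_len(n_reps)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          scene_id = sprintf("%s_r%d", cond, r), replicate = r,
          condition = cond, nucleus_label = seq_len(n_per),
          nucleolus_label = seq_len(n_per), n_pixels = 50L, size_um = 3,
          channel = "B23", mean_intensity = stats::rnorm(n_per, m, sd),
          integrated_intensity = NA_real_, response_contrast = 500,
          parent_on_border = FALSE)
      }
    }
    dplyr::bind_rows(rows)
  })
}
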