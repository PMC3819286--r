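#' Ground truth of a synthetic scene
#'
#' Integer label masks for nuclei and nucleoli, the nucleolus-to-nucleus
#' parent map, the noise-free planted mean intensity of every nucleolus in
#' every channel, and (for conditions with planted marker failures) which
#' nucleoli each negative marker "missed".
#'
#' @name ground_truth
#' @keywords internal
NULL

new_ground_truth <- function(nucleus_labels, nucleolus_labels, parent_of,
                             planted_mean, missed_by, border_nuclei,
                             pixel_size, z_spacing) {
  structure(
    list(nucleus_labels = nucleus_labels, nucleolus_labels = nucleolus_labels,
         parent_of = parent_of, planted_mean = planted_mean,
         missed_by = missed_by, border_nuclei = border_nuclei,
         pixel_size = pixel_size, z_spacing = z_spacing),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d nuclei, %d nucleoli\n",
              max(x$nucleus_labels), length(x$parent_of)))
  invisible(x)
}

placement_error <- function(msg) {
  stop(structure(class = c("nucleodemark_placement_error", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}

# Pixel-centre coordinate vectors in µm.
axis_coords <- function(n, step) (seq_len(n) - 0.5) * step

# Rasterize one ellipse/ellipsoid into label array `lab` (modified copy
# returned). Center/semi-axes in µm; theta rotates in the xy plane.
rasterize_ellipsoid <- function(lab, center, semi, theta, spec) {
  d <- dim(lab)
  px <- spec$pixel_size
  xs <- axis_coords(d[1], px); ys <- axis_coords(d[2], px)
  m <- max(semi[1:2])
  ix <- which(xs >= center[1] - m - px & xs <= center[1] + m + px)
  iy <- which(ys >= center[2] - m - px & ys <= center[2] + m + px)
  if (length(d) == 3L) {
    zs <- axis_coords(d[3], spec$z_spacing)
    iz <- which(zs >= center[3] - semi[3] - spec$z_spacing &
                  zs <= center[3] + semi[3] + spec$z_spacing)
  } else iz <- 1L
  if (!length(ix) || !length(iy) || !length(iz)) return(list(lab = lab, idx = integer(0)))
  gx <- xs[ix] - center[1]; gy <- ys[iy] - center[2]
  ct <- cos(theta); st <- sin(theta)
  u <- outer(gx, gy, function(a, b) ct * a + st * b)
  v <- outer(gx, gy, function(a, b) -st * a + ct * b)
  q2d <- (u / semi[1])^2 + (v / semi[2])^2
  idx <- integer(0)
  if (length(d) == 2L) {
    sel <- which(q2d <= 1)
    if (length(sel)) {
      rows <- ix[(sel - 1L) %% length(ix) + 1L]
      cols <- iy[(sel - 1L) %/% length(ix) + 1L]
      idx <- rows + (cols - 1L) * d[1]
    }
  } else {
    zs <- axis_coords(d[3], spec$z_spacing)
    for (k in iz) {
      qz <- ((zs[k] - center[3]) / semi[3])^2
      sel <- which(q2d + qz <= 1)
      if (length(sel)) {
        rows <- ix[(sel - 1L) %% length(ix) + 1L]
        cols <- iy[(sel - 1L) %/% length(ix) + 1L]
        idx <- c(idx, rows + (cols - 1L) * d[1] + (k - 1L) * d[1] * d[2])
      }
    }
  }
  list(idx = idx)
}

sphere_idx <- function(dims, center, r, spec) {
  semi <- if (length(dims) == 3L) c(r, r, r) else c(r, r)
  rasterize_ellipsoid(array(0L, dims), center, semi, 0, spec)$idx
}

field_extent_um <- function(spec) {
  d <- spec$field_shape
  ext <- d[1:2] * spec$pixel_size
  if (length(d) == 3L) ext <- c(ext, d[3] * spec$z_spacing)
  ext
}

place_nuclei <- function(spec) {
  ext <- field_extent_um(spec)
  three_d <- length(spec$field_shape) == 3L
  margin <- spec$border_margin_um
  nuclei <- list()
  for (i in seq_len(spec$n_nuclei)) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      ab <- sort(stats::runif(2, spec$nucleus_radius_range[1],
                              spec$nucleus_radius_range[2]), decreasing = TRUE)
      theta <- stats::runif(1, 0, pi)
      lo <- pmin(margin, ext[1:2] / 2)
      cx <- stats::runif(1, lo[1], ext[1] - lo[1])
      cy <- stats::runif(1, lo[2], ext[2] - lo[2])
      if (three_d) {
        cz_semi <- spec$nucleus_z_ratio * ab[1]
        if (2 * cz_semi > ext[3]) {
          placement_error("stack too thin for the requested nuclear size")
        }
        # nuclei stay whole along z; xy border contact is governed by margin
        cz <- stats::runif(1, cz_semi, ext[3] - cz_semi)
        center <- c(cx, cy, cz)
        semi <- c(ab, cz_semi)
      } else {
        center <- c(cx, cy)
        semi <- ab
      }
      ok <- TRUE
      for (nu in nuclei) {
        gap <- sqrt(sum((nu$center[1:2] - center[1:2])^2))
        if (gap < max(nu$semi[1:2]) + max(semi[1:2]) + 0.5) { ok <- FALSE; break }
      }
      if (ok) {
        nuclei[[i]] <- list(center = center, semi = semi, theta = theta)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      placement_error(sprintf(
        "could not place nucleus %d of %d without overlap", i, spec$n_nuclei))
    }
  }
  nuclei
}

# Place the nucleoli of one nucleus; returns list of (center, r) with
# fragmentation already applied (each remnant is one ground-truth nucleolus).
place_nucleoli <- function(spec, nucleus, nucleus_idx, dims) {
  three_d <- length(dims) == 3L
  sep <- 2 * spec$pixel_size
  for (layout_try in seq_len(25L)) {
    n_sites <- sample(seq(spec$nucleoli_per_nucleus_range[1],
                          spec$nucleoli_per_nucleus_range[2]), 1L)
    out <- list()
    failed <- FALSE
    for (s in seq_len(n_sites)) {
      r_site <- stats::runif(1, spec$nucleolus_radius_range[1],
                             spec$nucleolus_radius_range[2])
      site <- sample_point_in_nucleus(spec, nucleus, nucleus_idx, dims,
                                      r_site, out, sep)
      if (is.null(site)) { failed <- TRUE; break }
      if (spec$frag_split > 1L) {
        r_rem <- r_site * spec$frag_shrink
        for (f in seq_len(spec$frag_split)) {
          rem <- sample_point_in_nucleus(spec, nucleus, nucleus_idx, dims,
                                         r_rem, out, sep,
                                         near = site$center,
                                         near_dist = 2.5 * r_site)
          if (is.null(rem)) { failed <- TRUE; break }
          out[[length(out) + 1L]] <- list(center = rem$center, r = r_rem,
                                          idx = rem$idx)
        }
        if (failed) break
      } else {
        out[[length(out) + 1L]] <- list(center = site$center, r = r_site,
                                        idx = site$idx)
      }
    }
    if (!failed) return(out)
  }
  placement_error("could not place the requested nucleoli inside a nucleus")
}

sample_point_in_nucleus <- function(spec, nucleus, nucleus_idx, dims, r,
                                    existing, sep, near = NULL,
                                    near_dist = Inf) {
  three_d <- length(dims) == 3L
  for (try in seq_len(300L)) {
    if (is.null(near)) {
      jitter <- stats::runif(length(nucleus$center), -1, 1) * nucleus$semi
      center <- nucleus$center + jitter
    } else {
      center <- near + stats::runif(length(near), -1, 1) * near_dist
    }
    ok <- TRUE
    for (e in existing) {
      dvec <- e$center - center
      if (sqrt(sum(dvec^2)) < e$r + r + sep) { ok <- FALSE; break }
    }
    if (!ok) next
    idx <- sphere_idx(dims, center, r, spec)
    if (length(idx) == 0L) next
    if (all(idx %in% nucleus_idx)) return(list(center = center, idx = idx))
  }
  NULL
}

#' Render a synthetic multi-channel fluorescence scene
#'
#' Places elliptical nuclei and disjoint nucleoli according to the spec,
#' plants per-channel intensities (background outside cells, nucleoplasm
#' level inside nuclei, contrast-scaled level inside nucleoli), applies the
#' spec's condition phenotype via [apply_condition()], adds Gaussian noise
#' and quantizes to the declared integer dtype with saturation clipping.
#' Noise-free planted means are recorded per nucleolus and channel before
#' noise is applied. The same spec (same seed) renders bit-identical output.
#'
#' @param spec a [scene_spec()].
#' @return a list of class `scene` with elements `channels` (named list of
#'   [channel_image()]), `truth` (a `ground_truth`) and `spec`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  spec <- validate_scene_spec(apply_condition(spec))
  withr::with_seed(spec$seed, render_scene_impl(spec))
}

render_scene_impl <- function(spec) {
  dims <- spec$field_shape
  three_d <- length(dims) == 3L
  nuclei <- place_nuclei(spec)

  nucleus_labels <- array(0L, dims)
  nucleus_idx_list <- vector("list", length(nuclei))
  for (i in seq_along(nuclei)) {
    idx <- rasterize_ellipsoid(nucleus_labels, nuclei[[i]]$center,
                               nuclei[[i]]$semi, nuclei[[i]]$theta, spec)$idx
    nucleus_labels[idx] <- i
    nucleus_idx_list[[i]] <- idx
  }

  nucleolus_labels <- array(0L, dims)
  parent_of <- integer(0)
  nucleolus_idx_list <- list()
  for (i in seq_along(nuclei)) {
    nl <- place_nucleoli(spec, nuclei[[i]], nucleus_idx_list[[i]], dims)
    for (n1 in nl) {
      lab <- length(parent_of) + 1L
      nucleolus_labels[n1$idx] <- lab
      parent_of[as.character(lab)] <- i
      nucleolus_idx_list[[lab]] <- n1$idx
    }
  }
  n_nucleoli <- length(parent_of)

  # Disjoint per-marker miss sets (DRB): each nucleolus is missed by at most
  # one negative marker.
  neg <- names(spec$channels)[vapply(spec$channels, function(ch)
    ch$role == "marker" && ch$polarity == "excluded", logical(1))]
  missed <- matrix(FALSE, nrow = n_nucleoli, ncol = length(neg),
                   dimnames = list(NULL, neg))
  if (spec$miss_prob > 0 && length(neg) > 0 && n_nucleoli > 0) {
    if (length(neg) >= 2L) {
      p <- c(spec$miss_prob, spec$miss_prob, 1 - 2 * spec$miss_prob)
      assign_to <- apply(stats::rmultinom(n_nucleoli, 1L, p), 2,
                         which.max)
      missed[, 1] <- assign_to == 1L
      missed[, 2] <- assign_to == 2L
    } else {
      missed[, 1] <- stats::runif(n_nucleoli) < spec$miss_prob
    }
  }

  # Planted noise-free means per nucleolus and channel.
  planted <- vector("list", length(spec$channels))
  names(planted) <- names(spec$channels)
  for (nm in names(spec$channels)) {
    ch <- spec$channels[[nm]]
    eff_contrast <- rep(ch$contrast, n_nucleoli)
    if (nm %in% colnames(missed)) {
      eff_contrast[missed[, nm]] <- ch$contrast * spec$miss_attenuation
    }
    planted[[nm]] <- ch$nucleoplasm_level * contrast_factor(eff_contrast) *
      ch$effect
  }

  channels <- vector("list", length(spec$channels))
  names(channels) <- names(spec$channels)
  dmax <- dtype_max(spec$dtype)
  all_nucleus_idx <- which(nucleus_labels > 0L)
  for (nm in names(spec$channels)) {
    ch <- spec$channels[[nm]]
    img <- array(spec$background_level, dims)
    img[all_nucleus_idx] <- ch$nucleoplasm_level
    if (n_nucleoli > 0) {
      for (lab in seq_len(n_nucleoli)) {
        img[nucleolus_idx_list[[lab]]] <- planted[[nm]][lab]
      }
    }
    if (spec$noise_sigma > 0 || spec$poisson_scaling) {
      sd <- if (spec$poisson_scaling) {
        sqrt(spec$noise_sigma^2 + pmax(img, 0))
      } else spec$noise_sigma
      img <- img + stats::rnorm(length(img), 0, sd)
    }
    img <- round(img)
    img[img < 0] <- 0
    img[img > dmax] <- dmax
    channels[[nm]] <- channel_image(img, spec$pixel_size,
                                    z_spacing = if (three_d) spec$z_spacing,
                                    polarity = ch$polarity,
                                    dtype = spec$dtype, name = nm)
  }

  planted_tbl <- tibble::tibble(
    nucleolus = rep(seq_len(n_nucleoli), times = length(spec$channels)),
    channel = rep(names(spec$channels), each = n_nucleoli),
    planted_mean = unlist(planted, use.names = FALSE)
  )
  missed_tbl <- tibble::tibble(
    nucleolus = rep(seq_len(n_nucleoli), times = ncol(missed)),
    channel = rep(colnames(missed), each = n_nucleoli),
    missed = as.vector(missed)
  )
  truth <- new_ground_truth(
    nucleus_labels, nucleolus_labels, parent_of, planted_tbl, missed_tbl,
    border_nuclei = border_labels(nucleus_labels),
    pixel_size = spec$pixel_size,
    z_spacing = if (three_d) spec$z_spacing else NULL)

  structure(list(channels = channels, truth = truth, spec = spec),
            class = "scene")
}

# Labels touching any spatial border of the field.
border_labels <- function(labels) {
  d <- dim(labels)
  if (length(d) == 2L) {
    edge <- c(labels[1, ], labels[d[1], ], labels[, 1], labels[, d[2]])
  } else {
    edge <- c(labels[1, , ], labels[d[1], , ], labels[, 1, ],
              labels[, d[2], ], labels[, , 1], labels[, , d[3]])
  }
  sort(unique(edge[edge > 0L]))
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %s, channels: %s, %d nuclei / %d nucleoli, seed %d\n",
              paste(dim(x$truth$nucleus_labels), collapse = "x"),
              paste(names(x$channels), collapse = ", "),
              max(x$truth$nucleus_labels), length(x$truth$parent_of),
              x$spec$seed))
  invisible(x)
}

#' Render replicate fields of a scene spec
#'
#' Renders `n_fields` independent fields from one spec, with per-field seeds
#' derived from `base_seed` (recorded in each returned spec), mirroring the
#' replicate structure of an imaging experiment (several fields per
#' independent experiment, at least 30 cells per data point).
#'
#' @param spec a [scene_spec()].
#' @param n_fields number of fields (>= 1).
#' @param base_seed seed of the first field; field `i` uses `base_seed + i - 1`.
#' @return a list of `scene` objects; attribute `total_nuclei` reports the
#'   summed cell count.
#' @export
render_replicates <- function(spec, n_fields, base_seed = spec$seed) {
  if (n_fields < 1L) stop("n_fields must be >= 1", call. = FALSE)
  scenes <- lapply(seq_len(n_fields), function(i) {
    s <- spec
    s$seed <- as.integer(base_seed + i - 1L)
    render_scene(s)
  })
  attr(scenes, "total_nuclei") <-
    sum(vapply(scenes, function(s) max(s$truth$nucleus_labels), numeric(1)))
  scenes
}
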