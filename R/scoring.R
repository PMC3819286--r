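conn_offsets <- function(connectivity, three_d) {
  if (three_d) {
    if (!connectivity %in% c(6, 26)) {
      stop("3D connectivity must be 6 or 26", call. = FALSE)
    }
    g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
    if (connectivity == 6) g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1, ]
    cbind(as.integer(g$dx), as.integer(g$dy), as.integer(g$dz))
  } else {
    if (!connectivity %in% c(4, 8)) {
      stop("2D connectivity must be 4 or 8", call. = FALSE)
    }
    g <- expand.grid(dx = -1:1, dy = -1:1)
    g <- g[!(g$dx == 0 & g$dy == 0), ]
    if (connectivity == 4) g <- g[abs(g$dx) + abs(g$dy) == 1, ]
    cbind(as.integer(g$dx), as.integer(g$dy), 0L)
  }
}

label_mask <- function(mask, connectivity) {
  d <- dim(mask)
  lab <- cpp_label_components(as.logical(mask), as.integer(d),
                              conn_offsets(connectivity, length(d) == 3L))
  dim(lab) <- d
  lab
}

# Otsu threshold of a value vector on the [0, dmax] grey scale.
otsu_threshold <- function(vals, dmax = 65535) {
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L || diff(range(vals)) == 0) return(Inf)
  img <- EBImage::Image(matrix(vals / dmax, ncol = 1))
  EBImage::otsu(img, range = c(0, 1), levels = 256) * dmax
}

#' Segment nuclei from a nuclear-stain channel
#'
#' Global thresholding (Otsu by default, or a fixed user threshold in the
#' ImageJ-style mode), hole filling, removal of objects below a minimum
#' size, and connected-component labelling (8-connectivity in 2D,
#' 26-connectivity in 3D). Nuclei touching the field border are flagged (not
#' deleted); downstream quality control excludes them from quantification.
#'
#' @param dapi a [channel_image()] of the DAPI-like nuclear stain (2D or 3D).
#' @param min_size minimum object size in µm² (2D) or µm³ (3D).
#' @param threshold optional fixed grey-level threshold; when given, Otsu is
#'   skipped.
#' @return an integer label array of class `nucleus_mask`, with attributes
#'   `border_labels`, `pixel_size` and `z_spacing`.
#' @export
segment_nuclei <- function(dapi, min_size = 30, threshold = NULL) {
  stopifnot(inherits(dapi, "channel_image"))
  x <- dapi$pixels
  d <- dim(x)
  three_d <- length(d) == 3L
  thr <- threshold %||% otsu_threshold(as.numeric(x), dtype_max(dapi$dtype))
  mask <- x > thr
  if (!any(mask)) {
    warning("no nuclear foreground found; returning an empty mask",
            call. = FALSE)
    return(new_nucleus_mask(array(0L, d), integer(0), dapi))
  }
  # fill intranuclear holes (slice-wise for stacks)
  filled <- EBImage::fillHull(EBImage::Image(mask * 1, dim = d))
  mask <- EBImage::imageData(filled) > 0.5
  lab <- label_mask(mask, if (three_d) 26 else 8)
  voxel <- dapi$pixel_size^2 * (if (three_d) dapi$z_spacing else 1)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes * voxel >= min_size)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- array(0L, d)
  nz <- lab > 0L
  out[nz] <- relab[lab[nz]]
  new_nucleus_mask(out, border_labels(out), dapi)
}

new_nucleus_mask <- function(labels, border, img) {
  structure(labels, class = "nucleus_mask",
            border_labels = border,
            pixel_size = img$pixel_size, z_spacing = img$z_spacing)
}

#' Constraints for nucleolar segment scoring
#'
#' Candidate segments are accepted on the basis of size constraints and
#' intensity above local background: area (2D, µm²) or volume (3D, µm³)
#' within `[min_size, max_size]`, and mean filter response inside the
#' candidate exceeding the mean in a surrounding intranuclear annulus by at
#' least `min_intensity_above_background` grey levels.
#'
#' @param min_size,max_size accepted size range (µm² in 2D, µm³ in 3D);
#'   defaults 0.5--80 µm² cover typical HeLa nucleoli.
#' @param min_intensity_above_background minimum mean response contrast over
#'   the local background annulus, in grey levels; the default (100) is on
#'   the order of the camera noise so that candidates whose contrast is
#'   within the noise are rejected.
#' @param background_annulus_width width of the intranuclear background
#'   annulus around each candidate, µm.
#' @param connectivity neighbor rule (4/8 in 2D, 6/26 in 3D); `NULL` picks
#'   8 or 26 by dimensionality.
#' @return an object of class `scoring_constraints`.
#' @export
scoring_constraints <- function(min_size = 0.5, max_size = 80,
                                min_intensity_above_background = 100,
                                background_annulus_width = 1,
                                connectivity = NULL) {
  if (!(min_size > 0 && min_size < max_size)) {
    stop("need 0 < min_size < max_size", call. = FALSE)
  }
  if (background_annulus_width <= 0) {
    stop("background_annulus_width must be > 0", call. = FALSE)
  }
  if (min_intensity_above_background < 0) {
    stop("min_intensity_above_background must be >= 0", call. = FALSE)
  }
  structure(list(min_size = min_size, max_size = max_size,
                 min_intensity_above_background =
                   min_intensity_above_background,
                 background_annulus_width = background_annulus_width,
                 connectivity = connectivity),
            class = "scoring_constraints")
}

# Dilate a set of linear indices by an offset set, clipped to the image.
dilate_indices <- function(idx, dims, offsets) {
  co <- arrayInd(idx, dims)
  if (ncol(co) == 2L) co <- cbind(co, 1L)
  nx <- dims[1]; ny <- dims[2]; nz <- if (length(dims) == 3L) dims[3] else 1L
  out <- integer(0)
  for (j in seq_len(nrow(offsets))) {
    xx <- co[, 1] + offsets[j, 1]
    yy <- co[, 2] + offsets[j, 2]
    zz <- co[, 3] + offsets[j, 3]
    ok <- xx >= 1L & xx <= nx & yy >= 1L & yy <= ny & zz >= 1L & zz <= nz
    out <- c(out, xx[ok] + (yy[ok] - 1L) * nx + (zz[ok] - 1L) * nx * ny)
  }
  unique(out)
}

new_segment_labels <- function(labels, parent_of, provenance, stats,
                               pixel_size, z_spacing) {
  structure(list(labels = labels, parent_of = parent_of,
                 provenance = provenance, stats = stats,
                 pixel_size = pixel_size, z_spacing = z_spacing),
            class = "segment_labels")
}

#' @export
print.segment_labels <- function(x, ...) {
  cat(sprintf("<segment_labels> %d segments in %d nuclei (%s)\n",
              length(x$parent_of), length(unique(x$parent_of)),
              x$provenance$mode %||% "unknown mode"))
  invisible(x)
}

#' Score nucleolar segments within nuclei (2D)
#'
#' Converts a median-filtered holes image into accepted nucleolar segments.
#' Within each nucleus, the filter response is thresholded (Otsu restricted
#' to intranuclear pixels, or a fixed user threshold), connected components
#' become candidates, and each candidate is kept iff its area lies within
#' the configured bounds and its mean response exceeds the mean response of
#' a surrounding intranuclear annulus (other candidates excluded) by at
#' least the configured floor. Kept candidates are relabelled contiguously
#' and linked to their parent nucleus.
#'
#' @param median_img a [holes_image()], normally the output of
#'   [median_denoise()].
#' @param nuclei a `nucleus_mask` from [segment_nuclei()].
#' @param constraints a [scoring_constraints()].
#' @param threshold optional fixed response threshold replacing per-nucleus
#'   Otsu.
#' @param provenance optional list recording which marker/mode produced the
#'   holes image.
#' @return a `segment_labels` object.
#' @export
score_nucleoli <- function(median_img, nuclei, constraints =
                             scoring_constraints(), threshold = NULL,
                           provenance = list()) {
  stopifnot(inherits(median_img, "holes_image"),
            inherits(constraints, "scoring_constraints"))
  if (is_3d(median_img$response)) {
    stop("score_nucleoli expects 2D input; use score_nucleoli_3d",
         call. = FALSE)
  }
  score_engine(median_img, nuclei, constraints, threshold, provenance)
}

#' Score nucleolar segments in a 3D z-stack
#'
#' As [score_nucleoli()], with volumetric constraints (µm³) and
#' 26-connectivity on anisotropic voxels. A single-slice stack gives the
#' same segments as the 2D scorer on that slice.
#'
#' @inheritParams score_nucleoli
#' @return a `segment_labels` object whose stats report volumes in µm³.
#' @export
score_nucleoli_3d <- function(median_img, nuclei, constraints =
                                scoring_constraints(), threshold = NULL,
                              provenance = list()) {
  stopifnot(inherits(median_img, "holes_image"))
  if (!is_3d(median_img$response)) {
    stop("score_nucleoli_3d expects a 3D stack", call. = FALSE)
  }
  if (is.null(median_img$z_spacing)) {
    stop("3D scoring requires z-spacing metadata", call. = FALSE)
  }
  score_engine(median_img, nuclei, constraints, threshold, provenance)
}

score_engine <- function(median_img, nuclei, constraints, threshold,
                         provenance) {
  resp <- median_img$response
  d <- dim(resp)
  three_d <- length(d) == 3L
  if (!identical(dim(nuclei), d)) {
    stop("holes image and nucleus mask geometries differ", call. = FALSE)
  }
  conn <- constraints$connectivity %||% (if (three_d) 26 else 8)
  conn_off <- conn_offsets(conn, three_d)
  ann_off <- if (three_d) {
    ball_offsets(constraints$background_annulus_width,
                 median_img$pixel_size, median_img$z_spacing)
  } else {
    disk_offsets(constraints$background_annulus_width /
                   median_img$pixel_size)
  }
  voxel <- median_img$pixel_size^2 *
    (if (three_d) median_img$z_spacing else 1)
  border <- attr(nuclei, "border_labels") %||% integer(0)

  out <- array(0L, d)
  parent_of <- integer(0)
  rows <- list()
  n_nuc <- max(0L, max(nuclei))
  nuc_arr <- as.integer(nuclei); dim(nuc_arr) <- d
  for (L in seq_len(n_nuc)) {
    pix <- which(nuc_arr == L)
    if (!length(pix)) next
    thr <- threshold %||% otsu_threshold(resp[pix], max(resp[pix]))
    sel <- pix[resp[pix] > thr]
    if (!length(sel)) next
    mask <- array(FALSE, d)
    mask[sel] <- TRUE
    comp <- label_mask(mask, conn)
    ncand <- max(comp)
    cand_idx <- split(which(comp > 0L), comp[comp > 0L])
    all_cand <- unlist(cand_idx, use.names = FALSE)
    for (ci in seq_len(ncand)) {
      idx <- cand_idx[[as.character(ci)]]
      size_um <- length(idx) * voxel
      if (size_um < constraints$min_size || size_um > constraints$max_size) {
        next
      }
      ann <- dilate_indices(idx, d, ann_off)
      ann <- setdiff(intersect(ann, pix), all_cand)
      bg <- if (length(ann)) mean(resp[ann]) else 0
      contrast <- mean(resp[idx]) - bg
      if (contrast < constraints$min_intensity_above_background) next
      lab <- length(parent_of) + 1L
      out[idx] <- lab
      parent_of[as.character(lab)] <- L
      rows[[lab]] <- tibble::tibble(
        segment = lab, parent_nucleus = L, n_pixels = length(idx),
        size_um = size_um, mean_response = mean(resp[idx]),
        background_response = bg, response_contrast = contrast,
        parent_on_border = L %in% border)
    }
  }
  stats <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    segment = integer(0), parent_nucleus = integer(0),
    n_pixels = integer(0), size_um = numeric(0), mean_response = numeric(0),
    background_response = numeric(0), response_contrast = numeric(0),
    parent_on_border = logical(0))
  provenance$polarity_used <- median_img$polarity_used
  provenance$constraints <- constraints
  new_segment_labels(out, parent_of, provenance, stats,
                     median_img$pixel_size, median_img$z_spacing)
}
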