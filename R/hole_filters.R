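#' @useDynLib nucleodemark, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Structuring-element offset sets ---------------------------------------

# Disk of radius r_px (pixels): all (dx, dy) with dx^2 + dy^2 <= r^2.
disk_offsets <- function(r_px) {
  r <- floor(r_px + 1e-9)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= r_px^2 + 1e-9, , drop = FALSE]
  cbind(as.integer(g$dx), as.integer(g$dy), 0L)
}

# Anisotropy-aware ball: physical radius in µm against lateral pixel size
# and axial slice spacing.
ball_offsets <- function(r_um, pixel_size, z_spacing) {
  rx <- floor(r_um / pixel_size + 1e-9)
  rz <- floor(r_um / z_spacing + 1e-9)
  g <- expand.grid(dx = -rx:rx, dy = -rx:rx, dz = -rz:rz)
  keep <- (g$dx * pixel_size)^2 + (g$dy * pixel_size)^2 +
    (g$dz * z_spacing)^2 <= r_um^2 + 1e-9
  g <- g[keep, , drop = FALSE]
  cbind(as.integer(g$dx), as.integer(g$dy), as.integer(g$dz))
}

box_offsets <- function(r_px, three_d = FALSE) {
  r <- as.integer(r_px)
  if (three_d) {
    g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
    cbind(as.integer(g$dx), as.integer(g$dy), as.integer(g$dz))
  } else {
    g <- expand.grid(dx = -r:r, dy = -r:r)
    cbind(as.integer(g$dx), as.integer(g$dy), 0L)
  }
}

rank_filter <- function(x, offsets, op) {
  d <- dim(x)
  out <- cpp_rank_filter(as.numeric(x), as.integer(d), offsets, op)
  dim(out) <- d
  out
}

morph_erode  <- function(x, offsets) rank_filter(x, offsets, 0L)
morph_dilate <- function(x, offsets) rank_filter(x, offsets, 1L)
morph_open   <- function(x, offsets) morph_dilate(morph_erode(x, offsets), offsets)
morph_close  <- function(x, offsets) morph_erode(morph_dilate(x, offsets), offsets)

structuring_offsets <- function(img, radius_um) {
  x <- img$pixels
  d <- dim(x)
  r_px <- radius_um / img$pixel_size
  if (r_px < 1) {
    stop("structuring radius is smaller than 1 pixel", call. = FALSE)
  }
  if (2 * r_px + 1 > min(d[1:2])) {
    stop("structuring radius exceeds the image extent", call. = FALSE)
  }
  if (is_3d(x)) ball_offsets(radius_um, img$pixel_size, img$z_spacing)
  else disk_offsets(r_px)
}

# Hole filters ----------------------------------------------------------

#' Detect light holes (white top-hat)
#'
#' Demarcates nucleoli from a positive nucleolar marker: when the marker is
#' concentrated in nucleoli, nucleoli are brighter than the surrounding
#' nucleoplasm and appear as "light holes". The filter is the white top-hat
#' transform, `source - opening(source)`, with a disk (2D) or
#' anisotropy-aware ball (3D) structuring element of the given physical
#' radius. Bright blobs smaller than the structuring element yield a positive
#' response; flat regions yield zero. Borders are handled by symmetric
#' reflection.
#'
#' @param img a [channel_image()].
#' @param structuring_radius structuring element radius in micrometres; it
#'   must be at least the radius of the largest nucleolus to be detected
#'   (default in the pipeline: 1.25 x the configured maximum nucleolus
#'   radius) and at least one pixel.
#' @return a [holes_image()] with `polarity_used = "light"`.
#' @seealso [detect_dark_holes()], [median_denoise()]
#' @export
detect_light_holes <- function(img, structuring_radius) {
  stopifnot(inherits(img, "channel_image"))
  off <- structuring_offsets(img, structuring_radius)
  resp <- img$pixels - morph_open(img$pixels, off)
  holes_image(resp, "light", structuring_radius, img$pixel_size, img$z_spacing)
}

#' Detect dark holes (black top-hat)
#'
#' Demarcates nucleoli from a negative nucleolar marker: when the marker is
#' excluded from nucleoli (e.g. CAS, HuR), nucleoli appear as dark holes in
#' the nucleoplasm. The filter is the black top-hat transform,
#' `closing(source) - source`; dark blobs smaller than the structuring
#' element yield a positive response. `detect_dark_holes(img)` equals
#' `detect_light_holes()` of the intensity-inverted image.
#'
#' @inheritParams detect_light_holes
#' @return a [holes_image()] with `polarity_used = "dark"`.
#' @export
detect_dark_holes <- function(img, structuring_radius) {
  stopifnot(inherits(img, "channel_image"))
  off <- structuring_offsets(img, structuring_radius)
  resp <- morph_close(img$pixels, off) - img$pixels
  holes_image(resp, "dark", structuring_radius, img$pixel_size, img$z_spacing)
}

#' Median-denoise a holes image
#'
#' Per-pixel median over a square (2D) or cubic (3D) neighborhood of the
#' given pixel radius (radius 1 = 3x3), applied to a hole-filter response to
#' suppress isolated noise spikes before segment scoring. Borders are handled
#' by symmetric reflection; geometry is preserved.
#'
#' @param holes a [holes_image()].
#' @param radius neighborhood radius in pixels (integer >= 1).
#' @return a [holes_image()] of the same geometry.
#' @export
median_denoise <- function(holes, radius = 1L) {
  stopifnot(inherits(holes, "holes_image"))
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1) {
    stop("median radius must be a positive number of pixels", call. = FALSE)
  }
  off <- box_offsets(radius, three_d = is_3d(holes$response))
  resp <- rank_filter(holes$response, off, 2L)
  holes_image(resp, holes$polarity_used, holes$structuring_radius,
              holes$pixel_size, holes$z_spacing)
}

#' Combine two negative-marker images with the arithmetic add
#'
#' Pixel-wise sum of two negative-marker channels, accumulated in double
#' precision and then linearly rescaled so that the maximum of the sum maps
#' to the full output dtype range (no silent saturation). Adding two markers
#' that are excluded from nucleoli deepens the nucleolar holes relative to
#' per-pixel noise, so nucleoli missed by one marker (e.g. after DRB
#' treatment) can still be demarcated from the combined image with
#' [detect_dark_holes()].
#'
#' @param a,b [channel_image()]s of identical geometry and pixel size, both
#'   with `polarity = "excluded"`.
#' @param dtype output bit depth; defaults to the dtype of `a`.
#' @return a [channel_image()] with `polarity = "excluded"`.
#' @export
add_images <- function(a, b, dtype = a$dtype) {
  stopifnot(inherits(a, "channel_image"), inherits(b, "channel_image"))
  if (!same_geometry(a, b)) {
    stop("images to add must share shape, pixel size and z spacing",
         call. = FALSE)
  }
  if (a$polarity != "excluded" || b$polarity != "excluded") {
    stop("add_images combines negative (excluded) markers only", call. = FALSE)
  }
  s <- as.numeric(a$pixels) + as.numeric(b$pixels)
  m <- max(s)
  if (m > 0) s <- s * (dtype_max(dtype) / m)
  s <- round(s)
  dim(s) <- dim(a$pixels)
  channel_image(s, a$pixel_size, z_spacing = a$z_spacing,
                polarity = "excluded", dtype = dtype,
                name = paste(a$name %||% "a", b$name %||% "b", sep = "+"))
}

#' Invert a channel image
#'
#' Maps every pixel to `dtype_max - value`; turns dark holes into light holes
#' and vice versa.
#'
#' @param img a [channel_image()].
#' @return the inverted [channel_image()] with polarity flipped.
#' @export
invert_image <- function(img) {
  stopifnot(inherits(img, "channel_image"))
  pol <- switch(img$polarity, enriched = "excluded",
                excluded = "enriched", "unknown")
  channel_image(dtype_max(img$dtype) - img$pixels, img$pixel_size,
                z_spacing = img$z_spacing, polarity = pol,
                dtype = img$dtype, name = img$name)
}
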