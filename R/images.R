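#' Single-marker fluorescence image
#'
#' A `channel_image` wraps a 2D matrix or 3D array of pixel intensities for
#' one fluorescence channel, together with the physical pixel size, the bit
#' depth the camera delivered, and the marker's polarity with respect to
#' nucleoli: `"enriched"` for positive nucleolar markers (e.g. nucleolin,
#' which makes nucleoli brighter than the nucleoplasm), `"excluded"` for
#' negative markers (e.g. CAS or HuR, which leave nucleoli as dark holes),
#' or `"unknown"`.
#'
#' @param pixels numeric matrix (2D) or 3D array of intensities.
#' @param pixel_size lateral pixel size in micrometres (> 0).
#' @param z_spacing slice spacing in micrometres; required for 3D stacks.
#' @param polarity one of `"enriched"`, `"excluded"`, `"unknown"`.
#' @param dtype declared bit depth, `"16bit"` (0--65535) or `"8bit"` (0--255).
#' @param name optional channel name (e.g. `"nucleolin"`).
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(pixels, pixel_size, z_spacing = NULL,
                          polarity = c("unknown", "enriched", "excluded"),
                          dtype = c("16bit", "8bit"), name = NULL) {
  polarity <- match.arg(polarity)
  dtype <- match.arg(dtype)
  if (!is.numeric(pixels) || is.null(dim(pixels)) ||
      !(length(dim(pixels)) %in% c(2L, 3L))) {
    stop("'pixels' must be a numeric matrix or 3D array", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("'pixel_size' must be a single positive number (µm)", call. = FALSE)
  }
  if (length(dim(pixels)) == 3L) {
    if (is.null(z_spacing) || !is.numeric(z_spacing) || z_spacing <= 0) {
      stop("3D stacks require a positive 'z_spacing' (µm)", call. = FALSE)
    }
  } else {
    z_spacing <- NULL
  }
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > dtype_max(dtype)) {
    stop(sprintf("intensities outside the declared %s range [0, %d]",
                 dtype, dtype_max(dtype)), call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_size = pixel_size, z_spacing = z_spacing,
         polarity = polarity, dtype = dtype, name = name),
    class = "channel_image"
  )
}

#' Hole-filter response image
#'
#' The output of [detect_light_holes()] or [detect_dark_holes()]: a
#' non-negative residue ("holes image") with the same geometry as its source,
#' high where blobs smaller than the structuring element deviate from the
#' local background.
#'
#' @param response numeric matrix or 3D array, non-negative.
#' @param polarity_used `"light"` or `"dark"`.
#' @param structuring_radius structuring element radius in micrometres.
#' @param pixel_size,z_spacing geometry inherited from the source image.
#' @return an object of class `holes_image`.
#' @export
holes_image <- function(response, polarity_used = c("light", "dark"),
                        structuring_radius, pixel_size, z_spacing = NULL) {
  polarity_used <- match.arg(polarity_used)
  if (min(response) < -1e-9) {
    stop("holes response must be non-negative", call. = FALSE)
  }
  response[response < 0] <- 0
  structure(
    list(response = response, polarity_used = polarity_used,
         structuring_radius = structuring_radius,
         pixel_size = pixel_size, z_spacing = z_spacing),
    class = "holes_image"
  )
}

dtype_max <- function(dtype) switch(dtype, "8bit" = 255, "16bit" = 65535,
                                    stop("unknown dtype: ", dtype))

is_3d <- function(x) length(dim(x)) == 3L

img_pixels <- function(x) {
  if (inherits(x, "channel_image")) x$pixels
  else if (inherits(x, "holes_image")) x$response
  else x
}

#' @export
print.channel_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<channel_image%s> %s, %s, %s, pixel %g µm%s\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              paste(d, collapse = "x"), x$dtype, x$polarity, x$pixel_size,
              if (is.null(x$z_spacing)) "" else
                sprintf(", z %g µm", x$z_spacing)))
  invisible(x)
}

#' @export
print.holes_image <- function(x, ...) {
  d <- dim(x$response)
  cat(sprintf("<holes_image> %s, %s holes, structuring radius %g µm\n",
              paste(d, collapse = "x"), x$polarity_used, x$structuring_radius))
  invisible(x)
}

same_geometry <- function(a, b) {
  identical(dim(img_pixels(a)), dim(img_pixels(b))) &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    isTRUE(all.equal(a$z_spacing %||% -1, b$z_spacing %||% -1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
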