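#' Write a channel image or label mask as 16-bit TIFF
#'
#' 2D images are written as one plane, 3D stacks as one plane per slice.
#' Values are stored losslessly at the declared integer bit depth, so a
#' write-read round trip is bit-exact.
#'
#' @param x a [channel_image()] or an integer label array.
#' @param path output path (`.tif`).
#' @param dtype bit depth for plain arrays (label masks default to 16-bit).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(x, path, dtype = "16bit") {
  if (inherits(x, "channel_image")) {
    px <- x$pixels
    dtype <- x$dtype
  } else px <- x
  dmax <- dtype_max(dtype)
  if (max(px) > dmax || min(px) < 0) {
    stop("values outside the ", dtype, " range", call. = FALSE)
  }
  bits <- if (dtype == "8bit") 8L else 16L
  planes <- if (is_3d(px)) {
    lapply(seq_len(dim(px)[3]), function(k) px[, , k] / dmax)
  } else list(px / dmax)
  tiff::writeTIFF(planes, path, bits.per.sample = bits)
  invisible(path)
}

read_tiff_planes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  planes <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) stop("unreadable image (TIFF/OME-TIFF expected): ",
                             path, " [", conditionMessage(e), "]",
                             call. = FALSE))
  if (!is.list(planes)) planes <- list(planes)
  for (p in planes) {
    if (length(dim(p)) != 2L) {
      stop("unsupported format: multi-sample (e.g. RGB) images are not ",
           "single-marker grayscale channels", call. = FALSE)
    }
  }
  planes
}

#' Read a single-channel TIFF into a channel image
#'
#' Reads an 8/16-bit grayscale TIFF (one plane = 2D image, several planes =
#' z-stack). Pixel size is not stored by all writers, so it must be supplied
#' (or come from a scene's metadata sidecar via [read_scene()]).
#'
#' @param path TIFF path.
#' @param pixel_size lateral pixel size in µm (required).
#' @param z_spacing slice spacing in µm (required for stacks).
#' @param polarity,name marker annotation, see [channel_image()].
#' @return a [channel_image()].
#' @export
read_image <- function(path, pixel_size = NULL, z_spacing = NULL,
                       polarity = "unknown", name = NULL) {
  planes <- read_tiff_planes(path)
  if (is.null(pixel_size)) {
    stop("missing pixel size for ", path,
         ": supply 'pixel_size' (µm) explicitly", call. = FALSE)
  }
  dmax <- max(vapply(planes, max, numeric(1)))
  dtype <- if (dmax > 255) "16bit" else "8bit"
  px <- if (length(planes) == 1L) planes[[1]] else {
    if (is.null(z_spacing)) {
      stop("multi-plane stack requires 'z_spacing' (µm)", call. = FALSE)
    }
    array(unlist(planes), dim = c(dim(planes[[1]]), length(planes)))
  }
  channel_image(px, pixel_size, z_spacing = z_spacing, polarity = polarity,
                dtype = dtype, name = name %||%
                  tools::file_path_sans_ext(basename(path)))
}

#' Write a rendered scene to disk
#'
#' Writes one multi-plane TIFF with all channels (channel-major, then z for
#' stacks), 16-bit TIFF label masks for the ground-truth nuclei and
#' nucleoli, a CSV sidecar of planted noise-free means, the scene spec as
#' YAML, and a metadata YAML (dimensions, pixel size, channel names/roles)
#' that [read_scene()] uses to reconstruct everything bit-exactly.
#'
#' @param scene a `scene` from [render_scene()].
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return the metadata path, invisibly.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  stopifnot(inherits(scene, "scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dmax <- dtype_max(scene$spec$dtype)
  planes <- list()
  for (ch in scene$channels) {
    px <- ch$pixels
    if (is_3d(px)) {
      planes <- c(planes, lapply(seq_len(dim(px)[3]),
                                 function(k) px[, , k] / dmax))
    } else planes <- c(planes, list(px / dmax))
  }
  bits <- if (scene$spec$dtype == "8bit") 8L else 16L
  tiff::writeTIFF(planes, file.path(dir, paste0(name, ".tif")),
                  bits.per.sample = bits)
  write_image_tiff(scene$truth$nucleus_labels,
                   file.path(dir, paste0(name, "_nuclei.tif")))
  write_image_tiff(scene$truth$nucleolus_labels,
                   file.path(dir, paste0(name, "_nucleoli.tif")))
  utils::write.csv(scene$truth$planted_mean,
                   file.path(dir, paste0(name, "_planted.csv")),
                   row.names = FALSE)
  write_scene_spec(scene$spec, file.path(dir, paste0(name, "_spec.yaml")))
  meta <- list(
    field_shape = dim(img_pixels(scene$channels[[1]])),
    pixel_size = scene$spec$pixel_size,
    z_spacing = if (length(scene$spec$field_shape) == 3L)
      scene$spec$z_spacing,
    dtype = scene$spec$dtype,
    channels = lapply(scene$channels, function(ch)
      list(name = ch$name, polarity = ch$polarity)),
    parent_of = as.list(scene$truth$parent_of),
    border_nuclei = scene$truth$border_nuclei,
    missed_by = lapply(seq_len(nrow(scene$truth$missed_by)), function(i)
      as.list(scene$truth$missed_by[i, ])))
  meta_path <- file.path(dir, paste0(name, "_meta.yaml"))
  yaml::write_yaml(meta, meta_path)
  invisible(meta_path)
}

#' Read a scene written by [write_scene()]
#'
#' @param dir directory holding the scene files.
#' @param name file stem used at write time.
#' @return a list with `channels` (named [channel_image()]s) and `truth`
#'   (a `ground_truth`); pixel data round-trips bit-exactly.
#' @export
read_scene <- function(dir, name = "scene") {
  meta <- yaml::read_yaml(file.path(dir, paste0(name, "_meta.yaml")))
  d <- as.integer(unlist(meta$field_shape))
  three_d <- length(d) == 3L
  planes <- read_tiff_planes(file.path(dir, paste0(name, ".tif")))
  nz <- if (three_d) d[3] else 1L
  channels <- list()
  for (i in seq_along(meta$channels)) {
    take <- planes[((i - 1L) * nz + 1L):(i * nz)]
    px <- if (three_d) array(unlist(take), dim = d) else take[[1]]
    ch <- meta$channels[[i]]
    channels[[ch$name]] <- channel_image(
      px, meta$pixel_size, z_spacing = if (three_d) meta$z_spacing,
      polarity = ch$polarity, dtype = meta$dtype, name = ch$name)
  }
  read_labels <- function(stem) {
    pl <- read_tiff_planes(file.path(dir, paste0(name, stem)))
    lab <- if (three_d) array(unlist(pl), dim = d) else pl[[1]]
    storage.mode(lab) <- "integer"
    lab
  }
  missed <- dplyr::bind_rows(lapply(meta$missed_by, tibble::as_tibble))
  truth <- new_ground_truth(
    read_labels("_nuclei.tif"), read_labels("_nucleoli.tif"),
    setNames(as.integer(unlist(meta$parent_of)), names(meta$parent_of)),
    tibble::as_tibble(utils::read.csv(
      file.path(dir, paste0(name, "_planted.csv")))),
    missed, as.integer(unlist(meta$border_nuclei)),
    meta$pixel_size, if (three_d) meta$z_spacing)
  list(channels = channels, truth = truth)
}

write_scene_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Read a scene spec from YAML
#' @param path YAML file written by the generator.
#' @return a [scene_spec()].
#' @export
read_scene_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$field_shape <- as.integer(unlist(raw$field_shape))
  for (nm in c("nucleus_radius_range", "nucleolus_radius_range")) {
    raw[[nm]] <- as.numeric(unlist(raw[[nm]]))
  }
  raw$nucleoli_per_nucleus_range <-
    as.integer(unlist(raw$nucleoli_per_nucleus_range))
  spec <- structure(raw, class = "scene_spec")
  validate_scene_spec(spec)
}
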