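#' Measure per-nucleolus channel intensities
#'
#' For every accepted nucleolar segment, computes the mean and integrated
#' pixel intensity of each supplied channel over exactly the segment's
#' pixels. Measurements are always taken on the original (unfiltered)
#' channel images, never on holes images. One row per segment and channel,
#' in long format.
#'
#' @param labels a `segment_labels` object from [score_nucleoli()] /
#'   [score_nucleoli_3d()].
#' @param channels a named list of [channel_image()]s, geometry-matched to
#'   `labels`.
#' @param scene_id,replicate,condition identifiers recorded in the table.
#' @return a [tibble::tibble()] (`measurement_table`) with columns
#'   `scene_id`, `replicate`, `condition`, `nucleus_label`,
#'   `nucleolus_label`, `n_pixels`, `size_um` (µm² or µm³), `channel`,
#'   `mean_intensity`, `integrated_intensity`, plus the per-segment QC
#'   covariates `response_contrast` and `parent_on_border`.
#' @export
measure_segments <- function(labels, channels, scene_id = "scene",
                             replicate = 1L, condition = "control") {
  stopifnot(inherits(labels, "segment_labels"))
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("'channels' must be a named list", call. = FALSE)
  }
  lab <- labels$labels
  for (nm in names(channels)) {
    if (!identical(dim(img_pixels(channels[[nm]])), dim(lab))) {
      stop("channel '", nm, "' does not match the label geometry",
           call. = FALSE)
    }
  }
  n_seg <- length(labels$parent_of)
  if (n_seg == 0L) return(empty_measurement_table())
  idx <- which(lab > 0L)
  seg <- lab[idx]
  n_px <- tabulate(seg, nbins = n_seg)
  st <- labels$stats
  per_channel <- lapply(names(channels), function(nm) {
    v <- as.numeric(img_pixels(channels[[nm]])[idx])
    sums <- as.numeric(rowsum(v, seg, reorder = TRUE))
    tibble::tibble(
      scene_id = scene_id, replicate = replicate, condition = condition,
      nucleus_label = as.integer(labels$parent_of[as.character(1:n_seg)]),
      nucleolus_label = seq_len(n_seg),
      n_pixels = n_px,
      size_um = st$size_um[match(seq_len(n_seg), st$segment)],
      channel = nm,
      mean_intensity = sums / n_px,
      integrated_intensity = sums,
      response_contrast = st$response_contrast[match(seq_len(n_seg),
                                                     st$segment)],
      parent_on_border = st$parent_on_border[match(seq_len(n_seg),
                                                   st$segment)])
  })
  dplyr::bind_rows(per_channel)
}

empty_measurement_table <- function() {
  tibble::tibble(
    scene_id = character(0), replicate = integer(0), condition = character(0),
    nucleus_label = integer(0), nucleolus_label = integer(0),
    n_pixels = integer(0), size_um = numeric(0), channel = character(0),
    mean_intensity = numeric(0), integrated_intensity = numeric(0),
    response_contrast = numeric(0), parent_on_border = logical(0))
}

#' Automated quality control of a measurement table
#'
#' Replaces the visual inspection step of manual workflows ("segmentation
#' images were inspected visually to eliminate misidentified nucleoli") with
#' reproducible rules. Segments are dropped, with logged reasons, when
#' (in this order of precedence):
#' \itemize{
#'   \item their parent nucleus touches the field border (`"border"`);
#'   \item their size lies outside `size_bounds` (`"size"`);
#'   \item their scoring contrast over the intranuclear background is below
#'     `contrast_floor` (`"contrast"`);
#'   \item their parent nucleus holds more than `max_per_nucleus` segments
#'     (`"count"`; the whole nucleus is dropped as unreliable).
#' }
#' Surviving rows are returned unchanged; the exclusion log is attached as
#' attribute `"exclusions"` (also retrievable with [qc_exclusions()]).
#'
#' @param table a measurement table from [measure_segments()].
#' @param size_bounds length-2 numeric, accepted size range (µm²/µm³);
#'   `NULL` keeps all sizes.
#' @param contrast_floor minimum scoring response contrast; `NULL` disables.
#' @param max_per_nucleus maximum credible nucleolus count per nucleus.
#' @return the filtered table with attribute `exclusions`, a tibble of
#'   `scene_id`, `nucleolus_label` and `reason`.
#' @export
qc_filter <- function(table, size_bounds = NULL, contrast_floor = NULL,
                      max_per_nucleus = 10L) {
  seg <- dplyr::distinct(table, .data$scene_id, .data$nucleus_label,
                         .data$nucleolus_label, .data$size_um,
                         .data$response_contrast, .data$parent_on_border)
  seg$reason <- NA_character_
  if (!is.null(max_per_nucleus)) {
    counts <- dplyr::count(seg, .data$scene_id, .data$nucleus_label)
    bad <- counts[counts$n > max_per_nucleus, c("scene_id", "nucleus_label")]
    hit <- paste(seg$scene_id, seg$nucleus_label) %in%
      paste(bad$scene_id, bad$nucleus_label)
    seg$reason[hit] <- "count"
  }
  if (!is.null(contrast_floor)) {
    seg$reason[!is.na(seg$response_contrast) &
                 seg$response_contrast < contrast_floor] <- "contrast"
  }
  if (!is.null(size_bounds)) {
    seg$reason[seg$size_um < size_bounds[1] |
                 seg$size_um > size_bounds[2]] <- "size"
  }
  seg$reason[isTRUE_vec(seg$parent_on_border)] <- "border"

  excl <- seg[!is.na(seg$reason),
              c("scene_id", "nucleolus_label", "reason")]
  key <- paste(table$scene_id, table$nucleolus_label)
  drop_key <- paste(excl$scene_id, excl$nucleolus_label)
  out <- table[!key %in% drop_key, , drop = FALSE]
  attr(out, "exclusions") <- tibble::as_tibble(excl)
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Exclusion log of a QC-filtered table
#' @param table a table returned by [qc_filter()].
#' @return the exclusion tibble.
#' @export
qc_exclusions <- function(table) {
  attr(table, "exclusions") %||%
    tibble::tibble(scene_id = character(0), nucleolus_label = integer(0),
                   reason = character(0))
}

#' Measure a functional channel in existing nucleolar segments
#'
#' Applies the [measure_segments()] machinery to a functional readout
#' channel (e.g. EU incorporation reporting nascent RNA) using segments
#' demarcated from a marker channel, and appends the rows to an existing
#' measurement table so that downstream normalization and statistics are
#' shared.
#'
#' @param labels the `segment_labels` used for `table`.
#' @param eu_channel the functional [channel_image()], registered with the
#'   marker channels.
#' @param table the measurement table to append to.
#' @param name channel name recorded in the new rows.
#' @return the extended measurement table.
#' @export
measure_function_channel <- function(labels, eu_channel, table,
                                     name = eu_channel$name %||% "EU") {
  ids <- dplyr::distinct(table, .data$scene_id, .data$replicate,
                         .data$condition)
  if (nrow(ids) > 1L) {
    stop("table holds multiple scenes; measure each scene separately",
         call. = FALSE)
  }
  chans <- stats::setNames(list(eu_channel), name)
  extra <- measure_segments(labels, chans,
                            scene_id = if (nrow(ids)) ids$scene_id else "scene",
                            replicate = if (nrow(ids)) ids$replicate else 1L,
                            condition = if (nrow(ids)) ids$condition
                                        else "control")
  dplyr::bind_rows(table, extra)
}
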