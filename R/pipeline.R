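#' Pipeline configuration
#'
#' Describes a full synthetic experiment: which conditions to render, how
#' many independent replicates and fields, which marker strategy demarcates
#' nucleoli, the scoring constraints, and which channels are measured.
#'
#' @param conditions character vector of condition names (must include the
#'   control).
#' @param control_condition name of the control condition.
#' @param n_replicates independent experiments per condition (>= 2 for SEM
#'   and testing; the usual design is at least 3).
#' @param fields_per_replicate fields rendered per replicate.
#' @param marker_mode `"light"` (positive marker + detect light holes),
#'   `"dark"` (negative marker + detect dark holes) or `"add"` (sum of two
#'   negative markers + detect dark holes).
#' @param marker channel name(s): one name for `light`/`dark`, two for
#'   `add`. Defaults pick the first suitable channel(s) of the scene.
#' @param measure_channels channels measured in the accepted segments;
#'   default: all marker and function channels.
#' @param structuring_radius top-hat radius, µm; default 1.25 x the
#'   spec's maximum nucleolus radius.
#' @param median_radius median filter radius in pixels.
#' @param constraints a [scoring_constraints()].
#' @param qc list of [qc_filter()] arguments (`size_bounds`,
#'   `contrast_floor`, `max_per_nucleus`).
#' @param scene a [scene_spec()] used as the per-condition template.
#' @param base_seed integer; all per-scene seeds are derived from it.
#' @param effects optional named list `condition -> named numeric` of
#'   per-channel nucleolar effect multipliers to plant (e.g.
#'   `list(DRB = c(EU = 0.6))`), overriding the condition defaults.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(conditions = c("control", "DRB"),
                            control_condition = "control",
                            n_replicates = 3L,
                            fields_per_replicate = 1L,
                            marker_mode = c("light", "dark", "add"),
                            marker = NULL,
                            measure_channels = NULL,
                            structuring_radius = NULL,
                            median_radius = 1L,
                            constraints = scoring_constraints(),
                            qc = list(max_per_nucleus = 10L),
                            scene = scene_spec(),
                            base_seed = 1L,
                            effects = NULL) {
  marker_mode <- match.arg(marker_mode)
  if (!control_condition %in% conditions) {
    stop("conditions must include the control condition '",
         control_condition, "'", call. = FALSE)
  }
  bad <- setdiff(conditions, SCENE_CONDITIONS)
  if (length(bad)) {
    stop("unknown condition(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(conditions = conditions, control_condition = control_condition,
         n_replicates = as.integer(n_replicates),
         fields_per_replicate = as.integer(fields_per_replicate),
         marker_mode = marker_mode, marker = marker,
         measure_channels = measure_channels,
         structuring_radius = structuring_radius %||%
           1.25 * max(scene$nucleolus_radius_range),
         median_radius = median_radius, constraints = constraints,
         qc = qc, scene = scene, base_seed = as.integer(base_seed),
         effects = effects),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys mirror the [pipeline_config()] arguments,
#'   with `scene` and `constraints` as nested maps.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$scene)) raw$scene <- do.call(scene_spec, raw$scene)
  if (!is.null(raw$constraints)) {
    raw$constraints <- do.call(scoring_constraints, raw$constraints)
  }
  do.call(pipeline_config, raw)
}

pick_marker <- function(channels, mode, marker) {
  pol <- vapply(channels, `[[`, "", "polarity")
  role <- vapply(channels, `[[`, "", "role")
  if (mode == "light") {
    marker %||% names(channels)[which(role == "marker" &
                                        pol == "enriched")[1]]
  } else if (mode == "dark") {
    marker %||% names(channels)[which(role == "marker" &
                                        pol == "excluded")[1]]
  } else {
    m <- marker %||% names(channels)[which(role == "marker" &
                                             pol == "excluded")[1:2]]
    if (length(m) != 2L || anyNA(m)) {
      stop("add mode needs two negative-marker channels", call. = FALSE)
    }
    m
  }
}

#' Demarcate nucleoli in one scene
#'
#' The core demarcation chain on a rendered or loaded scene: marker
#' selection per the chosen mode, hole detection, median denoising, nucleus
#' segmentation from the nuclear stain, and constraint-based segment
#' scoring.
#'
#' @param scene a `scene` (or a list with a `channels` element).
#' @param config a [pipeline_config()].
#' @return a `segment_labels` object; the nucleus mask is attached as
#'   attribute `"nuclei"`.
#' @export
demarcate_scene <- function(scene, config) {
  channels <- scene$channels
  spec_channels <- scene$spec$channels %||% NULL
  roles <- if (!is.null(spec_channels)) {
    spec_channels
  } else {
    lapply(channels, function(ch) list(role = "marker",
                                       polarity = ch$polarity))
  }
  stain <- names(roles)[vapply(roles, function(x)
    identical(x$role, "nuclear_stain"), logical(1))][1]
  if (is.na(stain)) stop("no nuclear_stain channel", call. = FALSE)
  m <- pick_marker(roles, config$marker_mode, config$marker)
  img <- if (config$marker_mode == "add") {
    a <- channels[[m[1]]]; b <- channels[[m[2]]]
    a$polarity <- "excluded"; b$polarity <- "excluded"
    add_images(a, b)
  } else channels[[m]]
  holes <- if (config$marker_mode == "light") {
    detect_light_holes(img, config$structuring_radius)
  } else {
    detect_dark_holes(img, config$structuring_radius)
  }
  med <- median_denoise(holes, config$median_radius)
  nuclei <- segment_nuclei(channels[[stain]])
  three_d <- is_3d(med$response)
  segs <- if (three_d) {
    score_nucleoli_3d(med, nuclei, config$constraints,
                      provenance = list(marker = paste(m, collapse = "+"),
                                        mode = config$marker_mode))
  } else {
    score_nucleoli(med, nuclei, config$constraints,
                   provenance = list(marker = paste(m, collapse = "+"),
                                     mode = config$marker_mode))
  }
  attr(segs, "nuclei") <- nuclei
  segs
}

#' Run the full synthetic pipeline
#'
#' Renders every condition x replicate x field, demarcates nucleoli,
#' measures the configured channels on the original images, applies QC,
#' normalizes to the control per replicate and channel, and runs the
#' replicate-level comparison. All randomness derives from
#' `config$base_seed`, so a rerun with the same config writes byte-identical
#' CSVs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory; `NULL` skips writing files.
#' @param verbose print per-stage progress.
#' @return a list with `measurements` (QC-filtered, normalized table),
#'   `exclusions`, `comparison` (a `comparison_result`), and `scenes_meta`
#'   (per-scene seed/cell bookkeeping).
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  tables <- list()
  meta <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    spec0 <- config$scene
    spec0$condition <- cond
    spec0 <- apply_condition(spec0)
    eff <- config$effects[[cond]]
    for (nm in names(eff)) {
      spec0$channels[[nm]]$effect <- unname(eff[nm])
    }
    for (r in seq_len(config$n_replicates)) {
      base <- config$base_seed + 10000L * ci + 100L * r
      scenes <- render_replicates(spec0, config$fields_per_replicate, base)
      for (fi in seq_along(scenes)) {
        sc <- scenes[[fi]]
        segs <- demarcate_scene(sc, config)
        roles <- vapply(sc$spec$channels, `[[`, "", "role")
        measure_names <- config$measure_channels %||%
          names(roles)[roles %in% c("marker", "function")]
        tb <- measure_segments(segs, sc$channels[measure_names],
                               scene_id = sprintf("%s_r%d_f%d", cond, r, fi),
                               replicate = r, condition = cond)
        tables[[length(tables) + 1L]] <- tb
        meta[[length(meta) + 1L]] <- tibble::tibble(
          condition = cond, replicate = r, field = fi, seed = sc$spec$seed,
          n_nuclei = max(sc$truth$nucleus_labels),
          n_nucleoli = length(sc$truth$parent_of),
          n_segments = length(segs$parent_of))
      }
      say("condition %s replicate %d: rendered %d field(s)", cond, r,
          config$fields_per_replicate)
    }
  }
  table <- dplyr::bind_rows(tables)
  qc_args <- c(list(table = table), config$qc)
  table <- do.call(qc_filter, qc_args)
  excl <- qc_exclusions(table)
  table <- normalize_to_control(table, config$control_condition)
  comparison <- summarize_and_test(table, config$control_condition)
  scenes_meta <- dplyr::bind_rows(meta)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    utils::write.csv(excl, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(scenes_meta, file.path(out_dir, "scenes.csv"),
                     row.names = FALSE)
    writeLines(c(
      sprintf("nucleodemark %s",
              as.character(utils::packageVersion("nucleodemark"))),
      sprintf("base_seed: %d", config$base_seed),
      sprintf("marker_mode: %s", config$marker_mode),
      sprintf("conditions: %s", paste(config$conditions, collapse = ", ")),
      sprintf("total nuclei: %d", sum(scenes_meta$n_nuclei))),
      file.path(out_dir, "run_log.txt"))
  }
  list(measurements = table, exclusions = excl, comparison = comparison,
       scenes_meta = scenes_meta)
}
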