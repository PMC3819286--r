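#' Normalize nucleolar measurements to the control condition
#'
#' Within each replicate (independent experiment) and channel, every
#' nucleolar mean intensity is divided by that replicate's control
#' mean-of-nucleolar-means, so the control averages to exactly 1 per
#' replicate. Renormalizing an already-normalized table is a no-op.
#'
#' @param table a measurement table (from [measure_segments()] /
#'   [qc_filter()]), possibly spanning several scenes, replicates and
#'   conditions.
#' @param control_condition name of the control condition.
#' @return the table with a `normalized` column added (or recomputed).
#' @export
normalize_to_control <- function(table, control_condition = "control") {
  if (!control_condition %in% table$condition) {
    stop("control condition '", control_condition,
         "' absent from the table", call. = FALSE)
  }
  value <- if ("normalized" %in% names(table)) table$normalized
           else table$mean_intensity
  table$.value <- value
  pairs <- dplyr::distinct(table, .data$replicate, .data$channel)
  ctrl <- dplyr::filter(table, .data$condition == control_condition)
  have <- dplyr::distinct(ctrl, .data$replicate, .data$channel)
  missing <- dplyr::anti_join(pairs, have, by = c("replicate", "channel"))
  if (nrow(missing)) {
    stop("no control measurements for replicate(s) ",
         paste(unique(missing$replicate), collapse = ", "),
         " (channel ", paste(unique(missing$channel), collapse = ", "),
         ")", call. = FALSE)
  }
  denom <- dplyr::summarise(
    dplyr::group_by(ctrl, .data$replicate, .data$channel),
    .denom = mean(.data$.value), .groups = "drop")
  out <- dplyr::left_join(table, denom, by = c("replicate", "channel"))
  out$normalized <- out$.value / out$.denom
  out$.value <- NULL
  out$.denom <- NULL
  out
}

#' Summarize conditions and test against control
#'
#' Aggregates normalized nucleolar intensities to replicate means (the
#' statistical unit, avoiding pseudoreplication across nucleoli of one
#' experiment), then reports per condition and channel the mean of replicate
#' means, the SEM across replicates, and a two-sided two-sample t-test of
#' the replicate means against the control's (Welch by default; set
#' `pooled = TRUE` for the classical equal-variance Student test).
#' Significance stars follow the usual convention: `"*"` for
#' 0.01 <= p < 0.05, `"**"` for p < 0.01, `""` otherwise.
#'
#' With `units = "nucleolus"` individual nucleoli are used as units instead
#' (not recommended; provided for comparison with per-cell protocols).
#'
#' @param table a normalized table from [normalize_to_control()].
#' @param control_condition name of the control condition.
#' @param units `"replicate"` (default) or `"nucleolus"`.
#' @param pooled use the pooled-variance Student t-test instead of Welch.
#' @param holm apply a Holm multiple-testing correction across conditions
#'   within each channel before assigning stars (off by default, matching
#'   per-comparison annotation).
#' @return a tibble of class `comparison_result`: `condition`, `channel`,
#'   `normalized_mean`, `sem`, `n_replicates`, `n_cells`, `n_nucleoli`,
#'   `t`, `df`, `p`, `annotation`. Conditions with fewer than two units get
#'   `sem = NA`, no test, and a warning.
#' @export
summarize_and_test <- function(table, control_condition = "control",
                               units = c("replicate", "nucleolus"),
                               pooled = FALSE, holm = FALSE) {
  units <- match.arg(units)
  if (!"normalized" %in% names(table)) {
    stop("table is not normalized; run normalize_to_control() first",
         call. = FALSE)
  }
  if (!control_condition %in% table$condition) {
    stop("control condition '", control_condition, "' absent", call. = FALSE)
  }
  unit_values <- function(tb) {
    if (units == "replicate") {
      agg <- dplyr::summarise(
        dplyr::group_by(tb, .data$replicate),
        v = mean(.data$normalized), .groups = "drop")
      agg$v
    } else tb$normalized
  }
  out <- list()
  for (chan in unique(table$channel)) {
    tb_c <- table[table$channel == chan, ]
    ctrl_v <- unit_values(tb_c[tb_c$condition == control_condition, ])
    for (cond in unique(tb_c$condition)) {
      tb <- tb_c[tb_c$condition == cond, ]
      v <- unit_values(tb)
      n <- length(v)
      sem <- if (n >= 2L) stats::sd(v) / sqrt(n) else {
        warning("condition '", cond, "' (", chan, ") has fewer than 2 ",
                "units; SEM undefined and test skipped", call. = FALSE)
        NA_real_
      }
      ht <- if (cond == control_condition || n < 2L ||
                length(ctrl_v) < 2L) {
        NULL
      } else {
        welch_or_flag(v, ctrl_v, pooled)
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        condition = cond, channel = chan,
        normalized_mean = mean(v), sem = sem, n_replicates = n,
        n_cells = dplyr::n_distinct(paste(tb$scene_id, tb$nucleus_label)),
        n_nucleoli = dplyr::n_distinct(paste(tb$scene_id,
                                             tb$nucleolus_label)),
        t = if (is.null(ht)) NA_real_ else unname(ht$statistic),
        df = if (is.null(ht)) NA_real_ else unname(ht$parameter),
        p = if (is.null(ht)) NA_real_ else ht$p.value)
    }
  }
  res <- dplyr::bind_rows(out)
  if (holm) {
    res <- dplyr::mutate(
      dplyr::group_by(res, .data$channel),
      p = ifelse(is.na(.data$p), NA,
                 stats::p.adjust(.data$p, method = "holm")))
    res <- dplyr::ungroup(res)
  }
  res$annotation <- significance_stars(res$p)
  class(res) <- c("comparison_result", class(res))
  res
}

# Welch/Student t-test robust to zero-variance groups (which arise by
# construction: control replicate means are exactly 1 after normalization).
welch_or_flag <- function(x, y, pooled) {
  tryCatch(
    stats::t.test(x, y, var.equal = pooled),
    error = function(e) {
      if (isTRUE(all.equal(mean(x), mean(y)))) {
        list(statistic = c(t = 0), parameter = c(df = length(x) +
                                                   length(y) - 2),
             p.value = 1)
      } else {
        list(statistic = c(t = sign(mean(x) - mean(y)) * Inf),
             parameter = c(df = length(x) + length(y) - 2), p.value = 0)
      }
    })
}

#' Significance star annotation
#'
#' `"*"` for 0.01 <= p < 0.05, `"**"` for p < 0.01, `""` otherwise
#' (including `NA`).
#'
#' @param p vector of p-values.
#' @return character vector of annotations.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Bar chart of normalized nucleolar intensities
#'
#' Mean + SEM per condition and channel with significance stars, the usual
#' presentation of normalized nucleolar measurements.
#'
#' @param result a `comparison_result` from [summarize_and_test()].
#' @return a ggplot object.
#' @export
plot_comparison <- function(result) {
  ggplot2::ggplot(result,
                  ggplot2::aes(x = .data$condition,
                               y = .data$normalized_mean)) +
    ggplot2::geom_col(fill = "grey65", colour = "black", width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$normalized_mean - .data$sem,
                   ymax = .data$normalized_mean + .data$sem),
      width = 0.2, na.rm = TRUE) +
    ggplot2::geom_text(
      ggplot2::aes(y = .data$normalized_mean +
                     ifelse(is.na(.data$sem), 0, .data$sem),
                   label = .data$annotation),
      vjust = -0.4, size = 6) +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(y = "normalized nucleolar intensity (mean + SEM)",
                  x = NULL) +
    ggplot2::theme_classic()
}
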