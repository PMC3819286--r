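test_that("segment measurement is exact on noise-free scenes", {
  sc <- render_scene(tiny_spec(seed = 5L))
  segs <- demarcate(sc, "light")
  tb <- measure_segments(segs, sc$channels[c("nucleolin", "CAS", "EU")])
  # mean x pixel count equals integrated intensity exactly
  expect_equal(tb$mean_intensity * tb$n_pixels, tb$integrated_intensity)
  # (scene, nucleolus, channel) rows are unique
  expect_false(any(duplicated(tb[c("scene_id", "nucleolus_label",
                                   "channel")])))
  # measured means on perfectly recovered segments equal planted means
  m <- evaluate_segmentation(segs, sc$truth)
  perfect <- m$matches[m$matches$iou == 1, ]
  expect_gt(nrow(perfect), 0)
  for (k in seq_len(nrow(perfect))) {
    for (ch in c("nucleolin", "CAS", "EU")) {
      planted <- sc$truth$planted_mean
      want <- planted$planted_mean[planted$channel == ch &
                                     planted$nucleolus == perfect$truth[k]]
      got <- tb$mean_intensity[tb$channel == ch &
                                 tb$nucleolus_label == perfect$pred[k]]
      expect_equal(got, want)
    }
  }
})

test_that("measured masked means cover the planted mean at the Gaussian rate", {
  spec <- scene_spec(field_shape = c(64L, 64L), n_nuclei = 1L,
                     nucleus_radius_range = c(3.5, 3.5),
                     nucleoli_per_nucleus_range = c(1L, 1L),
                     nucleolus_radius_range = c(1, 1),
                     noise_sigma = 300, seed = 1L)
  inside <- 0L
  n_runs <- 300L
  for (seed in seq_len(n_runs)) {
    spec$seed <- seed
    sc <- render_scene(spec)
    tb <- measure_segments(truth_as_segments(sc$truth),
                           sc$channels["nucleolin"])
    planted <- sc$truth$planted_mean
    want <- planted$planted_mean[planted$channel == "nucleolin"]
    tol <- 4 * 300 / sqrt(tb$n_pixels[1])
    if (abs(tb$mean_intensity[1] - want) <= tol) inside <- inside + 1L
  }
  expect_gte(inside / n_runs, 0.99)
})

test_that("QC drops border, size and count violations with logged reasons", {
  sc <- render_scene(tiny_spec(seed = 5L))
  segs <- demarcate(sc, "light")
  tb <- measure_segments(segs, sc$channels["nucleolin"])

  clean <- qc_filter(tb)
  expect_equal(clean[names(tb)], tb, ignore_attr = TRUE)
  expect_equal(nrow(qc_exclusions(clean)), 0L)

  # size bound below the largest segment removes exactly that segment
  big <- tb$nucleolus_label[which.max(tb$size_um)]
  cut <- sort(tb$size_um, decreasing = TRUE)[2]
  f1 <- qc_filter(tb, size_bounds = c(0.1, (cut + max(tb$size_um)) / 2))
  expect_false(big %in% f1$nucleolus_label)
  ex <- qc_exclusions(f1)
  expect_identical(ex$reason, "size")
  expect_identical(ex$nucleolus_label, big)
  # survivors are untouched
  expect_identical(f1, tb[tb$nucleolus_label != big, ],
                   ignore_attr = TRUE)

  # per-nucleus cap: nuclei with >1 nucleolus are dropped entirely
  counts <- table(tb$nucleus_label)
  many <- as.integer(names(counts)[counts > 1])
  if (length(many)) {
    f2 <- qc_filter(tb, max_per_nucleus = 1L)
    expect_false(any(f2$nucleus_label %in% many))
    expect_true(all(qc_exclusions(f2)$reason == "count"))
  }

  # a border-touching nucleus loses all its segments
  bspec <- tiny_spec(seed = 23L, border_margin_um = 0.5,
                     n_nuclei = 3L)
  bsc <- render_scene(bspec)
  expect_gt(length(bsc$truth$border_nuclei), 0)
  bsegs <- demarcate(bsc, "light")
  btb <- measure_segments(bsegs, bsc$channels["nucleolin"])
  fb <- qc_filter(btb)
  exb <- qc_exclusions(fb)
  border_parents <- attr(attr(bsegs, "nuclei"), "border_labels")
  expect_true(all(!fb$nucleus_label %in% border_parents))
  if (nrow(exb)) expect_true(all(exb$reason == "border"))
})

test_that("normalization to control behaves as a per-replicate ratio", {
  tb <- synthetic_table(c("control", "DRB"), n_reps = 3L, n_per = 20L,
                        mean_by_condition = list(control = 2000, DRB = 1000),
                        sd = 0)
  norm <- normalize_to_control(tb)
  ctrl <- norm[norm$condition == "control", ]
  agg <- tapply(ctrl$normalized, ctrl$replicate, mean)
  expect_equal(as.numeric(agg), rep(1, 3))
  expect_true(all(abs(norm$normalized[norm$condition == "DRB"] - 0.5) <
                    1e-12))

  # idempotence
  norm2 <- normalize_to_control(norm)
  expect_equal(norm2$normalized, norm$normalized)

  # missing control replicate is a pairing error naming the replicate
  broken <- tb[!(tb$condition == "control" & tb$replicate == 2L), ]
  expect_error(normalize_to_control(broken), "replicate")
  expect_error(normalize_to_control(tb, "heat"), "absent")
})

test_that("replicate-level testing matches a hand-computed Welch oracle", {
  tb <- synthetic_table(c("control", "DRB"), n_reps = 3L, n_per = 1L, sd = 0)
  tb$mean_intensity <- ifelse(tb$condition == "control", 1,
                              c(0.5, 0.6, 0.7)[tb$replicate])
  tb$normalized <- tb$mean_intensity
  res <- summarize_and_test(tb)
  drb <- res[res$condition == "DRB", ]
  # closed-form Welch: control {1,1,1} (variance 0), treated {.5,.6,.7}
  v2 <- stats::var(c(0.5, 0.6, 0.7))
  t_hand <- (0.6 - 1) / sqrt(v2 / 3)
  df_hand <- (v2 / 3)^2 / ((v2 / 3)^2 / 2)
  p_hand <- 2 * stats::pt(-abs(t_hand), df_hand)
  expect_equal(drb$t, t_hand, tolerance = 1e-12)
  expect_equal(drb$df, df_hand, tolerance = 1e-12)
  expect_equal(drb$p, p_hand, tolerance = 1e-12)
  expect_equal(drb$sem, stats::sd(c(0.5, 0.6, 0.7)) / sqrt(3))
  expect_identical(drb$annotation,
                   significance_stars(p_hand))
  ctrl <- res[res$condition == "control", ]
  expect_equal(ctrl$normalized_mean, 1)
  expect_identical(ctrl$annotation, "")
})

test_that("identical groups give t = 0, p = 1 and no stars", {
  tb <- synthetic_table(c("control", "DEM"), n_reps = 3L, n_per = 1L, sd = 0)
  tb$normalized <- rep(c(0.9, 1.0, 1.1), 2)[order(rep(1:2, each = 3))]
  tb$normalized <- ifelse(tb$condition == "control",
                          c(0.9, 1, 1.1)[tb$replicate],
                          c(0.9, 1, 1.1)[tb$replicate])
  res <- summarize_and_test(tb)
  dem <- res[res$condition == "DEM", ]
  expect_equal(dem$t, 0)
  expect_equal(dem$p, 1)
  expect_identical(dem$annotation, "")
})

test_that("star annotation follows the p-value rule exactly", {
  expect_identical(significance_stars(c(0.2, 0.05, 0.049, 0.011, 0.01,
                                        0.0099, 1e-6, NA)),
                   c("", "", "*", "*", "*", "**", "**", ""))
})

test_that("a condition with a single replicate is flagged, not tested", {
  tb <- synthetic_table(c("control", "DEM"), n_reps = 3L, n_per = 5L)
  tb <- tb[!(tb$condition == "DEM" & tb$replicate > 1L), ]
  tb <- normalize_to_control(tb)
  expect_warning(res <- summarize_and_test(tb), "fewer than 2")
  dem <- res[res$condition == "DEM", ]
  expect_true(is.na(dem$sem))
  expect_true(is.na(dem$p))
  expect_identical(dem$annotation, "")
})

test_that("normalized results are invariant to global intensity rescaling", {
  tb <- synthetic_table(c("control", "DRB"), n_reps = 3L, n_per = 15L,
                        mean_by_condition = list(control = 2000, DRB = 1200),
                        sd = 150, seed = 4L)
  r1 <- summarize_and_test(normalize_to_control(tb))
  tb2 <- tb
  tb2$mean_intensity <- tb2$mean_intensity * 7.3
  r2 <- summarize_and_test(normalize_to_control(tb2))
  expect_equal(r1$normalized_mean, r2$normalized_mean)
  expect_equal(r1$t, r2$t)
  expect_equal(r1$p, r2$p)
})

test_that("functional-channel measurement shares the segment machinery", {
  sc <- render_scene(tiny_spec(seed = 7L))
  segs <- demarcate(sc, "dark")
  tb <- measure_segments(segs, sc$channels["CAS"])
  tb2 <- measure_function_channel(segs, sc$channels$CAS, tb, name = "EUlike")
  a <- tb2[tb2$channel == "CAS", "mean_intensity"]
  b <- tb2[tb2$channel == "EUlike", "mean_intensity"]
  expect_equal(a$mean_intensity, b$mean_intensity)
})

test_that("planted nucleolar effects are recovered monotonically", {
  effects <- c(0.8, 0.6, 0.4, 0.2)
  recovered <- numeric(length(effects))
  base <- tiny_spec(seed = 1L, n_nuclei = 3L,
                    nucleoli_per_nucleus_range = c(1L, 2L))
  base$noise_sigma <- 150
  measure_one <- function(spec, cond, rep, eff) {
    spec$seed <- spec$seed + 1000L * rep
    spec$channels$EU$effect <- eff
    sc <- render_scene(spec)
    segs <- demarcate(sc, "dark")
    measure_segments(segs, sc$channels["EU"],
                     scene_id = sprintf("%s_%d", cond, rep),
                     replicate = rep, condition = cond)
  }
  for (i in seq_along(effects)) {
    rows <- list()
    for (r in 1:3) {
      treated <- base
      treated$seed <- base$seed + 7L + i
      rows[[length(rows) + 1L]] <- measure_one(base, "control", r, 1)
      rows[[length(rows) + 1L]] <- measure_one(treated, "DRB", r, effects[i])
    }
    tb <- normalize_to_control(dplyr::bind_rows(rows))
    res <- summarize_and_test(tb)
    recovered[i] <- res$normalized_mean[res$condition == "DRB"]
  }
  expect_true(all(diff(recovered) < 0))
  expect_true(all(abs(recovered - effects) / effects < 0.1))
})
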