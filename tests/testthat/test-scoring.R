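test_that("nucleus segmentation recovers planted nuclei almost exactly", {
  spec <- scene_spec(field_shape = c(192L, 192L), n_nuclei = 5L,
                     nucleus_radius_range = c(3.5, 4.5),
                     nucleoli_per_nucleus_range = c(1L, 2L),
                     nucleolus_radius_range = c(0.7, 1.2),
                     noise_sigma = 0, seed = 31L)
  sc <- render_scene(spec)
  nuc <- segment_nuclei(sc$channels$DAPI)
  expect_equal(max(nuc), 5L)
  # each found nucleus overlaps >= 99% with one planted nucleus
  for (l in 1:5) {
    pred <- which(nuc == l)
    truth_lab <- as.integer(names(which.max(
      table(sc$truth$nucleus_labels[pred]))))
    tr <- which(sc$truth$nucleus_labels == truth_lab)
    expect_gt(length(intersect(pred, tr)) / length(union(pred, tr)), 0.99)
  }
})

test_that("blank fields and vacuous thresholds give empty nucleus masks", {
  blank <- channel_image(matrix(100, 64, 64), 0.25, dtype = "16bit")
  expect_warning(nuc <- segment_nuclei(blank), "no nuclear foreground")
  expect_true(all(nuc == 0L))

  sc <- render_scene(tiny_spec(seed = 2L))
  expect_warning(nuc2 <- segment_nuclei(sc$channels$DAPI, threshold = 70000),
                 "no nuclear foreground")
  expect_true(all(nuc2 == 0L))
})

test_that("an all-zero holes image yields zero segments", {
  sc <- render_scene(tiny_spec(seed = 2L))
  nuc <- segment_nuclei(sc$channels$DAPI)
  h <- holes_image(array(0, dim(nuc)), "light", tiny_radius, 0.25)
  segs <- score_nucleoli(h, nuc)
  expect_length(segs$parent_of, 0)
  expect_true(all(segs$labels == 0L))
})

test_that("noise-free scoring recovers every planted nucleolus with IoU >= 0.7", {
  for (seed in c(4L, 14L)) {
    sc <- render_scene(tiny_spec(seed = seed))
    segs <- demarcate(sc, "light")
    expect_length(segs$parent_of, length(sc$truth$parent_of))
    m <- evaluate_segmentation(segs, sc$truth, iou_threshold = 0.7)
    expect_equal(m$recall, 1)
    expect_true(all(m$matches$iou >= 0.7))
  }
})

test_that("segments never leak outside their parent nucleus", {
  spec <- tiny_spec(seed = 6L)
  spec$noise_sigma <- 300
  sc <- render_scene(spec)
  segs <- demarcate(sc, "light")
  nuc <- attr(segs, "nuclei")
  for (l in seq_along(segs$parent_of)) {
    sel <- segs$labels == l
    expect_true(all(nuc[sel] == segs$parent_of[[as.character(l)]]))
  }
})

test_that("tightening constraints never increases the segment count", {
  spec <- tiny_spec(seed = 10L)
  spec$noise_sigma <- 250
  sc <- render_scene(spec)
  nuc <- segment_nuclei(sc$channels$DAPI)
  med <- median_denoise(detect_light_holes(sc$channels$nucleolin,
                                           tiny_radius), 1)
  n_min_area <- vapply(c(0.3, 0.8, 1.5, 3), function(a) {
    length(score_nucleoli(med, nuc, scoring_constraints(
      min_size = a))$parent_of)
  }, numeric(1))
  expect_true(all(diff(n_min_area) <= 0))
  n_floor <- vapply(c(0, 200, 1000, 3000), function(f) {
    length(score_nucleoli(med, nuc, scoring_constraints(
      min_intensity_above_background = f))$parent_of)
  }, numeric(1))
  expect_true(all(diff(n_floor) <= 0))
})

test_that("scoring is deterministic and validates its inputs", {
  sc <- render_scene(tiny_spec(seed = 12L))
  nuc <- segment_nuclei(sc$channels$DAPI)
  med <- median_denoise(detect_light_holes(sc$channels$nucleolin,
                                           tiny_radius), 1)
  s1 <- score_nucleoli(med, nuc)
  s2 <- score_nucleoli(med, nuc)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$stats, s2$stats)

  expect_error(scoring_constraints(min_size = 5, max_size = 2), "min_size")
  expect_error(scoring_constraints(background_annulus_width = 0), "annulus")
  small <- holes_image(matrix(0, 10, 10), "light", 1, 0.25)
  expect_error(score_nucleoli(small, nuc), "geometr")
})

test_that("add-based DRB scoring recovers nucleoli single markers miss", {
  # seeds chosen to contain planted misses for both markers
  hits <- 0L
  for (seed in c(21L, 33L)) {
    sc <- render_scene(tiny_spec(seed = seed, condition = "DRB",
                                 nucleoli_per_nucleus_range = c(2L, 3L)))
    mb <- sc$truth$missed_by
    miss_cas <- mb$nucleolus[mb$channel == "CAS" & mb$missed]
    m_cas <- evaluate_segmentation(demarcate(sc, "dark"), sc$truth)
    m_add <- evaluate_segmentation(demarcate(sc, "add"), sc$truth)
    # everything CAS finds, add finds too (counted via matched truth sets)
    expect_true(all(m_cas$matches$truth %in% m_add$matches$truth))
    recovered <- intersect(miss_cas, m_add$matches$truth)
    found_by_cas <- intersect(miss_cas, m_cas$matches$truth)
    expect_length(found_by_cas, 0)
    if (length(miss_cas) > 0 && length(recovered) > 0) hits <- hits + 1L
  }
  expect_gt(hits, 0L)
})

test_that("a single-slice stack scores identically to the 2D path", {
  sc <- render_scene(tiny_spec(seed = 5L))
  px <- sc$channels$nucleolin$pixels
  stack <- channel_image(array(px, dim = c(dim(px), 1L)), 0.25,
                         z_spacing = 0.3, polarity = "enriched",
                         name = "nucleolin")
  dapi3 <- channel_image(array(sc$channels$DAPI$pixels,
                               dim = c(dim(px), 1L)), 0.25, z_spacing = 0.3)
  cons2 <- scoring_constraints(min_size = 0.5, max_size = 80)
  cons3 <- scoring_constraints(min_size = 0.5 * 0.3, max_size = 80 * 0.3)
  segs2 <- score_nucleoli(
    median_denoise(detect_light_holes(sc$channels$nucleolin, tiny_radius), 1),
    segment_nuclei(sc$channels$DAPI), cons2)
  segs3 <- score_nucleoli_3d(
    median_denoise(detect_light_holes(stack, tiny_radius), 1),
    segment_nuclei(dapi3, min_size = 30 * 0.3), cons3)
  expect_identical(as.integer(segs3$labels[, , 1]), as.integer(segs2$labels))
  expect_identical(segs3$parent_of, segs2$parent_of)
})

test_that("3D scoring recovers a spherical nucleolus volume", {
  spec <- scene_spec(field_shape = c(72L, 72L, 24L), pixel_size = 0.25,
                     z_spacing = 0.3, n_nuclei = 1L,
                     nucleus_radius_range = c(4.5, 4.5),
                     nucleoli_per_nucleus_range = c(1L, 1L),
                     nucleolus_radius_range = c(1.5, 1.5),
                     nucleus_z_ratio = 0.55, noise_sigma = 0, seed = 3L)
  sc <- render_scene(spec)
  med <- median_denoise(detect_dark_holes(sc$channels$CAS, 1.25 * 1.5), 1)
  nuc <- segment_nuclei(sc$channels$DAPI)
  segs <- score_nucleoli_3d(med, nuc)
  expect_length(segs$parent_of, 1L)
  analytic <- 4 / 3 * pi * 1.5^3
  expect_lt(abs(segs$stats$size_um[1] - analytic) / analytic, 0.15)

  expect_error(score_nucleoli_3d(
    median_denoise(detect_light_holes(sc$channels$nucleolin, 2), 1),
    nuc, threshold = NULL, constraints = scoring_constraints(),
    provenance = list()), NA)
  expect_error(score_nucleoli(med, nuc), "2D")
})

test_that("anisotropic and finer-sliced renderings agree on segment count", {
  base <- scene_spec(field_shape = c(64L, 64L, 24L), pixel_size = 0.25,
                     z_spacing = 0.3, n_nuclei = 1L,
                     nucleus_radius_range = c(4.5, 4.5),
                     nucleoli_per_nucleus_range = c(2L, 2L),
                     nucleolus_radius_range = c(1, 1.3),
                     nucleus_z_ratio = 0.55, noise_sigma = 0, seed = 8L)
  fine <- base
  fine$field_shape <- c(64L, 64L, 48L)
  fine$z_spacing <- 0.15   # same 7.2 µm physical depth
  n_base <- length(demarcate(render_scene(base), "light")$parent_of)
  n_fine <- length(demarcate(render_scene(fine), "light")$parent_of)
  expect_equal(n_base, n_fine)
})

test_that("evaluation metrics are exact on self-comparison and label-invariant", {
  sc <- render_scene(tiny_spec(seed = 4L))
  tr <- sc$truth
  m <- evaluate_segmentation(tr$nucleolus_labels, tr)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$mean_matched_iou, 1)

  empty <- array(0L, dim(tr$nucleolus_labels))
  me <- evaluate_segmentation(empty, tr)
  expect_equal(me$recall, 0)
  expect_equal(me$precision, 0)
  expect_false(me$precision_defined)
  expect_equal(nrow(me$missed), length(tr$parent_of))

  # permuting prediction labels changes nothing
  n <- max(tr$nucleolus_labels)
  withr::with_seed(9, perm <- sample(n))
  shuffled <- array(0L, dim(tr$nucleolus_labels))
  nz <- tr$nucleolus_labels > 0
  shuffled[nz] <- perm[tr$nucleolus_labels[nz]]
  mp <- evaluate_segmentation(shuffled, tr)
  expect_equal(mp$recall, m$recall)
  expect_equal(mp$precision, m$precision)
  expect_equal(mp$mean_matched_iou, m$mean_matched_iou)
})
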