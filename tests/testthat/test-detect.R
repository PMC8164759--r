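crafted_cell <- function(area = 50, aspect = 1, edge = FALSE, od = 0.8) {
  data.frame(
    label = 1L, x = 50, y = 50, n_px = 100L, area_um2 = area,
    major_axis_um = 8 * sqrt(aspect), minor_axis_um = 8 / sqrt(aspect),
    aspect_ratio = aspect, mean_stain_od = od, touches_edge = edge,
    solidity = 1
  )
}

verdict_of <- function(cell, crit = detection_criteria()) {
  as.character(apply_exclusion_rules(cell, crit, intensity_threshold = 0.35)$verdict)
}

test_that("a blank field yields no candidates and an auto_ok flag", {
  sim <- generate_field_image(small_field_params(
    seed = 2, n_positive = 0L, n_large_distractors = 0L,
    n_elongated_distractors = 0L, n_faint_distractors = 0L,
    n_edge_cells = 0L, n_melanin_granules = 0L
  ))
  fc <- count_field(sim$image)
  expect_equal(fc$n_accepted, 0L)
  expect_equal(fc$n_candidates, 0L)
  expect_equal(fc$qc_flag, "auto_ok")
})

test_that("candidate detection recovers every planted object", {
  p <- small_field_params(
    seed = 17, n_positive = 50L, n_large_distractors = 0L,
    n_elongated_distractors = 0L, n_faint_distractors = 0L,
    n_edge_cells = 0L, n_melanin_granules = 0L
  )
  sim <- generate_field_image(p)
  crit <- detection_criteria()
  ch <- separate_stain_channels(sim$image)
  cells <- detect_candidates(ch, NULL, crit, 0.44)
  expect_equal(nrow(cells), 50L)
})

test_that("exclusion rules fire on the documented boundaries", {
  # aspect ratio is a strict cutoff: exactly 2.0 passes, above fails
  expect_equal(verdict_of(crafted_cell(aspect = 2.5)), "rejected_aspect")
  expect_equal(verdict_of(crafted_cell(aspect = 2.0)), "accepted")
  expect_equal(verdict_of(crafted_cell(aspect = 2.0 + 1e-9)), "rejected_aspect")
  # a circular, well-stained, interior cell is accepted
  expect_equal(verdict_of(crafted_cell()), "accepted")
  # size window boundaries flip the verdict
  crit <- detection_criteria(min_area_um2 = 10, max_area_um2 = 120)
  expect_equal(verdict_of(crafted_cell(area = 10), crit), "accepted")
  expect_equal(verdict_of(crafted_cell(area = 9.999), crit), "rejected_size")
  expect_equal(verdict_of(crafted_cell(area = 120), crit), "accepted")
  expect_equal(verdict_of(crafted_cell(area = 120.001), crit), "rejected_size")
  # edge contact and intensity
  expect_equal(verdict_of(crafted_cell(edge = TRUE)), "rejected_edge")
  expect_equal(verdict_of(crafted_cell(od = 0.2)), "rejected_intensity")
  # fixed rule order: size outranks aspect, aspect outranks edge
  expect_equal(verdict_of(crafted_cell(area = 500, aspect = 3)), "rejected_size")
  expect_equal(verdict_of(crafted_cell(aspect = 3, edge = TRUE)), "rejected_aspect")
})

test_that("an object with a pixel on the image border is rejected as edge", {
  px <- array(0.95, dim = c(60, 80, 3))
  # strong square with its topmost pixels on row 1
  px[1:14, 30:43, 1] <- 0.18; px[1:14, 30:43, 2] <- 0.17; px[1:14, 30:43, 3] <- 0.19
  img <- field_image(px, pixel_size_um = 0.6)
  fc <- count_field(img)
  expect_equal(as.character(fc$cells$verdict), "rejected_edge")
})

test_that("every candidate receives exactly one verdict and counts reconcile", {
  for (s in c(23, 31, 44)) {
    sim <- generate_field_image(small_field_params(seed = s))
    fc <- count_field(sim$image)
    expect_false(any(is.na(fc$cells$verdict)))
    expect_equal(
      fc$n_accepted + sum(fc$n_rejected_by_reason),
      fc$n_candidates
    )
  }
})

test_that("loosening criteria is monotone in the accepted count", {
  sim <- generate_field_image(small_field_params(seed = 29))
  ch <- separate_stain_channels(sim$image)
  retained <- melanin_rejection_filter(sim$image, detection_criteria())
  cells <- detect_candidates(ch, retained, detection_criteria(), 0.44)
  n_at <- function(crit) {
    sum(apply_exclusion_rules(cells, crit)$verdict == "accepted")
  }
  ratios <- c(1, 1.5, 2, 3, 10)
  ns <- vapply(ratios, function(r) n_at(detection_criteria(max_aspect_ratio = r)),
               numeric(1))
  expect_true(all(diff(ns) >= 0))
  wide <- n_at(detection_criteria(min_area_um2 = 5, max_area_um2 = 300))
  narrow <- n_at(detection_criteria(min_area_um2 = 20, max_area_um2 = 80))
  expect_lte(narrow, wide)
})

test_that("physical measurements scale with the pixel size", {
  p <- small_field_params(
    seed = 35, n_positive = 10L, n_large_distractors = 0L,
    n_elongated_distractors = 0L, n_faint_distractors = 0L,
    n_edge_cells = 0L, n_melanin_granules = 0L
  )
  sim <- generate_field_image(p)
  crit <- detection_criteria()
  ch <- separate_stain_channels(sim$image)
  c1 <- detect_candidates(ch, NULL, crit, 0.44)
  c2 <- detect_candidates(ch, NULL, crit, 0.88)
  expect_equal(c2$major_axis_um, 2 * c1$major_axis_um)
  expect_equal(c2$area_um2, 4 * c1$area_um2)
  expect_equal(c2$aspect_ratio, c1$aspect_ratio)
})

test_that("merged nuclei reduce the candidate count and trip the QC flag", {
  p <- small_field_params(
    seed = 19, n_positive = 10L, overlap_fraction = 1,
    n_large_distractors = 0L, n_elongated_distractors = 0L,
    n_faint_distractors = 0L, n_edge_cells = 0L, n_melanin_granules = 0L
  )
  sim <- generate_field_image(p)
  fc <- count_field(sim$image)
  expect_lt(nrow(fc$cells), 10L)
  expect_equal(fc$qc_flag, "needs_manual_review")
})

test_that("over-selection by the software is flagged for manual review", {
  # many faint objects and few genuine cells: candidates >> accepted
  sim <- generate_field_image(small_field_params(
    seed = 26, n_positive = 2L, n_faint_distractors = 12L,
    n_large_distractors = 0L, n_elongated_distractors = 0L,
    n_edge_cells = 0L, n_melanin_granules = 0L
  ))
  fc <- count_field(sim$image)
  expect_equal(fc$n_accepted, 2L)
  expect_equal(fc$qc_flag, "needs_manual_review")
})
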