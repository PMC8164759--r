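test_that("same seed reproduces identical pixels and annotations", {
  p <- small_field_params(seed = 7, n_positive = 8L, n_melanin_granules = 10L)
  a <- generate_field_image(p)
  b <- generate_field_image(p)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$objects, b$truth$objects)
  expect_identical(a$truth$label_mask, b$truth$label_mask)
})

test_that("an empty parameter set yields an empty field", {
  p <- small_field_params(
    seed = 1, n_positive = 0L, n_large_distractors = 0L,
    n_elongated_distractors = 0L, n_faint_distractors = 0L,
    n_edge_cells = 0L, n_melanin_granules = 0L
  )
  sim <- generate_field_image(p)
  expect_equal(nrow(sim$truth$objects), 0L)
  expect_true(all(sim$truth$label_mask == 0L))
})

test_that("planted positives give exactly that many connected components", {
  p <- small_field_params(
    seed = 11, n_positive = 50L, n_large_distractors = 0L,
    n_elongated_distractors = 0L, n_faint_distractors = 0L,
    n_edge_cells = 0L, n_melanin_granules = 0L
  )
  sim <- generate_field_image(p)
  expect_equal(flood_fill_components(sim$truth$label_mask > 0L), 50L)
  # labels are distinct per object
  expect_equal(sort(unique(as.vector(sim$truth$label_mask[sim$truth$label_mask > 0]))),
               1:50)
})

test_that("default geometry matches the reference acquisition", {
  p <- image_sim_params()
  expect_equal(p$pixel_size_um, 0.11)
  expect_equal(p$width_px, 2560L)
  expect_equal(p$height_px, 1920L)
})

test_that("overcrowded fields are rejected rather than placed with overlap", {
  p <- image_sim_params(
    width_px = 120L, height_px = 120L, pixel_size_um = 0.44,
    n_positive = 80L, n_large_distractors = 0L, n_elongated_distractors = 0L,
    n_faint_distractors = 0L, n_edge_cells = 0L, n_melanin_granules = 0L,
    seed = 3
  )
  expect_error(generate_field_image(p), "overcrowded")
})

test_that("invalid simulation parameters are refused", {
  expect_error(image_sim_params(n_positive = -1), "non-negative")
  expect_error(image_sim_params(pixel_size_um = 0), "positive")
  expect_error(image_sim_params(background_noise_sd = -0.1), "non-negative")
})

test_that("ground truth is faithful to the acceptance predicate by construction", {
  crit <- detection_criteria("dab_ni_no_counterstain")
  for (s in c(2, 21, 57)) {
    sim <- generate_field_image(small_field_params(seed = s))
    obj <- sim$truth$objects
    ps <- sim$image$pixel_size_um
    area <- pi / 4 * obj$major_axis_px * obj$minor_axis_px * ps^2
    aspect <- obj$major_axis_px / obj$minor_axis_px
    size_ok <- area >= crit$min_area_um2 & area <= crit$max_area_um2
    aspect_ok <- aspect <= crit$max_aspect_ratio
    intense <- obj$mean_stain_od >= crit$od_floor

    pos <- obj$class == "positive"
    expect_true(all(size_ok[pos] & aspect_ok[pos] & intense[pos]))
    # each distractor violates exactly the criterion its class names
    expect_true(all(area[obj$class == "too_large"] > crit$max_area_um2))
    expect_true(all(aspect_ok[obj$class == "too_large"] &
                      intense[obj$class == "too_large"]))
    expect_true(all(aspect[obj$class == "elongated"] > crit$max_aspect_ratio))
    expect_true(all(size_ok[obj$class == "elongated"] &
                      intense[obj$class == "elongated"]))
    expect_true(all(!intense[obj$class == "faint"]))
    expect_true(all(size_ok[obj$class == "faint"] & aspect_ok[obj$class == "faint"]))
    expect_true(all(size_ok[obj$class == "melanin"] &
                      aspect_ok[obj$class == "melanin"] &
                      intense[obj$class == "melanin"]))
  }
})

test_that("field images and label masks round-trip through TIFF", {
  sim <- generate_field_image(small_field_params(
    seed = 5, n_positive = 3L, n_melanin_granules = 0L,
    n_large_distractors = 0L, n_elongated_distractors = 0L,
    n_faint_distractors = 0L, n_edge_cells = 0L,
    background_noise_sd = 0
  ))
  path <- file.path(tempdir(), "field.tif")
  write_field_image(sim$image, path, label_mask = sim$truth$label_mask)
  back <- read_field_image(path, pixel_size_um = 0.44)
  # 8-bit quantization: within one grey level
  expect_lt(max(abs(back$pixels - sim$image$pixels)), 1 / 255 + 1e-9)
  mask <- tiff::readTIFF(file.path(tempdir(), "field_labels.tif"))
  expect_equal(round(mask * 65535), sim$truth$label_mask, ignore_attr = TRUE)
  unlink(c(path, file.path(tempdir(), "field_labels.tif")))
})
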