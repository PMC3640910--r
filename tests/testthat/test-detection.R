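test_that("two disjoint disks are detected with pixel-accurate areas", {
  fx <- make_nucleus_image(48, 20, disks = rbind(c(14, 23.5, 3), c(32, 23.5, 3)))
  params <- detect_params(threshold = "fixed", fixed_level = 110,
                          calibration = 0.25)
  rec <- detect_agnors(fx$image, fx$mask, params)
  expect_equal(nrow(rec$particles), 2L)
  true_area <- pi * 0.75^2  # r = 3 px at 0.25 um/px
  expect_true(all(abs(rec$particles$area_um2 - true_area) / true_area <= 0.15))
  # pixel-count oracle: component areas sum to the thresholded pixel count
  n_dark <- sum(fx$image[fx$mask] <= 110)
  expect_equal(sum(rec$particles$area_um2), n_dark * 0.25^2)
  # both corrected counts are 1 (similar sizes, no conglomerate)
  expect_identical(rec$particles$corrected_count, c(1L, 1L))
})

test_that("a nucleus with no sub-threshold pixels yields an empty particle list", {
  fx <- make_nucleus_image(40, 16)
  params <- detect_params(threshold = "fixed", fixed_level = 110,
                          calibration = 0.25)
  rec <- detect_agnors(fx$image, fx$mask, params)
  expect_equal(nrow(rec$particles), 0L)
})

test_that("Otsu with a contrast guard ignores particle-free noisy nuclei", {
  fx <- make_nucleus_image(40, 16)
  set.seed(1)
  noisy <- fx$image + matrix(round(rnorm(1600, 0, 2)), 40, 40)
  storage.mode(noisy) <- "integer"
  rec <- detect_agnors(noisy, fx$mask, detect_params(calibration = 0.25))
  expect_equal(nrow(rec$particles), 0L)
  # ... but still finds real dots in the same noise
  dotted <- paint_disk(noisy, 19.5, 19.5, 3, 60, 160)
  rec2 <- detect_agnors(dotted, fx$mask, detect_params(calibration = 0.25))
  expect_equal(nrow(rec2$particles), 1L)
})

test_that("merged disks are flagged as a conglomerate and counted by area ratio", {
  # three lone reference disks + one pair at centre spacing 1.2 r
  r <- 3
  fx <- make_nucleus_image(64, 28, disks = rbind(
    c(16, 16, r), c(16, 44, r), c(44, 16, r),
    c(44, 40, r), c(44, 40 + 1.2 * r, r)))
  params <- detect_params(threshold = "fixed", fixed_level = 110,
                          calibration = 0.25)
  rec <- detect_agnors(fx$image, fx$mask, params)
  expect_equal(nrow(rec$particles), 4L)  # the pair merged into one component
  expect_identical(rec$particles$is_conglomerate, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(rec$particles$corrected_count[1], 2L)
  lone <- pi * r^2 * 0.25^2
  expect_gt(rec$particles$area_um2[1], 1.5 * lone)
  expect_lt(rec$particles$area_um2[1], 2 * lone)
})

test_that("count correction follows the area-ratio rule", {
  expect_identical(correct_count(1, 1), 1L)
  expect_identical(correct_count(1.5, 1), 1L)     # boundary: <= kappa * ref
  expect_identical(correct_count(2.2, 1), 2L)     # round half up of 2.2
  expect_identical(correct_count(0.4, 1), 1L)     # small particles never zero
  expect_identical(correct_count(1.6, 1), 2L)     # floor at 2 above kappa
  expect_identical(correct_count(3.5, 1), 4L)     # half rounds up
  expect_error(correct_count(-1, 1), "positive")
  expect_error(correct_count(1, 0), "positive")
})

test_that("reference area is the conglomerate-excluded median", {
  expect_equal(estimate_reference_area(rep(2.5, 5)), 2.5)
  expect_equal(estimate_reference_area(c(1, 1, 1, 3)), 1)
  expect_equal(estimate_reference_area(4.2), 4.2)
  expect_error(estimate_reference_area(numeric(0)), "no particles")
  expect_error(estimate_reference_area(c(1, -2)), "positive")
})

test_that("degenerate inputs raise explicit errors", {
  fx <- make_nucleus_image(40, 16)
  params <- detect_params(calibration = 0.25)
  expect_error(detect_agnors(fx$image, matrix(FALSE, 40, 40), params), "empty")
  expect_error(detect_agnors(fx$image, matrix(TRUE, 20, 20), params),
               "dimensions differ")
  expect_error(detect_params(kappa = 1))
  expect_error(detect_params(threshold = "fixed"), "fixed_level")
  expect_error(detect_params(min_area_um2 = 0.001), "one pixel")
})

test_that("detection is invariant to image translation and nucleus relabeling", {
  fs <- generate_image_set(disjoint_scenario(4), seed = 13)
  params <- detect_params(calibration = fs$calibration)
  base <- detect_case(fs$image, fs$mask, params)

  # translate the whole field by (5, 7) pixels
  H <- nrow(fs$image); W <- ncol(fs$image)
  img2 <- matrix(fs$scenario$background_intensity, H + 5, W + 7)
  msk2 <- matrix(0L, H + 5, W + 7)
  img2[6:(H + 5), 8:(W + 7)] <- fs$image
  msk2[6:(H + 5), 8:(W + 7)] <- fs$mask
  storage.mode(img2) <- "integer"
  shifted <- detect_case(img2, msk2, params)
  for (k in seq_along(base$records)) {
    b <- base$records[[k]]$particles
    s <- shifted$records[[k]]$particles
    expect_equal(s$area_um2, b$area_um2)
    expect_equal(s$d_norm, b$d_norm, tolerance = 1e-6)
    expect_equal(s$x_um - b$x_um, rep(7 * 0.25, nrow(b)))
  }

  # relabel nuclei: permuting ids permutes records but not their content
  perm <- c(3L, 1L, 4L, 2L)
  msk3 <- fs$mask
  msk3[fs$mask > 0] <- perm[fs$mask[fs$mask > 0]]
  relab <- detect_case(fs$image, msk3, params)
  for (k in seq_along(base$records)) {
    b <- base$records[[k]]
    r <- relab$records[[which(vapply(relab$records, `[[`, 0L, "nucleus_id") == perm[k])]]
    expect_equal(r$particles$area_um2, b$particles$area_um2)
    expect_equal(r$particles$corrected_count, b$particles$corrected_count)
  }
})

test_that("particles are sorted by descending area with (y, x) tie-break", {
  fx <- make_nucleus_image(64, 28, disks = rbind(
    c(20, 20, 2), c(44, 20, 4), c(20, 44, 2)))
  rec <- detect_agnors(fx$image, fx$mask,
                       detect_params(threshold = "fixed", fixed_level = 110,
                                     calibration = 0.25))
  a <- rec$particles$area_um2
  expect_true(all(diff(a) <= 0))
  ties <- which(abs(a - a[2]) < 1e-12)
  expect_length(ties, 2L)
  y <- rec$particles$y_um[ties]; x <- rec$particles$x_um[ties]
  expect_true(y[1] < y[2] || (y[1] == y[2] && x[1] <= x[2]))
})
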