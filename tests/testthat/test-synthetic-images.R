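test_that("noise-free construction yields the exact ground-truth count", {
  sc <- image_scenario(n_nuclei = 10,
                       agnor_count_distribution = c(0, 0, 0, 1, rep(0, 9)),
                       conglomerate_probability = 0, noise_sd = 0)
  fs <- generate_image_set(sc, seed = 42)
  expect_true(all(fs$nuclei$true_count == 3L))
  expect_equal(nrow(fs$ground_truth), 30L)
  gtf <- features_from_ground_truth(fs)
  expect_identical(gtf$nornbc_m, 3)
  expect_identical(gtf$nor_k3, 100)
})

test_that("identical (scenario, seed) produce identical images, masks and files", {
  sc <- scenario_preset("low_variability", n_nuclei = 6)
  a <- generate_image_set(sc, seed = 7)
  b <- generate_image_set(sc, seed = 7)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$ground_truth, b$ground_truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_image_set(a, d1)
  p2 <- write_image_set(b, d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  rt <- read_image_pair(p1[["image"]], p1[["mask"]])
  expect_identical(rt$image, a$image)
  expect_identical(rt$mask, a$mask)
})

test_that("every ground-truth particle lies strictly inside its nucleus mask", {
  for (preset in c("low_variability", "high_variability")) {
    fs <- generate_image_set(scenario_preset(preset, n_nuclei = 12), seed = 3)
    gt <- fs$ground_truth
    cal <- fs$calibration
    lab <- fs$mask[cbind(round(gt$y_um / cal) + 1, round(gt$x_um / cal) + 1)]
    expect_identical(lab, gt$nucleus_id)
    expect_true(all(gt$d_norm >= 0 & gt$d_norm < 1))
  }
})

test_that("ground-truth particle count >= connected components in the rendering", {
  fs <- generate_image_set(scenario_preset("high_variability", n_nuclei = 15),
                           seed = 9)
  det <- detect_case(fs$image, fs$mask,
                     detect_params(calibration = fs$calibration))
  for (r in det$records) {
    truth <- fs$nuclei$true_count[fs$nuclei$nucleus_id == r$nucleus_id]
    expect_gte(truth, nrow(r$particles))
  }
})

test_that("rendered pixel areas match true disk areas within discretization error", {
  fs <- generate_image_set(disjoint_scenario(12), seed = 5)
  det <- detect_case(fs$image, fs$mask,
                     detect_params(threshold = "fixed", fixed_level = 110,
                                   calibration = fs$calibration))
  gt <- fs$ground_truth
  for (r in det$records) {
    g <- gt[gt$nucleus_id == r$nucleus_id, ]
    expect_equal(nrow(r$particles), nrow(g))
    true_sorted <- sort(g$area_um2, decreasing = TRUE)
    det_sorted <- sort(r$particles$area_um2, decreasing = TRUE)
    r_px <- sqrt(true_sorted / pi) / fs$calibration
    rel_err <- abs(det_sorted - true_sorted) / true_sorted
    expect_true(all(rel_err <= 2 / r_px))
  }
})

test_that("high-variability fields disperse size and position more than low ones", {
  n_seeds <- 100
  wins_snar <- 0L
  wins_locat <- 0L
  lo_sc <- scenario_preset("low_variability", n_nuclei = 25)
  hi_sc <- scenario_preset("high_variability", n_nuclei = 25)
  for (s in seq_len(n_seeds)) {
    lo <- features_from_ground_truth(
      generate_image_set(lo_sc, seed = s, render = FALSE))
    hi <- features_from_ground_truth(
      generate_image_set(hi_sc, seed = 10000 + s, render = FALSE))
    if (hi$snar_r_v > lo$snar_r_v) wins_snar <- wins_snar + 1L
    if (hi$locat_v > lo$locat_v) wins_locat <- wins_locat + 1L
  }
  expect_gte(wins_snar, 95L)
  expect_gte(wins_locat, 95L)
})

test_that("a field too small for its nuclei fails loudly, adequate fields work", {
  sc <- scenario_preset("low_variability", n_nuclei = 10)
  expect_error(generate_image_set(sc, seed = 1, field_px = c(40, 40)),
               "too small")
  fs <- generate_image_set(scenario_preset("low_variability", n_nuclei = 3),
                           seed = 1, field_px = c(220, 220))
  expect_equal(length(unique(fs$mask[fs$mask > 0])), 3L)
})

test_that("scenario invariants are enforced", {
  expect_error(image_scenario(particle_intensity = 200, nucleus_intensity = 160),
               "dark dots")
  expect_error(image_scenario(conglomerate_probability = 1.5))
  expect_error(image_scenario(radial_position_distribution =
                                list(type = "uniform", min = -0.2, max = 0.5)))
  expect_error(scenario_preset("nope"))
})
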