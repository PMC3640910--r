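test_that("per-nucleus summaries follow from direct arithmetic", {
  z <- zone_definition(0.5, 0.8)

  one <- nucleus_features(make_record(2.3, 0.4), z)
  expect_equal(one$largest_ratio_pm, 1000)
  expect_equal(one$snar_sd, 0)
  expect_equal(one$corrected_count, 1L)

  two <- nucleus_features(make_record(c(1.7, 1.7), c(0.1, 0.9)), z)
  expect_equal(two$largest_ratio_pm, 500)
  expect_equal(two$snar_sd, 0)
  expect_equal(two$prop_central, 0.5)
  expect_equal(two$prop_peripheral, 0.5)
  expect_equal(sum(two$area_fractions_pm), 1000)

  none <- nucleus_features(make_record(numeric(0), numeric(0)), z)
  expect_equal(none$corrected_count, 0L)
  expect_true(is.na(none$snar_sd) && is.na(none$largest_ratio_pm))
})

test_that("case aggregation reproduces hand-computed values", {
  z <- zone_definition()
  rows <- lapply(1:10, function(i) make_record(1, 0.3, nucleus_id = i))
  cf <- case_features(rows, z)
  expect_equal(cf$nor_k1, 100)
  expect_equal(sum(cf[paste0("nor_k", c(0, 2:8))]), 0)
  expect_equal(cf$nornbc_m, 1)
  expect_equal(cf$mnrat2_m, 1000)
  expect_equal(cf$snar_r_v, 0)

  rows2 <- list(make_record(1, 0.2, 1L, 1), make_record(1, 0.2, 1L, 2),
                make_record(c(1, 1), c(0.2, 0.3), nucleus_id = 3),
                make_record(c(1, 1), c(0.2, 0.3), nucleus_id = 4))
  cf2 <- case_features(rows2, z)
  expect_equal(cf2$nor_k1, 50)
  expect_equal(cf2$nor_k2, 50)
  expect_equal(cf2$nornbc_m, 1.5)

  expect_error(case_features(list()), "no nuclei")
})

test_that("zero-particle nuclei enter the count classes but not area aggregates", {
  rows <- list(make_record(c(2, 2), c(0.1, 0.9)),
               make_record(numeric(0), numeric(0), nucleus_id = 2))
  cf <- case_features(rows)
  expect_equal(cf$nor_k0, 50)
  expect_equal(cf$nor_k2, 50)
  expect_equal(cf$nornbc_m, 1)
  expect_equal(cf$mnrat2_m, 500)   # only the populated nucleus contributes
  all0 <- case_features(list(make_record(numeric(0), numeric(0))))
  expect_equal(all0$nor_k0, 100)
  expect_true(is.na(all0$mnrat2_m))
})

test_that("count-class percentages sum to 100 and dispersions are nonnegative", {
  sc <- scenario_preset("low_variability", n_nuclei = 15)
  for (s in 1:5) {
    fs <- generate_image_set(sc, seed = 50 + s, render = FALSE)
    cf <- features_from_ground_truth(fs)
    expect_equal(sum(cf[paste0("nor_k", 0:8)]), 100, tolerance = 0.01)
    expect_true(all(cf[c("snar_r_v", "cent_r_v", "bord_r_v", "locat_v",
                         "center_v")] >= 0))
  }
})

test_that("feature aggregation matches a brute-force ground-truth oracle", {
  for (s in 1:50) {
    preset <- if (s %% 2) "low_variability" else "high_variability"
    fs <- generate_image_set(scenario_preset(preset, n_nuclei = 6),
                             seed = 200 + s, render = FALSE)
    got <- features_from_ground_truth(fs)
    want <- oracle_features_from_gt(fs$ground_truth, fs$nuclei)
    expect_equal(got$nornbc_m, want$nornbc_m)
    expect_equal(as.numeric(got[paste0("nor_k", 0:8)]), want$nor_k)
    if (!is.na(got$snar_r_v)) {
      expect_equal(got$snar_r_v, want$snar_r_v, tolerance = 1e-12)
      expect_equal(got$mnrat2_m, want$mnrat2_m, tolerance = 1e-12)
      expect_equal(got$cent_r_v, want$cent_r_v, tolerance = 1e-12)
      expect_equal(got$bord_r_v, want$bord_r_v, tolerance = 1e-12)
      expect_equal(got$locat_v, want$locat_v, tolerance = 1e-12)
      expect_equal(got$center_v, want$center_v, tolerance = 1e-12)
    }
  }
})

test_that("corrected counts never fall below raw component counts", {
  for (s in 1:10) {
    fs <- generate_image_set(scenario_preset("high_variability", n_nuclei = 8),
                             seed = 300 + s)
    det <- detect_case(fs$image, fs$mask,
                       detect_params(calibration = fs$calibration))
    raw_mean <- mean(vapply(det$records, function(r) nrow(r$particles), 0L))
    cf <- case_features(det)
    expect_gte(cf$nornbc_m, raw_mean)
  }
})

test_that("zone definitions are validated", {
  expect_error(zone_definition(0.8, 0.5))
  expect_error(zone_definition(0, 0.8))
  expect_error(zone_definition(0.5, 1))
})
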