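make_cohort <- function(time, status, cause = NULL) {
  if (is.null(cause)) cause <- ifelse(status == 1, "breast_cancer", "none")
  data.frame(case_id = seq_along(time), time_months = time, event = status,
             cause = cause)
}

test_that("product-limit estimator matches hand calculation and edge cases", {
  km <- km_estimate(make_cohort(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  km0 <- km_estimate(make_cohort(c(2, 5, 7), c(0, 0, 0)))
  expect_true(all(km0$survival == 1))

  expect_error(km_estimate(make_cohort(c(-1, 2), c(1, 1))), "non-negative")
})

test_that("KM equals a brute-force risk-set enumeration on random cohorts", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:15, 1)
    time <- sample(1:8, n, replace = TRUE)  # ties on purpose
    status <- rbinom(n, 1, 0.6)
    km <- km_estimate(make_cohort(time, status))
    oracle <- km_oracle(time, status)
    m <- merge(as.data.frame(km)[, c("time", "survival")], oracle, by = "time")
    expect_equal(m$survival.x, m$survival.y, tolerance = 1e-12)
  }
})

test_that("cox_fit validates its inputs with named errors", {
  coh <- make_cohort(rexp(50, 0.1), rbinom(50, 1, 0.5))
  coh$flat <- 0
  coh$ok <- rnorm(50)
  expect_error(cox_fit(coh, "flat"), "'flat' is constant")
  dead <- make_cohort(rexp(50, 0.1), rep(0, 50))
  dead$x <- rnorm(50)
  expect_error(cox_fit(dead, "x"), "fewer than 2 events")
  expect_error(cox_fit(coh, "not_there"), "lacks covariate")
})

test_that("cox_fit recovers a binary log-hazard of 2.0 without censoring", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(1000 + s)
    x <- rbinom(500, 1, 0.5)
    time <- rexp(500, 0.01 * 2^x)
    coh <- make_cohort(time, rep(1L, 500))
    coh$x <- x
    hr <- cox_fit(coh, "x")$coefficients["x", "hr"]
    if (hr >= 1.6 && hr <= 2.5) hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})

test_that("null covariates stay within 3 standard errors of zero", {
  ok <- 0L
  for (s in 1:100) {
    set.seed(2000 + s)
    coh <- make_cohort(rexp(200, 0.02), rbinom(200, 1, 0.7))
    coh$x <- rnorm(200)
    tab <- cox_fit(coh, "x")$coefficients
    if (abs(tab["x", "coef"]) <= 3 * tab["x", "se"]) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("LR statistics are nonnegative and dropping a term never helps the fit", {
  eff <- cohort_effects(c(pN = 0.5, G = 0.3), baseline_hazard = 0.004,
                        admin_censor_months = 200)
  coh <- generate_cohort(150, eff, seed = 17)
  fit <- cox_fit(coh, c("pN", "G", "pT"))
  expect_true(all(fit$coefficients$lr_stat >= 0))
  expect_true(all(fit$coefficients$lr_p >= 0 & fit$coefficients$lr_p <= 1))
  for (cv in c("pN", "G", "pT")) {
    red <- cox_fit(coh, setdiff(c("pN", "G", "pT"), cv))
    expect_lte(red$loglik, fit$loglik + 1e-8)
  }
  # hazard ratio is exp(coefficient)
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$coef))
})

test_that("Breslow and Efron tie handling are both available and differ on ties", {
  set.seed(5)
  coh <- make_cohort(sample(1:6, 120, TRUE), rbinom(120, 1, 0.6))
  coh$x <- rnorm(120)
  b <- cox_fit(coh, "x", ties = "breslow")
  e <- cox_fit(coh, "x", ties = "efron")
  expect_false(isTRUE(all.equal(b$loglik, e$loglik)))
})

test_that("stepwise stopping rules behave at the threshold boundaries", {
  eff <- cohort_effects(c(pN = log(2.5)), baseline_hazard = 0.004,
                        admin_censor_months = 240)
  coh <- generate_cohort(300, eff, seed = 23)

  # a single covariate with LR p below the threshold: zero removals
  st <- backward_stepwise_lr(coh, "pN", p_remove = 0.10)
  expect_length(st$removed_order, 0L)
  expect_identical(st$retained, "pN")

  # p_remove = 1: nothing is ever removed
  st1 <- backward_stepwise_lr(coh, c("pT", "pN", "G", "locat_v"), p_remove = 1)
  expect_length(st1$removed_order, 0L)
  expect_identical(sort(st1$retained), sort(c("pT", "pN", "G", "locat_v")))

  # p_remove = 0+: everything goes on a null cohort
  null_coh <- generate_cohort(200, cohort_effects(baseline_hazard = 0.005,
                                                  admin_censor_months = 200),
                              seed = 29)
  st0 <- backward_stepwise_lr(null_coh, c("pT", "G", "locat_v"), p_remove = 1e-9)
  expect_length(st0$retained, 0L)
  expect_null(st0$final_fit)
})

test_that("the trace removes exactly one covariate per step until the rule stops", {
  eff <- cohort_effects(c(pN = log(2), mnrat2_m = 0.005),
                        baseline_hazard = 1e-5, admin_censor_months = 240)
  coh <- generate_cohort(250, eff, seed = 31)
  covs <- c("pT", "pN", "G", "mnrat2_m", "locat_v")
  st <- backward_stepwise_lr(coh, covs, p_remove = 0.10)
  steps <- split(st$trace, st$trace$step)
  for (i in seq_along(steps)) {
    nrem <- sum(steps[[i]]$removed)
    if (i < length(steps)) expect_equal(nrem, 1L) else expect_lte(nrem, 1L)
  }
  expect_setequal(c(st$retained, st$removed_order), covs)
  expect_true(all(st$trace$p_value >= 0 & st$trace$p_value <= 1))
  # retained covariates all have final p <= threshold
  last <- steps[[length(steps)]]
  expect_true(all(last$p_value[!last$removed] <= 0.10 | last$removed))
})

test_that("cause-specific analysis censors other-cause deaths", {
  time <- c(10, 20, 30, 40, 50)
  coh <- make_cohort(time, c(1, 1, 0, 1, 0),
                     cause = c("breast_cancer", "other", "none",
                               "breast_cancer", "none"))
  ov <- endpoint_status(coh, "overall")
  cs <- endpoint_status(coh, "cause-specific")
  expect_equal(sum(ov$status), 3)
  expect_equal(sum(cs$status), 2)
  expect_gte(sum(ov$status), sum(cs$status))
  expect_error(endpoint_status(coh, "nonsense"))
})
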