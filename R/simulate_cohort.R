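#' Default marginal distributions for the cohort covariates
#'
#' One entry per covariate of the menu (`pT`, `pN`, `G`, `pkt_grad`, `polym`
#' and the 15 AgNOR parameters). Ordinal covariates are categorical over
#' their clinical levels; AgNOR parameters are truncated normals on their
#' natural scales. The source study reports no distributional parameters for
#' its cases, so these marginals are the package's own plausible choices;
#' they exist to exercise the estimators, not to mimic a particular cohort.
#'
#' Each entry is either `list(type = "ordinal", values =, probs =)` or
#' `list(type = "normal", mean =, sd =, min =, max =)`.
#'
#' @return named list of distribution specs.
#' @export
default_feature_distributions <- function() {
  nk <- list(
    nor_k0 = c(5, 3), nor_k1 = c(12, 5), nor_k2 = c(20, 6), nor_k3 = c(20, 6),
    nor_k4 = c(15, 5), nor_k5 = c(10, 4), nor_k6 = c(7, 3), nor_k7 = c(5, 3),
    nor_k8 = c(3, 2)
  )
  out <- list(
    pT = list(type = "ordinal", values = 1:4, probs = c(0.35, 0.35, 0.20, 0.10)),
    pN = list(type = "ordinal", values = 0:3, probs = c(0.50, 0.28, 0.15, 0.07)),
    G = list(type = "ordinal", values = 1:3, probs = c(0.20, 0.50, 0.30)),
    pkt_grad = list(type = "ordinal", values = 3:9,
                    probs = c(0.05, 0.10, 0.20, 0.25, 0.20, 0.12, 0.08)),
    polym = list(type = "ordinal", values = 1:3, probs = c(0.25, 0.50, 0.25)),
    nornbc_m = list(type = "normal", mean = 3, sd = 1, min = 0.5, max = Inf),
    snar_r_v = list(type = "normal", mean = 150, sd = 50, min = 1, max = Inf),
    center_v = list(type = "normal", mean = 0.12, sd = 0.04, min = 0.01, max = 1),
    cent_r_v = list(type = "normal", mean = 0.20, sd = 0.07, min = 0.01, max = 1),
    bord_r_v = list(type = "normal", mean = 0.15, sd = 0.05, min = 0.01, max = 1),
    locat_v = list(type = "normal", mean = 0.05, sd = 0.02, min = 0.001, max = 0.25),
    mnrat2_m = list(type = "normal", mean = 550, sd = 120, min = 50, max = 1000)
  )
  for (nm in names(nk)) {
    out[[nm]] <- list(type = "normal", mean = nk[[nm]][1], sd = nk[[nm]][2],
                      min = 0, max = 100)
  }
  out[agnor_covariate_menu()]
}

draw_covariate <- function(spec, n) {
  if (spec$type == "ordinal") {
    sample(spec$values, n, replace = TRUE, prob = spec$probs)
  } else if (spec$type == "normal") {
    x <- stats::rnorm(n, spec$mean, spec$sd)
    pmin(pmax(x, spec$min), spec$max)
  } else {
    stop("unknown distribution type: ", spec$type)
  }
}

#' Simulate a survival cohort with known hazard structure
#'
#' Draws covariates from per-covariate marginal distributions, then simulates
#' follow-up from an exponential proportional-hazards model: the event time of
#' case i is exponential with rate `baseline_hazard * exp(sum_j beta_j x_ij)`.
#' The censoring time is the minimum of the administrative horizon and an
#' independent exponential censoring draw (whichever are enabled); the
#' observed time is `min(event time, censoring time)`. Observed deaths are
#' attributed to breast cancer with probability `cause_mix`, otherwise to
#' another cause.
#'
#' @param n number of cases (>= 2).
#' @param effects a [cohort_effects()].
#' @param feature_distributions named list of distribution specs; defaults to
#'   [default_feature_distributions()]. Every covariate named in the effects
#'   must have a distribution.
#' @param seed integer seed.
#' @param missing_prob optional named numeric vector: probability of an
#'   independently missing (NA) value per named covariate.
#' @return data frame with `case_id`, one column per covariate of the menu,
#'   `time_months`, `event` (0/1) and `cause`
#'   (`"breast_cancer"`, `"other"`, `"none"`).
#' @export
#' @examples
#' eff <- cohort_effects(c(pN = log(2)), baseline_hazard = 0.004,
#'                       admin_censor_months = 120)
#' coh <- generate_cohort(100, eff, seed = 1)
#' mean(coh$event)
generate_cohort <- function(n, effects,
                            feature_distributions = default_feature_distributions(),
                            seed = 1L, missing_prob = NULL) {
  stopifnot(inherits(effects, "cohort_effects"), n >= 2)
  missing_dist <- setdiff(names(effects$coefficients), names(feature_distributions))
  if (length(missing_dist)) {
    stop("no feature distribution for covariate(s): ",
         paste(missing_dist, collapse = ", "))
  }
  set.seed(seed)
  covs <- names(feature_distributions)
  X <- as.data.frame(lapply(feature_distributions, draw_covariate, n = n))
  names(X) <- covs

  lp <- rep(0, n)
  for (nm in names(effects$coefficients)) {
    lp <- lp + effects$coefficients[[nm]] * X[[nm]]
  }
  rate <- effects$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, rate)
  t_cens <- rep(Inf, n)
  if (!is.null(effects$censor_rate) && effects$censor_rate > 0) {
    t_cens <- stats::rexp(n, effects$censor_rate)
  }
  if (!is.null(effects$admin_censor_months)) {
    t_cens <- pmin(t_cens, effects$admin_censor_months)
  }
  event <- as.integer(t_event <= t_cens)
  time <- pmin(t_event, t_cens)
  cause <- rep("none", n)
  if (any(event == 1L)) {
    bc <- stats::rbinom(sum(event), 1, effects$cause_mix)
    cause[event == 1L] <- ifelse(bc == 1, "breast_cancer", "other")
  }

  if (!is.null(missing_prob)) {
    bad <- setdiff(names(missing_prob), covs)
    if (length(bad)) stop("missing_prob names not in covariate menu: ",
                          paste(bad, collapse = ", "))
    for (nm in names(missing_prob)) {
      drop <- stats::runif(n) < missing_prob[[nm]]
      X[[nm]][drop] <- NA
    }
  }

  out <- cbind(data.frame(case_id = sprintf("case%04d", seq_len(n))),
               X,
               data.frame(time_months = time, event = event, cause = cause))
  rownames(out) <- NULL
  out
}

#' Calibrate the baseline hazard to a target event fraction
#'
#' Solves for the baseline event rate at which the expected fraction of
#' observed events matches `target`, given the covariate distributions, the
#' log-hazard coefficients and the censoring model. The expectation is taken
#' over a Monte-Carlo draw of covariates using the closed-form event
#' probability for exponential event and censoring times
#' (`a/(a+rho) * (1 - exp(-(a+rho)*tau))` for event rate `a`, censoring rate
#' `rho` and horizon `tau`).
#'
#' @param effects a [cohort_effects()]; its `baseline_hazard` is replaced.
#' @param feature_distributions as in [generate_cohort()].
#' @param target target event fraction in (0, 1).
#' @param n_mc Monte-Carlo sample size for the covariate expectation.
#' @param seed seed for the Monte-Carlo draw.
#' @return the effects object with `baseline_hazard` set to the calibrated rate.
#' @export
calibrate_baseline <- function(effects,
                               feature_distributions = default_feature_distributions(),
                               target = 0.3, n_mc = 4000, seed = 1L) {
  stopifnot(inherits(effects, "cohort_effects"), target > 0, target < 1)
  set.seed(seed)
  X <- as.data.frame(lapply(feature_distributions, draw_covariate, n = n_mc))
  names(X) <- names(feature_distributions)
  lp <- rep(0, n_mc)
  for (nm in names(effects$coefficients)) {
    lp <- lp + effects$coefficients[[nm]] * X[[nm]]
  }
  rho <- if (is.null(effects$censor_rate)) 0 else effects$censor_rate
  tau <- if (is.null(effects$admin_censor_months)) Inf else effects$admin_censor_months
  if (rho == 0 && !is.finite(tau)) {
    return(effects)  # no censoring: every record is an event at any rate
  }
  pev <- function(lambda) {
    a <- lambda * exp(lp)
    mean(a / (a + rho) * (1 - exp(-(a + rho) * min(tau, 1e9))))
  }
  f <- function(loglam) pev(exp(loglam)) - target
  sol <- stats::uniroot(f, lower = log(1e-8), upper = log(10), tol = 1e-10)
  effects$baseline_hazard <- exp(sol$root)
  effects
}

#' Write a cohort table to CSV
#'
#' One row per case, columns named exactly as the covariate menu plus
#' `time_months`, `event`, `cause`.
#'
#' @param cohort data frame from [generate_cohort()] (or the same contract).
#' @param path output file.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a clinical cohort CSV
#'
#' @param path CSV with `case_id`, covariate columns, `time_months`, `event`
#'   and optionally `cause` (defaulted to `"breast_cancer"` for events when
#'   absent, since an all-cause register cannot distinguish causes).
#' @return data frame.
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "time_months", "event")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("cohort CSV lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(x$cause)) {
    x$cause <- ifelse(x$event == 1, "breast_cancer", "none")
  }
  x
}
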