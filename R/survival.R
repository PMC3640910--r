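#' Endpoint status for a cohort
#'
#' `"overall"` counts any death as an event; `"cause_specific"` counts only
#' deaths attributed to breast cancer, censoring deaths from other causes at
#' their death time.
#'
#' @param cohort data frame with `time_months`, `event` and `cause`.
#' @param endpoint `"overall"` or `"cause_specific"` (the spelling
#'   `"cause-specific"` is accepted).
#' @return list with numeric `time` and integer `status`.
#' @export
endpoint_status <- function(cohort, endpoint = c("overall", "cause_specific")) {
  endpoint <- gsub("-", "_", endpoint[1])
  endpoint <- match.arg(endpoint, c("overall", "cause_specific"))
  need <- c("time_months", "event")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  status <- as.integer(cohort$event == 1)
  if (endpoint == "cause_specific") {
    if (is.null(cohort$cause)) stop("cause-specific endpoint requires a 'cause' column")
    status <- as.integer(cohort$event == 1 & cohort$cause == "breast_cancer")
  }
  list(time = as.numeric(cohort$time_months), status = status,
       endpoint = endpoint)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function for the chosen endpoint;
#' cases censored at t leave the risk set after t.
#'
#' @param cohort data frame with `time_months`, `event`, `cause`.
#' @param endpoint see [endpoint_status()].
#' @return An object of class `"km_estimate"`: a data frame with columns
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`, with the underlying
#'   [survival::survfit] object as attribute `"fit"`.
#' @export
km_estimate <- function(cohort, endpoint = "overall") {
  es <- endpoint_status(cohort, endpoint)
  if (!length(es$time)) stop("empty cohort")
  if (any(!is.finite(es$time)) || any(es$time < 0)) {
    stop("survival times must be finite and non-negative")
  }
  fit <- survival::survfit(survival::Surv(es$time, es$status) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  attr(out, "fit") <- fit
  attr(out, "endpoint") <- es$endpoint
  class(out) <- c("km_estimate", "data.frame")
  out
}

#' @export
plot.km_estimate <- function(x, ...) {
  plot(attr(x, "fit"), xlab = "Months", ylab = "Survival probability",
       mark.time = TRUE, ...)
  invisible(x)
}

#' Cox proportional-hazards fit with likelihood-ratio removal tests
#'
#' Fits the Cox model for the chosen endpoint on the listwise-complete cases
#' (every requested covariate, time and status present) and reports, per
#' covariate, the coefficient, its standard error, the hazard ratio and the
#' p-value of the likelihood-ratio chi-square test comparing the model with
#' versus without that covariate — the removal statistic of backward stepwise
#' selection. Partial-likelihood maximisation is delegated to
#' [survival::coxph].
#'
#' @param cohort cohort data frame.
#' @param covariates character vector of covariate column names.
#' @param endpoint see [endpoint_status()].
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param data_prepared internal: pass a pre-subset complete-case data frame.
#' @return An object of class `"agnor_cox"` with elements `coefficients`
#'   (data frame: `coef`, `se`, `hr`, `lr_stat`, `lr_p`), `loglik`,
#'   `null_loglik`, `n`, `nevent`, `ties`, `endpoint`, `fit`.
#' @export
cox_fit <- function(cohort, covariates, endpoint = "overall",
                    ties = c("breslow", "efron"), data_prepared = NULL) {
  ties <- match.arg(ties)
  if (!length(covariates)) stop("no covariates supplied")
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) stop("cohort lacks covariate(s): ", paste(miss, collapse = ", "))
  df <- if (is.null(data_prepared)) {
    prepare_cox_data(cohort, covariates, endpoint)
  } else data_prepared

  nev <- sum(df$.status)
  if (nev < 2) stop("fewer than 2 events in the analysed cases")
  for (cv in covariates) {
    if (length(unique(df[[cv]])) <= 1L) {
      stop("covariate '", cv, "' is constant on the analysed cases")
    }
  }
  fml <- stats::as.formula(paste("survival::Surv(.time, .status) ~",
                                 paste(covariates, collapse = " + ")))
  ctrl <- survival::coxph.control(iter.max = 50)
  fit <- survival::coxph(fml, data = df, ties = ties, control = ctrl)
  ll_full <- fit$loglik[2]
  ll_null <- fit$loglik[1]

  lr <- vapply(covariates, function(cv) {
    red <- setdiff(covariates, cv)
    ll_red <- if (!length(red)) ll_null else {
      f2 <- stats::as.formula(paste("survival::Surv(.time, .status) ~",
                                    paste(red, collapse = " + ")))
      survival::coxph(f2, data = df, ties = ties, control = ctrl)$loglik[2]
    }
    stat <- 2 * (ll_full - ll_red)
    c(stat = max(stat, 0), p = stats::pchisq(max(stat, 0), df = 1,
                                             lower.tail = FALSE))
  }, c(stat = 0, p = 0))

  co <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  tab <- data.frame(coef = as.numeric(co), se = se, hr = exp(as.numeric(co)),
                    lr_stat = lr["stat", ], lr_p = lr["p", ],
                    row.names = covariates)
  structure(list(coefficients = tab, loglik = ll_full, null_loglik = ll_null,
                 n = nrow(df), nevent = nev, ties = ties,
                 endpoint = gsub("-", "_", endpoint[1]),
                 covariates = covariates, fit = fit),
            class = "agnor_cox")
}

# Listwise deletion on the requested covariates plus time/status.
prepare_cox_data <- function(cohort, covariates, endpoint) {
  es <- endpoint_status(cohort, endpoint)
  df <- cohort[, covariates, drop = FALSE]
  df$.time <- es$time
  df$.status <- es$status
  keep <- stats::complete.cases(df)
  df[keep, , drop = FALSE]
}

#' @export
print.agnor_cox <- function(x, digits = 4, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties), endpoint: %s\n",
              x$ties, x$endpoint))
  cat(sprintf("n = %d cases, %d events; log partial likelihood %.3f\n",
              x$n, x$nevent, x$loglik))
  tab <- x$coefficients
  tab$lr_p <- signif(tab$lr_p, 3)
  print(round(tab, digits))
  invisible(x)
}

#' @export
summary.agnor_cox <- function(object, ...) {
  lr_global <- 2 * (object$loglik - object$null_loglik)
  p_global <- stats::pchisq(lr_global, df = length(object$covariates),
                            lower.tail = FALSE)
  out <- list(coefficients = object$coefficients, n = object$n,
              nevent = object$nevent, loglik = object$loglik,
              lr_global = lr_global, p_global = p_global,
              endpoint = object$endpoint, ties = object$ties)
  class(out) <- "summary.agnor_cox"
  out
}

#' @export
print.summary.agnor_cox <- function(x, ...) {
  cat(sprintf("Cox fit, endpoint %s: n = %d, events = %d\n",
              x$endpoint, x$n, x$nevent))
  cat(sprintf("Global LR chi-square = %.2f on %d df, p = %.4g\n",
              x$lr_global, nrow(x$coefficients), x$p_global))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.agnor_cox <- function(object, ...) {
  stats::setNames(object$coefficients$coef, rownames(object$coefficients))
}

#' Backward stepwise Cox regression with likelihood-ratio removal
#'
#' Starts from the full model on the listwise-complete cases (fixed for the
#' whole run) and repeatedly removes the covariate with the largest
#' likelihood-ratio p-value, as long as that p-value exceeds `p_remove`;
#' stops when every remaining covariate has p at or below the threshold (or
#' none remain). Each step's per-covariate significances are recorded, so the
#' trace prints like the classic SPSS "reverse step-by-step (likelihood
#' ratio)" output.
#'
#' @param cohort cohort data frame.
#' @param covariates covariates of the full model.
#' @param endpoint see [endpoint_status()].
#' @param p_remove removal threshold (default 0.10, the classical value: a
#'   covariate is dropped only if its removal p exceeds this).
#' @param ties `"breslow"` or `"efron"`.
#' @return An object of class `"cox_stepwise"`: `trace` (data frame `step`,
#'   `covariate`, `p_value`, `removed`), `retained`, `removed_order`,
#'   `final_fit` (an `"agnor_cox"`, or `NULL` if everything was removed),
#'   `p_remove`, `endpoint`, `n`, `nevent`.
#' @export
#' @examples
#' eff <- cohort_effects(c(pN = log(2.2)), baseline_hazard = 0.004,
#'                       admin_censor_months = 180)
#' coh <- generate_cohort(300, eff, seed = 7)
#' st <- backward_stepwise_lr(coh, c("pT", "pN", "G"), p_remove = 0.10)
#' st$retained
backward_stepwise_lr <- function(cohort, covariates, endpoint = "overall",
                                 p_remove = 0.10, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(p_remove >= 0, p_remove <= 1, length(covariates) >= 1)
  df <- prepare_cox_data(cohort, covariates, endpoint)

  current <- covariates
  trace <- list()
  removed_order <- character(0)
  step <- 0L
  final_fit <- NULL
  while (length(current)) {
    step <- step + 1L
    fit <- tryCatch(
      cox_fit(cohort, current, endpoint, ties, data_prepared = df),
      error = function(e) stop("stepwise step ", step, ": ", conditionMessage(e),
                               call. = FALSE))
    ps <- fit$coefficients$lr_p
    names(ps) <- rownames(fit$coefficients)
    worst <- names(ps)[order(-ps, names(ps))][1]
    drop_it <- ps[[worst]] > p_remove
    trace[[step]] <- data.frame(step = step, covariate = names(ps),
                                p_value = as.numeric(ps),
                                removed = drop_it & names(ps) == worst)
    if (!drop_it) { final_fit <- fit; break }
    removed_order <- c(removed_order, worst)
    current <- setdiff(current, worst)
    if (!length(current)) final_fit <- NULL
  }
  trace <- do.call(rbind, trace)
  rownames(trace) <- NULL
  structure(list(trace = trace, retained = current,
                 removed_order = removed_order, final_fit = final_fit,
                 p_remove = p_remove,
                 endpoint = gsub("-", "_", endpoint[1]),
                 n = nrow(df), nevent = sum(df$.status)),
            class = "cox_stepwise")
}

#' @export
print.cox_stepwise <- function(x, ...) {
  cat(sprintf("Cox regression, reverse step-by-step (likelihood ratio)\n"))
  cat(sprintf("endpoint: %s; n = %d, events = %d; removal threshold p > %g\n\n",
              x$endpoint, x$n, x$nevent, x$p_remove))
  for (s in unique(x$trace$step)) {
    rows <- x$trace[x$trace$step == s, ]
    cat(sprintf("Step %d\n", s))
    for (i in seq_len(nrow(rows))) {
      star <- if (rows$removed[i]) "  <- removed" else ""
      cat(sprintf("  %-10s %s%s\n", rows$covariate[i],
                  sub("^0\\.", ".", sprintf("%.3f", rows$p_value[i])), star))
    }
  }
  if (length(x$retained)) {
    cat("\nRetained: ", paste(x$retained, collapse = ", "), "\n", sep = "")
  } else {
    cat("\nNo covariate retained.\n")
  }
  invisible(x)
}

#' @export
summary.cox_stepwise <- function(object, ...) {
  cat(sprintf("Backward stepwise LR selection: %d step(s), removed %d of %d covariates\n",
              max(object$trace$step), length(object$removed_order),
              length(object$removed_order) + length(object$retained)))
  if (length(object$removed_order)) {
    cat("Removal order:", paste(object$removed_order, collapse = " -> "), "\n")
  }
  if (!is.null(object$final_fit)) print(object$final_fit)
  invisible(object)
}

#' Write a stepwise trace to CSV
#'
#' Columns `step`, `covariate`, `significance`, `removed`, mirroring the
#' layout of the classic stepwise report tables.
#'
#' @param x a `"cox_stepwise"`.
#' @param path output file.
#' @export
write_stepwise_csv <- function(x, path) {
  stopifnot(inherits(x, "cox_stepwise"))
  out <- data.frame(step = x$trace$step, covariate = x$trace$covariate,
                    significance = x$trace$p_value, removed = x$trace$removed)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
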