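#' Pipeline run configuration
#'
#' Collects everything one end-to-end run needs. Exactly one input mode is
#' allowed: `"synthetic"` (fields are generated, features computed, and
#' survival simulated from those features) or `"files"` (image/mask TIFF
#' pairs plus a clinical CSV are read from disk).
#'
#' In synthetic mode the hazard acts on standardised covariates: each
#' covariate named in the effects is z-scored across the cohort before the
#' linear predictor is formed, so a coefficient is a log hazard ratio per
#' standard deviation regardless of the covariate's natural scale (per-mille
#' features would otherwise dwarf ordinal ones). The baseline hazard is
#' calibrated to `target_event_fraction` given the realised covariates.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param n_cases number of cases (synthetic mode).
#' @param scenario an [image_scenario()] or a preset name.
#' @param effects a [cohort_effects()] (synthetic mode).
#' @param target_event_fraction expected fraction of observed events the
#'   baseline hazard is calibrated to (synthetic mode).
#' @param detection a [detect_params()].
#' @param zones a [zone_definition()].
#' @param endpoints character vector among `"overall"`, `"cause_specific"`.
#' @param stepwise_covariates covariates of the full stepwise model; default
#'   is the 18-parameter menu (pT, pN, G and the 15 AgNOR parameters).
#' @param p_remove stepwise removal threshold.
#' @param seed integer seed (required in synthetic mode).
#' @param outdir output directory.
#' @param image_files files mode: data frame or list with `case_id`,
#'   `image`, `mask` paths.
#' @param clinical_csv files mode: clinical CSV path (joined on `case_id`).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       n_cases = 244,
                       scenario = scenario_preset("high_variability"),
                       effects = cohort_effects(
                         c(mnrat2_m = log(2), pN = log(1.8)),
                         admin_censor_months = 247),
                       target_event_fraction = 81 / 244,
                       detection = NULL,
                       zones = zone_definition(),
                       endpoints = c("overall", "cause_specific"),
                       stepwise_covariates = NULL,
                       p_remove = 0.10,
                       seed = NULL,
                       outdir = tempfile("agnor_run_"),
                       image_files = NULL,
                       clinical_csv = NULL) {
  mode <- match.arg(mode)
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  if (is.null(detection)) {
    detection <- detect_params(calibration = scenario$calibration)
  }
  if (mode == "synthetic" && is.null(seed)) {
    stop("synthetic mode requires a seed")
  }
  if (mode == "files" && (is.null(image_files) || is.null(clinical_csv))) {
    stop("files mode requires image_files and clinical_csv")
  }
  if (is.null(stepwise_covariates)) {
    # the 18-covariate full model: conventional parameters plus the 15 AgNOR
    # parameters (nor_k0 is omitted: with counts capped at 8 it is an exact
    # linear combination of the other count-class percentages)
    stepwise_covariates <- setdiff(agnor_covariate_menu(),
                                   c("pkt_grad", "polym", "nor_k0"))
  }
  endpoints <- vapply(endpoints, function(e) gsub("-", "_", e), "")
  stopifnot(all(endpoints %in% c("overall", "cause_specific")))
  structure(list(mode = mode, n_cases = n_cases, scenario = scenario,
                 effects = effects,
                 target_event_fraction = target_event_fraction,
                 detection = detection, zones = zones, endpoints = endpoints,
                 stepwise_covariates = stepwise_covariates,
                 p_remove = p_remove, seed = seed, outdir = outdir,
                 image_files = image_files, clinical_csv = clinical_csv),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [run_config()] arguments; `scenario` may
#' be a preset name or a mapping of [image_scenario()] arguments; `effects`
#' is a mapping with `coefficients`, `baseline_hazard`, `admin_censor_months`,
#' `censor_rate`, `cause_mix`; `detection` and `zones` are mappings of the
#' respective constructor arguments.
#'
#' @param path YAML file.
#' @return a `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("mode", "n_cases", "target_event_fraction", "endpoints",
               "stepwise_covariates", "p_remove", "seed", "outdir",
               "clinical_csv")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$scenario)) {
    args$scenario <- if (is.character(y$scenario)) {
      scenario_preset(y$scenario)
    } else {
      sc <- y$scenario
      if (!is.null(sc$radial_position_distribution)) {
        sc$radial_position_distribution <- as.list(sc$radial_position_distribution)
      }
      do.call(image_scenario, sc)
    }
  }
  if (!is.null(y$effects)) {
    ef <- y$effects
    ef$coefficients <- unlist(ef$coefficients)
    args$effects <- do.call(cohort_effects, ef)
  }
  if (!is.null(y$detection)) args$detection <- do.call(detect_params, y$detection)
  if (!is.null(y$zones)) args$zones <- do.call(zone_definition, y$zones)
  if (!is.null(y$image_files)) args$image_files <- as.data.frame(y$image_files)
  do.call(run_config, args)
}

#' Simulate survival from measured case features
#'
#' Exponential proportional-hazards simulation where the linear predictor is
#' built from the cohort's own (standardised) feature columns, so downstream
#' selection can be tested against a known truth on realistic, image-derived
#' covariates.
#'
#' @param features data frame with one row per case containing every
#'   covariate named in the effects.
#' @param effects a [cohort_effects()].
#' @param seed integer seed.
#' @param target_event_fraction if not `NULL`, the baseline hazard is
#'   calibrated so the expected event fraction matches it.
#' @return `features` with `time_months`, `event`, `cause` columns appended.
#' @export
simulate_survival_from_features <- function(features, effects, seed,
                                            target_event_fraction = NULL) {
  stopifnot(inherits(effects, "cohort_effects"))
  n <- nrow(features)
  lp <- rep(0, n)
  for (nm in names(effects$coefficients)) {
    if (is.null(features[[nm]])) stop("features lack covariate '", nm, "'")
    x <- features[[nm]]
    s <- stats::sd(x)
    z <- if (is.na(s) || s == 0) rep(0, n) else (x - mean(x)) / s
    lp <- lp + effects$coefficients[[nm]] * z
  }
  lambda <- effects$baseline_hazard
  rho <- if (is.null(effects$censor_rate)) 0 else effects$censor_rate
  tau <- if (is.null(effects$admin_censor_months)) Inf else effects$admin_censor_months
  if (!is.null(target_event_fraction) && (rho > 0 || is.finite(tau))) {
    pev <- function(l) {
      a <- l * exp(lp)
      mean(a / (a + rho) * (1 - exp(-(a + rho) * min(tau, 1e9))))
    }
    sol <- stats::uniroot(function(g) pev(exp(g)) - target_event_fraction,
                          lower = log(1e-8), upper = log(10), tol = 1e-10)
    lambda <- exp(sol$root)
  }
  set.seed(seed)
  t_event <- stats::rexp(n, lambda * exp(lp))
  t_cens <- rep(Inf, n)
  if (rho > 0) t_cens <- stats::rexp(n, rho)
  if (is.finite(tau)) t_cens <- pmin(t_cens, tau)
  event <- as.integer(t_event <= t_cens)
  cause <- rep("none", n)
  if (any(event == 1L)) {
    bc <- stats::rbinom(sum(event), 1, effects$cause_mix)
    cause[event == 1L] <- ifelse(bc == 1, "breast_cancer", "other")
  }
  features$time_months <- pmin(t_event, t_cens)
  features$event <- event
  features$cause <- cause
  features
}

#' Run the full AgNOR quantification and survival pipeline
#'
#' Synthetic mode: renders one field per case, detects AgNORs inside the
#' nucleus masks, computes the case-level feature vector, draws the
#' conventional covariates, simulates survival from the measured features
#' per the configured hazard structure, and runs Kaplan-Meier estimation,
#' case-processing summaries and backward stepwise Cox selection for each
#' endpoint. Files mode: reads image/mask pairs and the clinical CSV and
#' runs the same downstream stages. All outputs are written as CSV plus a
#' JSON manifest (config hash, seed, versions); rerunning an identical
#' configuration reproduces identical CSVs.
#'
#' @param config a [run_config()] or path to a YAML configuration.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `features`, `cohort`, and per-endpoint
#'   `case_processing`, `stepwise`, `km`, plus `outdir` and `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$outdir, "run.log")
  cat("", file = logfile)
  say <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
    if (!quiet) message(msg)
  }
  stage <- function(name, id, expr) {
    tryCatch(expr, error = function(e) {
      say("ERROR in stage '%s' (case %s): %s", name, format(id),
          conditionMessage(e))
      stop("pipeline stage '", name, "' failed on case ", format(id), ": ",
           conditionMessage(e), call. = FALSE)
    })
  }

  if (config$mode == "synthetic") {
    say("synthetic mode: %d cases, seed %d", config$n_cases, config$seed)
    cases <- vector("list", config$n_cases)
    for (i in seq_len(config$n_cases)) {
      cid <- sprintf("case%04d", i)
      fs <- stage("simulate-images", cid,
                  generate_image_set(config$scenario,
                                     seed = substream_seed(config$seed, 7000 + i),
                                     case_id = cid))
      cases[[i]] <- stage("detect", cid,
                          detect_case(fs$image, fs$mask, config$detection, cid))
    }
    features <- stage("features", "all",
                      case_feature_table(cases, config$zones))
    say("feature table: %d cases x %d columns", nrow(features), ncol(features))

    set.seed(substream_seed(config$seed, 900001))
    conv <- default_feature_distributions()[c("pT", "pN", "G", "pkt_grad", "polym")]
    for (nm in names(conv)) features[[nm]] <- draw_covariate(conv[[nm]], nrow(features))

    cohort <- stage("simulate-cohort", "all",
                    simulate_survival_from_features(
                      features, config$effects,
                      seed = substream_seed(config$seed, 900002),
                      target_event_fraction = config$target_event_fraction))
  } else {
    imf <- as.data.frame(config$image_files)
    say("files mode: %d image pairs", nrow(imf))
    cases <- lapply(seq_len(nrow(imf)), function(i) {
      cid <- as.character(imf$case_id[i])
      pr <- stage("read-images", cid,
                  read_image_pair(imf$image[i], imf$mask[i]))
      stage("detect", cid, detect_case(pr$image, pr$mask, config$detection, cid))
    })
    features <- stage("features", "all", case_feature_table(cases, config$zones))
    clinical <- stage("read-clinical", "all", read_cohort_csv(config$clinical_csv))
    cohort <- merge(features, clinical, by = "case_id", sort = TRUE)
  }

  write_cohort_csv(features[, !(names(features) %in% c("time_months", "event", "cause"))],
                   file.path(config$outdir, "features.csv"))
  write_cohort_csv(cohort, file.path(config$outdir, "cohort.csv"))

  results <- list()
  for (ep in config$endpoints) {
    say("endpoint %s: case processing, KM, stepwise", ep)
    cp <- stage("case-processing", ep,
                case_processing_summary(cohort, ep,
                                        covariates = config$stepwise_covariates))
    km <- stage("km", ep, km_estimate(cohort, ep))
    sw <- stage("stepwise", ep,
                backward_stepwise_lr(cohort, config$stepwise_covariates, ep,
                                     p_remove = config$p_remove))
    write_case_processing_csv(cp, file.path(config$outdir,
                                            paste0("case_processing_", ep, ".csv")))
    utils::write.csv(as.data.frame(km),
                     file.path(config$outdir, paste0("km_", ep, ".csv")),
                     row.names = FALSE)
    write_stepwise_csv(sw, file.path(config$outdir, paste0("stepwise_", ep, ".csv")))
    say("endpoint %s: retained {%s}", ep, paste(sw$retained, collapse = ", "))
    results[[ep]] <- list(case_processing = cp, km = km, stepwise = sw)
  }

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    mode = config$mode,
    n_cases = if (config$mode == "synthetic") config$n_cases else length(cases),
    endpoints = config$endpoints,
    p_remove = config$p_remove,
    package_version = as.character(utils::packageVersion("agnortools")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: outputs in %s", config$outdir)
  invisible(c(list(features = features, cohort = cohort,
                   outdir = config$outdir, manifest = manifest), results))
}

# Stable digest of the configuration: canonical YAML serialisation hashed
# with md5 (via a temp file; tools::md5sum is file-based). The output
# directory is where results land, not what they are, so it is excluded.
config_hash <- function(config) {
  ser <- config
  ser$outdir <- NULL
  ser$scenario <- unclass(ser$scenario)
  ser$effects <- unclass(ser$effects)
  ser$detection <- unclass(ser$detection)
  ser$zones <- unclass(ser$zones)
  txt <- yaml::as.yaml(lapply(unclass(ser), function(x) x))
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}
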