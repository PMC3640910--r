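#' Synthetic image scenario
#'
#' Describes the study conditions under which synthetic silver-stained fields
#' are rendered: how many tumour nuclei are marked, how large they are, how
#' many AgNOR dots each contains, how big and how peripheral those dots are,
#' how often dots sit close enough to merge into a conglomerate, and the
#' grey-level/noise model of the 8-bit image.
#'
#' AgNORs are dark dots on lighter nuclei, so `particle_intensity` must be
#' below `nucleus_intensity`.
#'
#' @param n_nuclei number of marked nuclei per field.
#' @param nucleus_radius_range length-2 numeric, semi-major axis range in
#'   micrometres. Nuclei are ellipses with axis ratio drawn in `[0.6, 1]`.
#' @param agnor_count_distribution probability vector over true AgNOR counts
#'   `0..12` (length 13, re-normalised internally).
#' @param agnor_radius_range length-2 numeric, particle radius range (um).
#' @param radial_position_distribution distribution of the normalised radial
#'   position `d_norm` in `[0, 1]`: either
#'   `list(type = "uniform", min =, max =)` or
#'   `list(type = "beta", shape1 =, shape2 =)`.
#' @param conglomerate_probability probability that a placement event is a
#'   conglomerate of 2--3 touching particles rather than a lone particle.
#' @param background_intensity,nucleus_intensity,particle_intensity grey
#'   levels in 0--255.
#' @param noise_sd additive Gaussian noise SD in grey levels.
#' @param calibration pixel size in micrometres per pixel.
#' @return An object of class `"image_scenario"`.
#' @seealso [scenario_preset()] for the low/high variability phenotypes,
#'   [generate_image_set()] to render a field.
#' @export
image_scenario <- function(n_nuclei = 30,
                           nucleus_radius_range = c(4.5, 7),
                           agnor_count_distribution = NULL,
                           agnor_radius_range = c(0.50, 0.60),
                           radial_position_distribution = list(type = "uniform", min = 0.1, max = 0.7),
                           conglomerate_probability = 0.1,
                           background_intensity = 210,
                           nucleus_intensity = 160,
                           particle_intensity = 60,
                           noise_sd = 0,
                           calibration = 0.25) {
  if (is.null(agnor_count_distribution)) {
    agnor_count_distribution <- stats::dpois(0:12, 3)
  }
  stopifnot(
    length(n_nuclei) == 1L, n_nuclei >= 1,
    length(nucleus_radius_range) == 2L, all(nucleus_radius_range > 0),
    diff(nucleus_radius_range) >= 0,
    length(agnor_count_distribution) == 13L, all(agnor_count_distribution >= 0),
    sum(agnor_count_distribution) > 0,
    length(agnor_radius_range) == 2L, all(agnor_radius_range > 0),
    diff(agnor_radius_range) >= 0,
    conglomerate_probability >= 0, conglomerate_probability <= 1,
    noise_sd >= 0, calibration > 0
  )
  if (!particle_intensity < nucleus_intensity) {
    stop("particle_intensity must be below nucleus_intensity (AgNORs are dark dots)")
  }
  for (lev in c(background_intensity, nucleus_intensity, particle_intensity)) {
    if (lev < 0 || lev > 255) stop("intensities must lie in 0..255")
  }
  rpd <- radial_position_distribution
  if (!is.list(rpd) || is.null(rpd$type)) stop("radial_position_distribution must be a list with a 'type'")
  if (rpd$type == "uniform") {
    stopifnot(rpd$min >= 0, rpd$max <= 1, rpd$min <= rpd$max)
  } else if (rpd$type == "beta") {
    stopifnot(rpd$shape1 > 0, rpd$shape2 > 0)
  } else {
    stop("unknown radial position distribution type: ", rpd$type)
  }
  structure(list(
    n_nuclei = as.integer(n_nuclei),
    nucleus_radius_range = as.numeric(nucleus_radius_range),
    agnor_count_distribution = agnor_count_distribution / sum(agnor_count_distribution),
    agnor_radius_range = as.numeric(agnor_radius_range),
    radial_position_distribution = rpd,
    conglomerate_probability = conglomerate_probability,
    background_intensity = background_intensity,
    nucleus_intensity = nucleus_intensity,
    particle_intensity = particle_intensity,
    noise_sd = noise_sd,
    calibration = calibration
  ), class = "image_scenario")
}

#' Scenario presets for the two AgNOR variability phenotypes
#'
#' `"low_variability"` emulates tumours whose nuclei carry few, similar-sized,
#' centrally clustered AgNORs; `"high_variability"` emulates the opposite
#' phenotype with widely varying dot number, size and position. These are the
#' two qualitative extremes the morphometric dispersion features (`snar_r_v`,
#' `locat_v`, ...) are designed to separate.
#'
#' @param name `"low_variability"` or `"high_variability"`.
#' @param ... overrides passed on to [image_scenario()].
#' @return An `"image_scenario"`.
#' @export
scenario_preset <- function(name = c("low_variability", "high_variability"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    low_variability = list(
      nucleus_radius_range = c(4, 6.5),
      agnor_count_distribution = c(0, 0.05, 0.40, 0.35, 0.15, 0.05, rep(0, 7)),
      agnor_radius_range = c(0.50, 0.60),
      radial_position_distribution = list(type = "uniform", min = 0.15, max = 0.45),
      conglomerate_probability = 0.05,
      noise_sd = 2
    ),
    high_variability = list(
      nucleus_radius_range = c(4.5, 7),
      agnor_count_distribution = c(0.05, 0.08, 0.10, 0.10, 0.10, 0.10, 0.10,
                                   0.09, 0.08, 0.07, 0.05, 0.04, 0.04),
      agnor_radius_range = c(0.30, 0.80),
      radial_position_distribution = list(type = "uniform", min = 0.02, max = 0.95),
      conglomerate_probability = 0.20,
      noise_sd = 2
    )
  )
  args <- utils::modifyList(base, list(...))
  do.call(image_scenario, args)
}

#' @export
print.image_scenario <- function(x, ...) {
  cat("Synthetic AgNOR image scenario\n")
  cat(sprintf("  nuclei per field : %d (semi-major axis %.2f-%.2f um)\n",
              x$n_nuclei, x$nucleus_radius_range[1], x$nucleus_radius_range[2]))
  cat(sprintf("  AgNOR count      : categorical over 0..12, mean %.2f\n",
              sum((0:12) * x$agnor_count_distribution)))
  cat(sprintf("  AgNOR radius     : %.2f-%.2f um; conglomerate prob %.2f\n",
              x$agnor_radius_range[1], x$agnor_radius_range[2],
              x$conglomerate_probability))
  cat(sprintf("  grey levels      : background %g, nucleus %g, particle %g, noise sd %g\n",
              x$background_intensity, x$nucleus_intensity, x$particle_intensity,
              x$noise_sd))
  cat(sprintf("  calibration      : %g um/pixel\n", x$calibration))
  invisible(x)
}

#' The cohort covariate menu
#'
#' The covariate names every cohort-level routine validates against: the
#' three conventional prognostic parameters (`pT`, `pN`, `G`), the 15
#' case-level AgNOR parameters (`nor_k0` included for uniform k-handling),
#' and the two grading sub-scores (`pkt_grad`, the seven-point
#' Bloom-Richardson/Elston-Ellis point score, and `polym`, its pleomorphism
#' component).
#'
#' @return character vector of covariate names.
#' @export
agnor_covariate_menu <- function() {
  c("pT", "pN", "G",
    "nornbc_m", paste0("nor_k", 0:8),
    "snar_r_v", "center_v", "cent_r_v", "bord_r_v", "locat_v", "mnrat2_m",
    "pkt_grad", "polym")
}

#' Hazard structure for a synthetic survival cohort
#'
#' Specifies the exponential proportional-hazards model from which follow-up
#' is simulated: per-covariate log-hazard coefficients, a baseline event rate,
#' a censoring model (administrative horizon and/or independent exponential
#' censoring), and the proportion of deaths attributed to breast cancer.
#'
#' @param coefficients named numeric vector of true log-hazard ratios; names
#'   must belong to the covariate menu (`pT`, `pN`, `G`, `pkt_grad`, `polym`
#'   and the 15 AgNOR parameters). May be empty for a null cohort.
#' @param baseline_hazard baseline event rate in events per month (> 0).
#' @param admin_censor_months administrative censoring horizon in months, or
#'   `NULL` for none.
#' @param censor_rate rate of an independent exponential censoring process
#'   (per month), or `NULL`/0 for none.
#' @param cause_mix probability that an observed death is attributed to
#'   breast cancer rather than another cause.
#' @return An object of class `"cohort_effects"`.
#' @export
cohort_effects <- function(coefficients = numeric(0),
                           baseline_hazard = 0.003,
                           admin_censor_months = NULL,
                           censor_rate = NULL,
                           cause_mix = 0.57) {
  if (length(coefficients)) {
    if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
      stop("coefficients must be a named numeric vector")
    }
    bad <- setdiff(names(coefficients), agnor_covariate_menu())
    if (length(bad)) {
      stop("unknown covariate name(s) in effects: ", paste(bad, collapse = ", "))
    }
  }
  stopifnot(baseline_hazard > 0, cause_mix >= 0, cause_mix <= 1)
  if (!is.null(admin_censor_months)) stopifnot(admin_censor_months > 0)
  if (!is.null(censor_rate)) stopifnot(censor_rate >= 0)
  structure(list(
    coefficients = coefficients,
    baseline_hazard = baseline_hazard,
    admin_censor_months = admin_censor_months,
    censor_rate = censor_rate,
    cause_mix = cause_mix
  ), class = "cohort_effects")
}

#' @export
print.cohort_effects <- function(x, ...) {
  cat("Synthetic cohort hazard structure\n")
  cat(sprintf("  baseline hazard : %g events/month\n", x$baseline_hazard))
  if (length(x$coefficients)) {
    cat("  log-hazard coefficients:\n")
    for (nm in names(x$coefficients)) {
      cat(sprintf("    %-10s %+.3f (HR %.2f)\n", nm, x$coefficients[[nm]],
                  exp(x$coefficients[[nm]])))
    }
  } else {
    cat("  no covariate effects (null cohort)\n")
  }
  cat(sprintf("  censoring       : admin %s months, exponential rate %s\n",
              if (is.null(x$admin_censor_months)) "none" else format(x$admin_censor_months),
              if (is.null(x$censor_rate)) "none" else format(x$censor_rate)))
  cat(sprintf("  cause mix       : %.0f%% of deaths attributed to breast cancer\n",
              100 * x$cause_mix))
  invisible(x)
}
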