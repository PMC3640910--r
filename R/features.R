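#' Nuclear zone definition for positional AgNOR features
#'
#' The nucleus is partitioned by the normalised radial position `d_norm`:
#' particles with `d_norm <= central` are central, particles with
#' `d_norm >= peripheral` lie in the peripheral (border) zone.
#'
#' @param central central cutoff on `d_norm` (default 0.5).
#' @param peripheral peripheral cutoff on `d_norm` (default 0.8).
#' @return An object of class `"zone_definition"`.
#' @export
zone_definition <- function(central = 0.5, peripheral = 0.8) {
  stopifnot(central > 0, peripheral < 1, central < peripheral)
  structure(list(central = central, peripheral = peripheral),
            class = "zone_definition")
}

#' Per-nucleus AgNOR feature summaries
#'
#' Computes, for one nucleus record, the conglomerate-corrected AgNOR count,
#' the per-mille area fractions of its particles (particle area over total
#' AgNOR area, times 1000), the within-nucleus dispersion of those fractions,
#' the largest-to-total area ratio (per mille), and the proportions of
#' particles in the central and peripheral zones. A nucleus without particles
#' yields count 0 with the area and zone statistics flagged missing (`NA`).
#'
#' Within-nucleus dispersion uses the population (divide-by-n) standard
#' deviation so a single-particle nucleus has dispersion 0.
#'
#' @param record a `"nucleus_record"` from [detect_agnors()].
#' @param zones a [zone_definition()].
#' @return An object of class `"nucleus_feature_row"`: list with
#'   `nucleus_id`, `n_components`, `corrected_count`, `area_fractions_pm`,
#'   `snar_sd`, `largest_ratio_pm`, `prop_central`, `prop_peripheral`,
#'   `d_norms`.
#' @export
nucleus_features <- function(record, zones = zone_definition()) {
  stopifnot(inherits(record, "nucleus_record"), inherits(zones, "zone_definition"))
  p <- record$particles
  n_comp <- nrow(p)
  if (n_comp == 0L) {
    row <- list(nucleus_id = record$nucleus_id, n_components = 0L,
                corrected_count = 0L, area_fractions_pm = numeric(0),
                snar_sd = NA_real_, largest_ratio_pm = NA_real_,
                prop_central = NA_real_, prop_peripheral = NA_real_,
                d_norms = numeric(0))
    return(structure(row, class = "nucleus_feature_row"))
  }
  if (any(is.na(p$corrected_count))) {
    stop("nucleus record has unassigned conglomerate counts; run detection ",
         "with a reference area (see detect_case)")
  }
  total <- sum(p$area_um2)
  frac_pm <- p$area_um2 / total * 1000
  row <- list(
    nucleus_id = record$nucleus_id,
    n_components = n_comp,
    corrected_count = as.integer(sum(p$corrected_count)),
    area_fractions_pm = frac_pm,
    snar_sd = sd_pop(frac_pm),
    largest_ratio_pm = max(p$area_um2) / total * 1000,
    prop_central = mean(p$d_norm <= zones$central),
    prop_peripheral = mean(p$d_norm >= zones$peripheral),
    d_norms = p$d_norm
  )
  structure(row, class = "nucleus_feature_row")
}

#' Case-level AgNOR feature vector
#'
#' Aggregates per-nucleus feature rows into the 15-parameter case-level
#' vector used as prognostic covariates:
#'
#' * `nornbc_m` — mean conglomerate-corrected AgNOR count per nucleus;
#' * `nor_k0` .. `nor_k8` — percentage of nuclei containing exactly k AgNORs
#'   (corrected counts);
#' * `snar_r_v` — mean over nuclei of the within-nucleus SD of the per-mille
#'   single-AgNOR area fractions;
#' * `mnrat2_m` — mean over nuclei of the largest-to-total AgNOR area ratio
#'   in per mille;
#' * `cent_r_v` / `bord_r_v` — SD across nuclei of the proportion of
#'   particles in the central / peripheral zone;
#' * `center_v` — SD of `d_norm` over all centrally located particles pooled
#'   across nuclei;
#' * `locat_v` — variance of `d_norm` over all particles pooled across
#'   nuclei.
#'
#' Nuclei with zero particles enter the count-class percentages (as count 0)
#' but are excluded from the area and zone aggregates.
#'
#' @param rows list of `"nucleus_feature_row"` (non-empty), or an
#'   `"agnor_case"` whose records are summarised first.
#' @param zones a [zone_definition()]; needed for `center_v`.
#' @return one-row data frame with the columns above plus `n_nuclei`.
#' @export
#' @examples
#' sc <- scenario_preset("low_variability", n_nuclei = 8)
#' fs <- generate_image_set(sc, seed = 3)
#' det <- detect_case(fs$image, fs$mask, detect_params())
#' case_features(det)
case_features <- function(rows, zones = zone_definition()) {
  if (inherits(rows, "agnor_case")) {
    rows <- lapply(rows$records, nucleus_features, zones = zones)
  }
  if (!length(rows)) stop("no nuclei: cannot compute case features")
  rows <- lapply(rows, function(r) {
    if (inherits(r, "nucleus_record")) nucleus_features(r, zones) else r
  })
  stopifnot(all(vapply(rows, inherits, TRUE, "nucleus_feature_row")))
  counts <- vapply(rows, function(r) r$corrected_count, 0L)
  n_nuc <- length(rows)
  nor_k <- vapply(0:8, function(k) 100 * sum(counts == k) / n_nuc, 0)
  names(nor_k) <- paste0("nor_k", 0:8)

  with_p <- rows[vapply(rows, function(r) r$n_components > 0L, TRUE)]
  if (length(with_p)) {
    snar_r_v <- mean(vapply(with_p, function(r) r$snar_sd, 0))
    mnrat2_m <- mean(vapply(with_p, function(r) r$largest_ratio_pm, 0))
    cent_r_v <- sd_sample0(vapply(with_p, function(r) r$prop_central, 0))
    bord_r_v <- sd_sample0(vapply(with_p, function(r) r$prop_peripheral, 0))
    dn_all <- unlist(lapply(with_p, function(r) r$d_norms))
    locat_v <- var_pop(dn_all)
    dn_central <- dn_all[dn_all <= zones$central]
    center_v <- if (length(dn_central) >= 2L) sd_pop(dn_central) else 0
  } else {
    snar_r_v <- mnrat2_m <- cent_r_v <- bord_r_v <- locat_v <- center_v <- NA_real_
  }
  out <- data.frame(
    nornbc_m = mean(counts),
    t(nor_k),
    snar_r_v = snar_r_v, center_v = center_v, cent_r_v = cent_r_v,
    bord_r_v = bord_r_v, locat_v = locat_v, mnrat2_m = mnrat2_m,
    n_nuclei = n_nuc
  )
  rownames(out) <- NULL
  out
}

#' Case features computed directly from synthetic ground truth
#'
#' Bypasses image rendering and detection: conglomerate groups are collapsed
#' into one effective particle (summed member areas, area-weighted mean
#' `d_norm`) whose corrected count is the true multiplicity, mirroring what a
#' perfect detector would measure, and the case-level vector is aggregated
#' with the same rules as [case_features()]. Useful as the ground-truth
#' reference in recovery checks and for fast large-scale simulation.
#'
#' @param image_set an `"agnor_image_set"`.
#' @param zones a [zone_definition()].
#' @return one-row data frame as in [case_features()].
#' @export
features_from_ground_truth <- function(image_set, zones = zone_definition()) {
  stopifnot(inherits(image_set, "agnor_image_set"))
  gt <- image_set$ground_truth
  rows <- lapply(image_set$nuclei$nucleus_id, function(nid) {
    p <- gt[gt$nucleus_id == nid, , drop = FALSE]
    if (!nrow(p)) {
      rec <- structure(list(nucleus_id = nid, area_um2 = 1,
                            centroid_um = c(x = 0, y = 0), boundary_px = NULL,
                            reference_area = NA_real_, threshold_used = NA_real_,
                            particles = empty_particles()),
                       class = "nucleus_record")
      return(nucleus_features(rec, zones))
    }
    grp <- ifelse(is.na(p$conglomerate_group), -seq_len(nrow(p)),
                  p$conglomerate_group)
    agg <- lapply(split(p, grp), function(q) {
      data.frame(area_um2 = sum(q$area_um2),
                 d_norm = sum(q$d_norm * q$area_um2) / sum(q$area_um2),
                 corrected_count = nrow(q))
    })
    agg <- do.call(rbind, agg)
    part <- data.frame(particle_id = seq_len(nrow(agg)),
                       area_um2 = agg$area_um2, x_um = 0, y_um = 0,
                       d_norm = agg$d_norm,
                       is_conglomerate = agg$corrected_count > 1L,
                       corrected_count = as.integer(agg$corrected_count))
    ord <- order(-part$area_um2, part$d_norm)
    part <- part[ord, , drop = FALSE]
    rec <- structure(list(nucleus_id = nid, area_um2 = 1,
                          centroid_um = c(x = 0, y = 0), boundary_px = NULL,
                          reference_area = NA_real_, threshold_used = NA_real_,
                          particles = part),
                     class = "nucleus_record")
    nucleus_features(rec, zones)
  })
  case_features(rows, zones)
}

empty_particles <- function() {
  data.frame(particle_id = integer(0), area_um2 = numeric(0),
             x_um = numeric(0), y_um = numeric(0), d_norm = numeric(0),
             is_conglomerate = logical(0), corrected_count = integer(0))
}

#' Feature table for a set of cases
#'
#' @param case_list list of `"agnor_case"` objects.
#' @param zones a [zone_definition()].
#' @return data frame with `case_id` and one feature row per case.
#' @export
case_feature_table <- function(case_list, zones = zone_definition()) {
  stopifnot(length(case_list) > 0)
  rows <- lapply(case_list, function(cs) {
    cbind(data.frame(case_id = cs$case_id), case_features(cs, zones))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
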