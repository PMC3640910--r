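# Hand-built image fixtures and independent oracles used across the suite.

# Paint an anti-aliased dark disk onto an integer image matrix.
paint_disk <- function(img, cy, cx, r_px, level, base_level) {
  d <- sqrt(outer(((seq_len(nrow(img)) - 1) - cy)^2,
                  ((seq_len(ncol(img)) - 1) - cx)^2, `+`))
  cov <- pmin(1, pmax(0, r_px + 0.5 - d))
  out <- img + cov * (level - base_level)
  storage.mode(out) <- "integer"
  out
}

# One circular nucleus mask plus dark disks at given (cy, cx, r) in pixels.
make_nucleus_image <- function(size = 48, nucleus_r = 20, disks = NULL,
                               background = 210, nucleus_level = 160,
                               particle_level = 60) {
  ctr <- (size - 1) / 2
  d <- sqrt(outer(((seq_len(size) - 1) - ctr)^2,
                  ((seq_len(size) - 1) - ctr)^2, `+`))
  mask <- d <= nucleus_r
  img <- matrix(background, size, size)
  img[mask] <- nucleus_level
  storage.mode(img) <- "integer"
  if (!is.null(disks)) {
    for (i in seq_len(nrow(disks))) {
      img <- paint_disk(img, disks[i, 1], disks[i, 2], disks[i, 3],
                        particle_level, nucleus_level)
    }
  }
  list(image = img, mask = mask, center = c(ctr, ctr))
}

# A synthetic nucleus record built directly (no image), for feature tests.
make_record <- function(areas, d_norms, corrected = NULL, nucleus_id = 1L) {
  n <- length(areas)
  if (is.null(corrected)) corrected <- rep(1L, n)
  p <- data.frame(particle_id = seq_len(n), area_um2 = areas,
                  x_um = numeric(n), y_um = numeric(n), d_norm = d_norms,
                  is_conglomerate = corrected > 1L,
                  corrected_count = as.integer(corrected))
  structure(list(nucleus_id = nucleus_id, area_um2 = 100,
                 centroid_um = c(x = 0, y = 0), boundary_px = NULL,
                 reference_area = if (n) stats::median(areas) else NA_real_,
                 threshold_used = 110, particles = p),
            class = "nucleus_record")
}

# Brute-force Kaplan-Meier: direct risk-set enumeration, independent of
# survival::survfit.
km_oracle <- function(time, status) {
  ut <- sort(unique(time))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    t <- ut[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & status == 1)
    if (n_risk > 0) s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ut, survival = surv)
}

# Brute-force case features computed straight off the ground-truth table by
# plain loops: conglomerate groups are merged (summed areas, area-weighted
# d_norm, multiplicity = member count) and the case-level statistics are
# re-derived from first principles, independently of nucleus_features() /
# case_features().
oracle_features_from_gt <- function(gt, nuclei, central = 0.5, peripheral = 0.8) {
  counts <- c(); snar <- c(); mrat <- c(); pc <- c(); pp <- c(); dns <- c()
  for (nid in nuclei$nucleus_id) {
    p <- gt[gt$nucleus_id == nid, ]
    if (nrow(p) == 0) { counts <- c(counts, 0); next }
    key <- ifelse(is.na(p$conglomerate_group), paste0("s", seq_len(nrow(p))),
                  paste0("g", p$conglomerate_group))
    areas <- c(); dn <- c(); mult <- c()
    for (k in unique(key)) {
      q <- p[key == k, ]
      areas <- c(areas, sum(q$area_um2))
      dn <- c(dn, sum(q$d_norm * q$area_um2) / sum(q$area_um2))
      mult <- c(mult, nrow(q))
    }
    counts <- c(counts, sum(mult))
    fr <- areas / sum(areas) * 1000
    snar <- c(snar, sqrt(mean((fr - mean(fr))^2)))
    mrat <- c(mrat, max(areas) / sum(areas) * 1000)
    pc <- c(pc, mean(dn <= central))
    pp <- c(pp, mean(dn >= peripheral))
    dns <- c(dns, dn)
  }
  n <- length(counts)
  nor_k <- sapply(0:8, function(k) 100 * sum(counts == k) / n)
  dcentral <- dns[dns <= central]
  list(
    nornbc_m = mean(counts),
    nor_k = nor_k,
    snar_r_v = mean(snar),
    mnrat2_m = mean(mrat),
    cent_r_v = if (length(pc) >= 2) stats::sd(pc) else 0,
    bord_r_v = if (length(pp) >= 2) stats::sd(pp) else 0,
    locat_v = mean((dns - mean(dns))^2),
    center_v = if (length(dcentral) >= 2) {
      sqrt(mean((dcentral - mean(dcentral))^2))
    } else 0
  )
}

# Scenario used for exact recovery checks: noise-free, narrow particle size
# range, no conglomerates, so every rendered particle is a disjoint disk.
disjoint_scenario <- function(n_nuclei = 20, ...) {
  scenario_preset("low_variability", n_nuclei = n_nuclei,
                  conglomerate_probability = 0, noise_sd = 0, ...)
}
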