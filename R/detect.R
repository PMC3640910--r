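#' Detection parameters for AgNOR particles
#'
#' @param threshold `"otsu"` for a per-nucleus Otsu threshold on the
#'   within-mask intensities, or `"fixed"` for a global grey level.
#' @param fixed_level grey level in 0--255; pixels at or below it are
#'   particle candidates (required when `threshold = "fixed"`).
#' @param min_area_um2 minimum particle area; defaults to two pixels' area at
#'   the given calibration, suppressing single-pixel noise.
#' @param kappa conglomerate area factor (dimensionless, > 1): a particle
#'   whose area exceeds `kappa` times the reference single-AgNOR area is
#'   recorded as a conglomerate and its count corrected by area ratio.
#' @param min_contrast minimum separation (grey levels) between the mean
#'   intensities of the two Otsu classes for the dark class to be accepted as
#'   particles; guards against splitting pure noise in particle-free nuclei.
#' @param calibration pixel size in um per pixel.
#' @return An object of class `"detect_params"`.
#' @export
detect_params <- function(threshold = c("otsu", "fixed"), fixed_level = NULL,
                          min_area_um2 = NULL, kappa = 1.5,
                          min_contrast = 20, calibration = 0.25) {
  threshold <- match.arg(threshold)
  stopifnot(calibration > 0, kappa > 1, min_contrast >= 0)
  if (threshold == "fixed") {
    if (is.null(fixed_level)) stop("fixed threshold requires fixed_level")
    stopifnot(fixed_level >= 0, fixed_level <= 255)
  }
  px_area <- calibration^2
  if (is.null(min_area_um2)) min_area_um2 <- 2 * px_area
  if (min_area_um2 < px_area) {
    stop("min_area_um2 must be at least one pixel's area (", px_area, " um2)")
  }
  structure(list(threshold = threshold, fixed_level = fixed_level,
                 min_area_um2 = min_area_um2, kappa = kappa,
                 min_contrast = min_contrast, calibration = calibration),
            class = "detect_params")
}

#' Detect AgNOR particles inside one nucleus mask
#'
#' Particles are the connected components (4-connectivity) of below-threshold
#' pixels within the externally supplied nucleus mask, filtered by minimum
#' area. Areas are pixel counts times the squared calibration; centroids are
#' unweighted means of pixel centres (0-based row/col, converted to um); the
#' normalised radial position `d_norm` of each particle is its centroid
#' distance from the nucleus centroid divided by the centroid-to-boundary
#' distance along the same ray, so it is shape-independent and `0` for a
#' particle at the centroid. Particles are sorted by descending area with a
#' lexicographic (y, x) centroid tie-break.
#'
#' Conglomerate status is assigned by comparing each particle's area with a
#' reference single-AgNOR area: either supplied (typically estimated across
#' the whole case by [estimate_reference_area()]) or estimated from this
#' nucleus's own particles.
#'
#' @param image integer matrix of grey values 0--255.
#' @param nucleus_mask logical or 0/1 matrix of the same dimensions marking
#'   the nucleus; must be nonempty.
#' @param params a [detect_params()].
#' @param nucleus_id identifier stored on the record.
#' @param reference_area single-AgNOR reference area in um2, or `NULL` to
#'   estimate it from the detected particles.
#' @return An object of class `"nucleus_record"`: list with `nucleus_id`,
#'   `area_um2` (mask area), `centroid_um`, `boundary_px` (mask-edge pixel
#'   coordinates), `reference_area`, `threshold_used` and `particles` (data
#'   frame with `particle_id`, `area_um2`, `x_um`, `y_um`, `d_norm`,
#'   `is_conglomerate`, `corrected_count`).
#' @export
detect_agnors <- function(image, nucleus_mask, params = detect_params(),
                          nucleus_id = 1L, reference_area = NULL) {
  stopifnot(inherits(params, "detect_params"))
  if (!all(dim(image) == dim(nucleus_mask))) {
    stop("image and nucleus mask dimensions differ")
  }
  m <- nucleus_mask != 0
  idx <- which(m)
  if (!length(idx)) stop("nucleus mask is empty")
  cal <- params$calibration
  vals <- image[idx]

  thr <- NA_real_
  binary <- matrix(FALSE, nrow(image), ncol(image))
  if (params$threshold == "fixed") {
    thr <- params$fixed_level
    binary[idx] <- vals <= thr
  } else {
    # Otsu separates the dark (dot) and bright (nucleoplasm) classes; the
    # binarization level is then set midway between the dark-class core
    # level (5% quantile) and the bright-class mean, i.e. the half-depth
    # contour. This keeps measured areas at the 50%-coverage boundary of an
    # anti-aliased dot instead of wherever the raw Otsu split lands inside
    # the soft edge.
    t_otsu <- otsu_threshold(vals)
    lo <- vals[vals <= t_otsu]; hi <- vals[vals > t_otsu]
    if (length(lo) && length(hi) && mean(hi) - mean(lo) >= params$min_contrast) {
      thr <- floor((stats::quantile(lo, 0.05, names = FALSE) + mean(hi)) / 2)
      binary[idx] <- vals <= thr
    }  # otherwise: no credible dark class, nucleus has no particles
  }

  # nucleus geometry (0-based pixel centres -> um)
  rc <- arrayInd(idx, dim(m))
  cy <- mean(rc[, 1] - 1); cx <- mean(rc[, 2] - 1)
  centroid_um <- c(x = cx * cal, y = cy * cal)
  area_um2 <- length(idx) * cal^2
  boundary_px <- mask_boundary(m)

  particles <- data.frame(particle_id = integer(0), area_um2 = numeric(0),
                          x_um = numeric(0), y_um = numeric(0),
                          d_norm = numeric(0), is_conglomerate = logical(0),
                          corrected_count = integer(0))
  if (any(binary)) {
    lab <- EBImage::bwlabel(binary)
    nlab <- max(lab)
    rows <- list()
    for (l in seq_len(nlab)) {
      pidx <- which(lab == l)
      a <- length(pidx) * cal^2
      if (a < params$min_area_um2) next
      prc <- arrayInd(pidx, dim(m))
      py <- mean(prc[, 1] - 1); px <- mean(prc[, 2] - 1)
      dn <- dnorm_on_mask(m, c(cy, cx), c(py, px))
      rows[[length(rows) + 1L]] <- data.frame(
        area_um2 = a, x_um = px * cal, y_um = py * cal, d_norm = dn)
    }
    if (length(rows)) {
      particles <- do.call(rbind, rows)
      ord <- order(-particles$area_um2, particles$y_um, particles$x_um)
      particles <- particles[ord, , drop = FALSE]
      if (is.null(reference_area)) {
        reference_area <- estimate_reference_area(particles$area_um2, params$kappa)
      }
      if (is.na(reference_area)) {  # deferred: caller assigns case-level flags
        particles$is_conglomerate <- NA
        particles$corrected_count <- NA_integer_
      } else {
        particles$is_conglomerate <- particles$area_um2 > params$kappa * reference_area
        particles$corrected_count <- vapply(
          particles$area_um2, correct_count, 0L,
          reference_area = reference_area, kappa = params$kappa)
      }
      particles <- cbind(particle_id = seq_len(nrow(particles)), particles)
      rownames(particles) <- NULL
    }
  }
  structure(list(nucleus_id = nucleus_id, area_um2 = area_um2,
                 centroid_um = centroid_um, boundary_px = boundary_px,
                 reference_area = reference_area, threshold_used = thr,
                 particles = particles),
            class = "nucleus_record")
}

#' Detect AgNORs in every nucleus of a labelled field
#'
#' Runs [detect_agnors()] for each label of the nucleus mask. The
#' single-AgNOR reference area is estimated once across all particles of the
#' case (first pass without conglomerate flags, then [estimate_reference_area()]
#' on the pooled areas, then flags applied), so conglomerate status is
#' consistent across nuclei of the same section.
#'
#' @param image integer grey matrix.
#' @param label_mask integer label matrix (0 = background, k = nucleus k).
#' @param params a [detect_params()].
#' @param case_id identifier.
#' @return list of class `"agnor_case"`: `case_id`, `reference_area`,
#'   `records` (list of `"nucleus_record"`).
#' @export
detect_case <- function(image, label_mask, params = detect_params(),
                        case_id = "case1") {
  labs <- sort(setdiff(unique(as.integer(label_mask)), 0L))
  if (!length(labs)) stop("label mask contains no nuclei")
  records <- lapply(labs, function(l) {
    detect_agnors(image, label_mask == l, params, nucleus_id = l,
                  reference_area = NA_real_)  # flags assigned case-wide below
  })
  areas <- unlist(lapply(records, function(r) r$particles$area_um2))
  ref <- if (length(areas)) estimate_reference_area(areas, params$kappa) else NA_real_
  records <- lapply(records, function(r) {
    r$reference_area <- ref
    if (nrow(r$particles)) {
      r$particles$is_conglomerate <- r$particles$area_um2 > params$kappa * ref
      r$particles$corrected_count <- vapply(
        r$particles$area_um2, correct_count, 0L,
        reference_area = ref, kappa = params$kappa)
    }
    r
  })
  structure(list(case_id = case_id, reference_area = ref, records = records),
            class = "agnor_case")
}

#' Conglomerate-corrected particle count
#'
#' A particle whose area is at most `kappa` times the reference single-AgNOR
#' area counts as one AgNOR; a larger particle is a conglomerate and counts
#' as its area ratio rounded half up, never below two. Small particles never
#' count as zero.
#'
#' @param particle_area,reference_area areas in um2 (> 0).
#' @param kappa conglomerate area factor (> 1).
#' @return integer count (>= 1).
#' @export
#' @examples
#' correct_count(2.2, 1)  # 2
#' correct_count(0.4, 1)  # 1
correct_count <- function(particle_area, reference_area, kappa = 1.5) {
  if (!is.finite(particle_area) || particle_area <= 0) {
    stop("particle_area must be positive")
  }
  if (!is.finite(reference_area) || reference_area <= 0) {
    stop("reference_area must be positive")
  }
  stopifnot(kappa > 1)
  if (particle_area <= kappa * reference_area) return(1L)
  max(2L, as.integer(floor(particle_area / reference_area + 0.5)))
}

#' Estimate the reference single-AgNOR area of a case
#'
#' Robust to conglomerates: the reference is the median area of the particles
#' not exceeding `kappa` times the median of all areas (one exclusion pass,
#' deterministic).
#'
#' @param areas particle areas in um2 (>= 1 value, all > 0).
#' @param kappa conglomerate area factor.
#' @return reference area in um2.
#' @export
#' @examples
#' estimate_reference_area(c(1, 1, 1, 3))  # 1: the 3 is excluded
estimate_reference_area <- function(areas, kappa = 1.5) {
  if (!length(areas)) stop("no particles: cannot estimate reference area")
  if (any(!is.finite(areas) | areas <= 0)) stop("particle areas must be positive")
  med <- stats::median(areas)
  keep <- areas[areas <= kappa * med]
  if (!length(keep)) return(med)
  stats::median(keep)
}

# Normalised radial position of a point on a pixel mask: distance from the
# mask centroid divided by the centroid-to-boundary distance along the same
# ray, found by marching along the ray in quarter-pixel steps until leaving
# the mask. Coordinates are 0-based (row, col) pixel centres.
dnorm_on_mask <- function(mask, centroid_rc, point_rc) {
  d <- point_rc - centroid_rc
  len <- sqrt(sum(d^2))
  if (len == 0) return(0)
  u <- d / len
  step <- 0.25
  t <- 0
  repeat {
    t2 <- t + step
    p <- centroid_rc + t2 * u
    r <- as.integer(round(p[1])) + 1L
    c <- as.integer(round(p[2])) + 1L
    if (r < 1L || c < 1L || r > nrow(mask) || c > ncol(mask) || !mask[r, c]) break
    t <- t2
  }
  bdist <- t + step / 2
  min(len / bdist, 0.999)
}

# Mask-edge pixels: mask pixels with at least one 4-neighbour outside the
# mask (or on the image border). Returned as a 2-column (row, col) matrix of
# 0-based coordinates, a light-weight boundary polygon.
mask_boundary <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  core <- pad[2:(H + 1L), 2:(W + 1L)] &
    pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  edge <- m & !core
  rc <- arrayInd(which(edge), dim(m))
  cbind(row = rc[, 1] - 1L, col = rc[, 2] - 1L)
}

#' @export
print.nucleus_record <- function(x, ...) {
  cat(sprintf("Nucleus %s: area %.1f um2, %d particle(s), corrected count %d\n",
              format(x$nucleus_id), x$area_um2, nrow(x$particles),
              if (nrow(x$particles)) sum(x$particles$corrected_count) else 0L))
  if (nrow(x$particles)) {
    print(x$particles, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
print.agnor_case <- function(x, ...) {
  np <- sum(vapply(x$records, function(r) nrow(r$particles), 0L))
  cat(sprintf("AgNOR case '%s': %d nuclei, %d detected particles, reference area %.3f um2\n",
              x$case_id, length(x$records), np, x$reference_area))
  invisible(x)
}
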