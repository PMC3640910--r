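#' Render a synthetic silver-stained field with known AgNOR ground truth
#'
#' Generates one grayscale field containing `scenario$n_nuclei` elliptical
#' nuclei, each carrying dark AgNOR dots drawn from the scenario's count,
#' size and radial-position distributions, together with the matching nucleus
#' label mask and a per-particle ground-truth table. Conglomerates are
#' synthesised by placing 2--3 particles close enough (centre spacing below
#' the sum of radii) that they render as one connected component; the ground
#' truth records the true multiplicity.
#'
#' The output is a pure function of `(scenario, seed)`: each nucleus draws
#' from its own deterministic substream, so adding nuclei to a scenario does
#' not perturb the ones already generated.
#'
#' @param scenario an [image_scenario()].
#' @param seed integer seed.
#' @param case_id identifier recorded in the ground-truth table.
#' @param field_px optional `c(height, width)` in pixels. By default the
#'   field is sized so every nucleus fits on a jittered grid; when supplied,
#'   nuclei are placed at random without overlap and placement failure after
#'   bounded retries is an error (the field is too small).
#' @param render if `FALSE`, skip rasterisation and return only the ground
#'   truth (image and mask are `NULL`); the geometry and ground truth are
#'   identical to a rendered call with the same seed. Useful for large
#'   seed sweeps over ground-truth-level statistics.
#' @return An object of class `"agnor_image_set"`: a list with `image`
#'   (integer matrix, 0--255), `mask` (integer label matrix, 0 = background,
#'   k = nucleus k), `ground_truth` (data frame with columns `case_id`,
#'   `nucleus_id`, `particle_id`, `area_um2`, `x_um`, `y_um`, `d_norm`,
#'   `conglomerate_group`, `true_count`), `nuclei` (per-nucleus geometry),
#'   plus the scenario, seed and calibration.
#' @export
#' @examples
#' sc <- scenario_preset("low_variability", n_nuclei = 6)
#' fs <- generate_image_set(sc, seed = 1)
#' table(fs$nuclei$true_count)
generate_image_set <- function(scenario, seed, case_id = "case1",
                               field_px = NULL, render = TRUE) {
  stopifnot(inherits(scenario, "image_scenario"), length(seed) == 1L)
  cal <- scenario$calibration
  n <- scenario$n_nuclei
  amax_px <- scenario$nucleus_radius_range[2] / cal

  # -- nucleus geometry ------------------------------------------------------
  geom <- vector("list", n)
  for (k in seq_len(n)) {
    set.seed(substream_seed(seed, k))
    a_um <- stats::runif(1, scenario$nucleus_radius_range[1], scenario$nucleus_radius_range[2])
    ratio <- stats::runif(1, 0.6, 1.0)
    geom[[k]] <- list(a = a_um, b = a_um * ratio, phi = stats::runif(1, 0, pi),
                      jit = stats::runif(2, -1, 1))
  }

  if (is.null(field_px)) {
    cell <- ceiling(2 * (amax_px + 4))
    ncc <- ceiling(sqrt(n))
    nrc <- ceiling(n / ncc)
    H <- nrc * cell; W <- ncc * cell
    for (k in seq_len(n)) {
      i <- (k - 1) %/% ncc; j <- (k - 1) %% ncc
      a_px <- geom[[k]]$a / cal
      free <- max(0, cell / 2 - a_px - 2)
      geom[[k]]$y0 <- i * cell + (cell - 1) / 2 + geom[[k]]$jit[1] * free
      geom[[k]]$x0 <- j * cell + (cell - 1) / 2 + geom[[k]]$jit[2] * free
    }
  } else {
    stopifnot(length(field_px) == 2L, all(field_px >= 1))
    H <- field_px[1]; W <- field_px[2]
    for (k in seq_len(n)) {
      set.seed(substream_seed(seed, 500000 + k))
      a_px <- geom[[k]]$a / cal
      placed <- FALSE
      for (try in seq_len(200L)) {
        if (H - 1 - a_px - 2 < a_px + 2 || W - 1 - a_px - 2 < a_px + 2) break
        y0 <- stats::runif(1, a_px + 2, H - 1 - a_px - 2)
        x0 <- stats::runif(1, a_px + 2, W - 1 - a_px - 2)
        ok <- TRUE
        for (m in seq_len(k - 1)) {
          dm <- sqrt((y0 - geom[[m]]$y0)^2 + (x0 - geom[[m]]$x0)^2)
          if (dm < a_px + geom[[m]]$a / cal + 3) { ok <- FALSE; break }
        }
        if (ok) { geom[[k]]$y0 <- y0; geom[[k]]$x0 <- x0; placed <- TRUE; break }
      }
      if (!placed) {
        stop("unable to place nucleus ", k, " after bounded retries: field ",
             H, "x", W, " px is too small for ", n, " nuclei")
      }
    }
  }

  # -- particles per nucleus -------------------------------------------------
  gt <- list()
  for (k in seq_len(n)) {
    set.seed(substream_seed(seed, 100000 + k))
    g <- geom[[k]]
    center_um <- c(x = g$x0 * cal, y = g$y0 * cal)
    k_true <- sample(0:12, 1, prob = scenario$agnor_count_distribution)
    geom[[k]]$true_count <- k_true
    parts <- gen_nucleus_particles(scenario, g, center_um, k_true, k)
    geom[[k]]$particles <- parts
    if (nrow(parts)) {
      parts$case_id <- case_id
      parts$nucleus_id <- k
      parts$true_count <- k_true
      gt[[length(gt) + 1L]] <- parts
    }
  }
  ground_truth <- if (length(gt)) {
    do.call(rbind, gt)[, c("case_id", "nucleus_id", "particle_id", "area_um2",
                           "x_um", "y_um", "d_norm", "conglomerate_group",
                           "true_count")]
  } else {
    data.frame(case_id = character(0), nucleus_id = integer(0),
               particle_id = integer(0), area_um2 = numeric(0),
               x_um = numeric(0), y_um = numeric(0), d_norm = numeric(0),
               conglomerate_group = integer(0), true_count = integer(0))
  }
  rownames(ground_truth) <- NULL

  # -- rasterise -------------------------------------------------------------
  if (!render) {
    nuclei <- data.frame(
      nucleus_id = seq_len(n),
      x_um = vapply(geom, function(g) g$x0 * cal, 0),
      y_um = vapply(geom, function(g) g$y0 * cal, 0),
      a_um = vapply(geom, function(g) g$a, 0),
      b_um = vapply(geom, function(g) g$b, 0),
      phi = vapply(geom, function(g) g$phi, 0),
      true_count = vapply(geom, function(g) as.integer(g$true_count), 0L)
    )
    return(structure(list(image = NULL, mask = NULL,
                          ground_truth = ground_truth, nuclei = nuclei,
                          scenario = scenario, seed = seed, case_id = case_id,
                          calibration = cal),
                     class = "agnor_image_set"))
  }
  img <- matrix(scenario$background_intensity, H, W)
  mask <- matrix(0L, H, W)
  cov <- matrix(0, H, W)
  for (k in seq_len(n)) {
    g <- geom[[k]]
    a_px <- g$a / cal; b_px <- g$b / cal
    rr <- max(1L, floor(g$y0 - a_px)):min(H, ceiling(g$y0 + a_px) + 2L)
    cc <- max(1L, floor(g$x0 - a_px)):min(W, ceiling(g$x0 + a_px) + 2L)
    py <- (rr - 1) - g$y0
    px <- (cc - 1) - g$x0
    cphi <- cos(g$phi); sphi <- sin(g$phi)
    u <- (outer(py, px, function(y, x) (cphi * x + sphi * y))) / a_px
    v <- (outer(py, px, function(y, x) (-sphi * x + cphi * y))) / b_px
    inside <- (u^2 + v^2) <= 1
    sub_m <- mask[rr, cc]; sub_m[inside] <- k; mask[rr, cc] <- sub_m
    sub_i <- img[rr, cc]; sub_i[inside] <- scenario$nucleus_intensity; img[rr, cc] <- sub_i
    p <- g$particles
    for (q in seq_len(nrow(p))) {
      r_px <- p$r_um[q] / cal
      cy <- p$y_um[q] / cal; cx <- p$x_um[q] / cal
      pr <- max(1L, floor(cy - r_px)):min(H, ceiling(cy + r_px) + 2L)
      pc <- max(1L, floor(cx - r_px)):min(W, ceiling(cx + r_px) + 2L)
      d <- sqrt(outer(((pr - 1) - cy)^2, ((pc - 1) - cx)^2, `+`))
      cq <- pmin(1, pmax(0, r_px + 0.5 - d))
      cov[pr, pc] <- pmax(cov[pr, pc], cq)
    }
  }
  img <- img + cov * (scenario$particle_intensity - scenario$nucleus_intensity)
  if (scenario$noise_sd > 0) {
    set.seed(substream_seed(seed, 999983))
    img <- img + stats::rnorm(length(img), 0, scenario$noise_sd)
  }
  img <- round(img)
  img[img < 0] <- 0; img[img > 255] <- 255
  storage.mode(img) <- "integer"

  nuclei <- data.frame(
    nucleus_id = seq_len(n),
    x_um = vapply(geom, function(g) g$x0 * cal, 0),
    y_um = vapply(geom, function(g) g$y0 * cal, 0),
    a_um = vapply(geom, function(g) g$a, 0),
    b_um = vapply(geom, function(g) g$b, 0),
    phi = vapply(geom, function(g) g$phi, 0),
    true_count = vapply(geom, function(g) as.integer(g$true_count), 0L)
  )

  structure(list(image = img, mask = mask, ground_truth = ground_truth,
                 nuclei = nuclei, scenario = scenario, seed = seed,
                 case_id = case_id, calibration = cal),
            class = "agnor_image_set")
}

# Distance from the ellipse centre to its boundary along direction theta,
# for semi-axes a, b (um) rotated by phi.
ellipse_boundary_dist <- function(a, b, phi, theta) {
  dx <- cos(theta); dy <- sin(theta)
  c1 <- (cos(phi) * dx + sin(phi) * dy) / a
  c2 <- (-sin(phi) * dx + cos(phi) * dy) / b
  1 / sqrt(c1^2 + c2^2)
}

draw_dnorm <- function(rpd) {
  if (rpd$type == "uniform") stats::runif(1, rpd$min, rpd$max)
  else stats::rbeta(1, rpd$shape1, rpd$shape2)
}

# Place the particles of one nucleus. Placement events are either singletons
# or conglomerates of 2-3 particles whose centres sit at 0.75 * (sum of radii)
# so the rendered disks merge; distinct events keep >= 2 px clearance so they
# never merge with each other. Coordinates in um, absolute in the field.
gen_nucleus_particles <- function(scenario, g, center_um, k_true, nucleus_id) {
  rr <- scenario$agnor_radius_range
  rpd <- scenario$radial_position_distribution
  cal <- scenario$calibration
  margin <- 1.5 * cal
  sep <- 2 * cal
  out <- data.frame(particle_id = integer(0), area_um2 = numeric(0),
                    x_um = numeric(0), y_um = numeric(0), d_norm = numeric(0),
                    conglomerate_group = integer(0), r_um = numeric(0),
                    group_tag = integer(0))
  if (k_true == 0L) return(out)
  remaining <- k_true
  group_id <- 0L
  pid <- 0L
  placed <- list()  # each: x, y, r, tag
  while (remaining > 0L) {
    group_id <- group_id + 1L
    size <- 1L
    if (remaining >= 2L && stats::runif(1) < scenario$conglomerate_probability) {
      size <- sample(2:min(3L, remaining), 1L)
    }
    members <- list()
    # anchor; crowded nuclei progressively shrink the candidate radius toward
    # the range minimum (dots compete for space) before giving up
    ok <- FALSE
    rmax <- rr[2]
    for (try in seq_len(600L)) {
      if (try %% 100L == 0L) rmax <- max(rr[1], 0.7 * rmax)
      theta <- stats::runif(1, 0, 2 * pi)
      r_p <- stats::runif(1, rr[1], rmax)
      R <- ellipse_boundary_dist(g$a, g$b, g$phi, theta)
      dmax <- R - r_p - margin
      if (dmax <= 0) next
      dist <- min(draw_dnorm(rpd) * R, dmax)
      # crowding relaxation: once the preferred radial band is exhausted,
      # fall back to any feasible radius (dots get pushed outward)
      if (try > 200L) dist <- stats::runif(1, 0, dmax)
      pos <- center_um + dist * c(cos(theta), sin(theta))
      if (clear_of_others(pos, r_p, placed, group_id, sep)) {
        members[[1L]] <- list(x = pos[1], y = pos[2], r = r_p)
        ok <- TRUE; break
      }
    }
    if (!ok) stop("unable to place AgNOR particle in nucleus ", nucleus_id,
                  " after bounded retries")
    if (size > 1L) {
      for (m in 2:size) {
        okm <- FALSE
        rmax <- rr[2]
        for (try in seq_len(300L)) {
          if (try %% 100L == 0L) rmax <- max(rr[1], 0.7 * rmax)
          ref <- members[[sample.int(length(members), 1L)]]
          r_i <- stats::runif(1, rr[1], rmax)
          ang <- stats::runif(1, 0, 2 * pi)
          d <- 0.75 * (ref$r + r_i)
          pos <- c(ref$x + d * cos(ang), ref$y + d * sin(ang))
          rel <- pos - center_um
          dc <- sqrt(sum(rel^2))
          th <- atan2(rel[2], rel[1])
          R <- ellipse_boundary_dist(g$a, g$b, g$phi, th)
          if (dc + r_i > R - margin) next
          if (!clear_of_others(pos, r_i, placed, group_id, sep)) next
          members[[m]] <- list(x = pos[1], y = pos[2], r = r_i)
          okm <- TRUE; break
        }
        if (!okm) { size <- m - 1L; break }  # conglomerate degrades gracefully
      }
    }
    for (m in seq_along(members)) {
      mb <- members[[m]]
      pid <- pid + 1L
      rel <- c(mb$x, mb$y) - center_um
      dc <- sqrt(sum(rel^2))
      dn <- if (dc == 0) 0 else {
        dc / ellipse_boundary_dist(g$a, g$b, g$phi, atan2(rel[2], rel[1]))
      }
      out <- rbind(out, data.frame(
        particle_id = pid, area_um2 = pi * mb$r^2, x_um = mb$x, y_um = mb$y,
        d_norm = dn,
        conglomerate_group = if (length(members) > 1L) group_id else NA_integer_,
        r_um = mb$r, group_tag = group_id))
      placed[[length(placed) + 1L]] <- list(x = mb$x, y = mb$y, r = mb$r,
                                            tag = group_id)
    }
    remaining <- remaining - length(members)
  }
  out
}

clear_of_others <- function(pos, r, placed, group_id, sep) {
  for (p in placed) {
    if (p$tag == group_id) next
    if (sqrt((pos[1] - p$x)^2 + (pos[2] - p$y)^2) < r + p$r + sep) return(FALSE)
  }
  TRUE
}

#' Write a synthetic image set to disk
#'
#' Writes the grayscale field as an 8-bit TIFF, the nucleus label mask as a
#' 16-bit TIFF and the ground truth as CSV. Identical inputs produce
#' bit-identical files.
#'
#' @param x an `"agnor_image_set"`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; defaults to the case id.
#' @return Invisibly, the named vector of paths written.
#' @export
write_image_set <- function(x, dir, prefix = x$case_id) {
  stopifnot(inherits(x, "agnor_image_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    image = file.path(dir, paste0(prefix, "_image.tif")),
    mask = file.path(dir, paste0(prefix, "_mask.tif")),
    ground_truth = file.path(dir, paste0(prefix, "_ground_truth.csv"))
  )
  tiff::writeTIFF(x$image / 255, paths[["image"]], bits.per.sample = 8,
                  compression = "none")
  tiff::writeTIFF(x$mask / 65535, paths[["mask"]], bits.per.sample = 16,
                  compression = "none")
  utils::write.csv(x$ground_truth, paths[["ground_truth"]], row.names = FALSE)
  invisible(paths)
}

#' Read a grayscale field and its nucleus label mask from TIFF
#'
#' @param image_path 8-bit grayscale TIFF.
#' @param mask_path 16-bit label TIFF (0 = background, k = nucleus k).
#' @return list with integer matrices `image` (0--255) and `mask`.
#' @export
read_image_pair <- function(image_path, mask_path) {
  img <- round(tiff::readTIFF(image_path) * 255)
  msk <- round(tiff::readTIFF(mask_path) * 65535)
  storage.mode(img) <- "integer"
  storage.mode(msk) <- "integer"
  if (!all(dim(img) == dim(msk))) stop("image and mask dimensions differ")
  list(image = img, mask = msk)
}

#' @export
print.agnor_image_set <- function(x, ...) {
  size <- if (is.null(x$image)) "unrendered" else {
    sprintf("%dx%d px", nrow(x$image), ncol(x$image))
  }
  cat(sprintf("Synthetic AgNOR field '%s': %s (%.2f um/px), %d nuclei, %d particles\n",
              x$case_id, size, x$calibration,
              nrow(x$nuclei), nrow(x$ground_truth)))
  invisible(x)
}
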