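# Internal numeric helpers shared across modules.

# Round half away from zero (the convention of classic statistical report
# tables, as opposed to R's banker's rounding).
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a percentage the way SPSS-era report tables print it
#'
#' Rounds half away from zero to one decimal and suppresses the leading zero
#' for values below 1 (`0.4` prints as `".4%"`).
#'
#' @param p numeric vector of percentages (already on the 0--100 scale).
#' @return character vector like `"33.2%"`, `".4%"`, `"100.0%"`.
#' @export
#' @examples
#' format_percent(c(33.19672, 0.4098, 100))
format_percent <- function(p) {
  r <- round_half_away(p, 1)
  out <- sprintf("%.1f%%", r)
  small <- abs(r) < 1 & r != 0
  out[small] <- sub("^0", "", out[small])
  out[r == 0] <- ".0%"
  out
}

# Otsu's threshold on a vector of 8-bit intensities.  Returns the level t that
# maximises between-class variance for the split {0..t} vs {t+1..255}; callers
# classify "dark" pixels as intensity <= t.  Written on the intensity vector
# because the standard image-level implementations cannot be restricted to the
# pixels of one nucleus mask.
otsu_threshold <- function(v) {
  v <- as.integer(round(v))
  v[v < 0L] <- 0L
  v[v > 255L] <- 255L
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256L]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  which.max(sb2) - 1L
}

# Deterministic substream seed: a fixed mixing function of (seed, k) so that
# per-nucleus / per-case streams do not shift when the number of nuclei or
# cases changes.  Exact in double arithmetic (products stay below 2^53).
substream_seed <- function(seed, k) {
  s <- (abs(as.numeric(seed)) %% 2147483647) * 48271 + as.numeric(k) * 40503 + 1
  as.integer(s %% 2147483647)
}

# Population (divide-by-n) standard deviation / variance: used for pooled and
# within-nucleus dispersion so single-observation sets are well-defined (0).
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

var_pop <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sum((x - mean(x))^2) / n
}

# Sample SD that degrades to 0 (not NA) below two observations; used for
# across-nucleus dispersion features.
sd_sample0 <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x)
}
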