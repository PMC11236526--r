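# Discrete wavelet transform with symmetric (half-sample) boundary extension
# and Donoho-Johnstone universal-threshold de-noising.  Only the sym4
# (least-asymmetric Daubechies, 8-tap) wavelet is provided; it is the filter
# conventionally used for physiological BOLD time series.

# sym4 analysis low-pass filter (orthonormal; high-pass and synthesis filters
# are derived from it by the usual quadrature-mirror relations).
.sym4_dec_lo <- c(
  -0.075765714789273325, -0.029635527645998510, 0.497618667632015450,
   0.803738751805916140,  0.297857795605277360, -0.099219543576847216,
  -0.012603967262037833,  0.032223100604042702)

.wt_filters <- function(family) {
  if (!identical(family, "sym4"))
    stop("only the 'sym4' wavelet family is supported", call. = FALSE)
  lo <- .sym4_dec_lo
  n <- length(lo)
  hi <- rev(lo) * (-1)^seq_len(n)             # QMF high-pass
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi), len = n)
}

# half-sample symmetric extension by `n` samples on each side
.symext <- function(x, n) {
  idx <- seq_along(x)
  refl <- function(k) {
    # reflect index k (possibly out of range) back into 1..length(x)
    m <- length(x)
    p <- 2L * m
    k <- ((k - 1L) %% p + p) %% p + 1L
    ifelse(k > m, p - k + 1L, k)
  }
  x[refl(c(rev(seq_len(n)) * -1L + 1L, idx, length(x) + seq_len(n)))]
}

# single-level analysis: returns approximation and detail coefficients,
# length floor((n + flen - 1) / 2) each
.dwt1 <- function(x, filt) {
  fl <- filt$len
  ext <- .symext(x, fl - 1L)
  nc <- (length(x) + fl - 1L) %/% 2L
  # correlation of the extension with the time-reversed filter, decimated;
  # matches the standard analysis convention (convolve then keep odd samples)
  ca <- stats::filter(ext, filt$dec_lo, method = "convolution", sides = 1)
  cd <- stats::filter(ext, filt$dec_hi, method = "convolution", sides = 1)
  keep <- fl + 2L * seq_len(nc) - 1L
  list(cA = as.numeric(ca[keep]), cD = as.numeric(cd[keep]))
}

# single-level synthesis inverting .dwt1; `n_out` is the parent length
.idwt1 <- function(cA, cD, n_out, filt) {
  fl <- filt$len
  up <- function(c) {
    u <- numeric(2L * length(c))
    u[seq(1L, length(u), by = 2L)] <- c
    u
  }
  ya <- stats::convolve(up(cA), rev(filt$rec_lo), type = "open")
  yd <- stats::convolve(up(cD), rev(filt$rec_hi), type = "open")
  y <- ya + yd
  y[(fl - 2L) + seq_len(n_out)]
}

# multi-level decomposition; returns list(cA, cD_list (finest first), lengths)
.wavedec <- function(x, level, filt) {
  stopifnot(level >= 1L)
  details <- vector("list", level)
  lens <- integer(level)
  a <- x
  for (j in seq_len(level)) {
    lens[j] <- length(a)
    d <- .dwt1(a, filt)
    details[[j]] <- d$cD
    a <- d$cA
  }
  list(cA = a, cD = details, parent_len = lens)
}

.waverec <- function(dec, filt) {
  a <- dec$cA
  for (j in rev(seq_along(dec$cD)))
    a <- .idwt1(a, dec$cD[[j]], dec$parent_len[j], filt)
  a
}

#' Wavelet de-noising with the universal hard threshold
#'
#' De-noises a 1-D signal by discrete wavelet decomposition, hard
#' thresholding of the detail coefficients at the Donoho-Johnstone
#' universal threshold, and reconstruction.  The threshold is
#' \eqn{\lambda = \hat\sigma \sqrt{2 \ln N}} with \eqn{N} the signal length
#' and \eqn{\hat\sigma} the median absolute deviation of the finest-level
#' detail coefficients divided by 0.6745; the same \eqn{\lambda} is applied
#' at every level (level-independent thresholding).  Boundaries are handled
#' by half-sample symmetric extension, so reconstruction is exact when no
#' coefficient is thresholded.
#'
#' @param trace numeric vector, length at least `2^level`.
#' @param family wavelet family; only `"sym4"` is available.
#' @param level decomposition depth (default 2).
#' @param threshold_rule only `"universal"` is available.
#' @param threshold_mode only `"hard"` is available.
#' @return numeric vector of the same length as `trace`.
#' @examples
#' x <- sin(seq(0, 4 * pi, length.out = 256)) + rnorm(256, sd = 0.3)
#' y <- denoise_wavelet(x)
#' var(y) < var(x)
#' @export
denoise_wavelet <- function(trace, family = "sym4", level = 2L,
                            threshold_rule = "universal",
                            threshold_mode = "hard") {
  if (!identical(threshold_rule, "universal"))
    stop("only the universal threshold rule is supported", call. = FALSE)
  if (!identical(threshold_mode, "hard"))
    stop("only hard thresholding is supported", call. = FALSE)
  trace <- as.numeric(trace)
  level <- as.integer(level)
  if (length(trace) < 2^level)
    stop("trace too short for a level-", level, " decomposition",
         call. = FALSE)
  filt <- .wt_filters(family)
  dec <- .wavedec(trace, level, filt)
  d1 <- dec$cD[[1L]]
  sigma <- stats::median(abs(d1)) / 0.6745
  lambda <- universal_threshold(sigma, length(trace))
  dec$cD <- lapply(dec$cD, function(d) ifelse(abs(d) > lambda, d, 0))
  .waverec(dec, filt)
}

#' Donoho-Johnstone universal threshold
#'
#' \eqn{\lambda = \sigma \sqrt{2 \ln N}}.
#'
#' @param sigma noise standard deviation estimate.
#' @param n signal length.
#' @return the threshold value.
#' @export
universal_threshold <- function(sigma, n) {
  stopifnot(sigma >= 0, n >= 1)
  sigma * sqrt(2 * log(n))
}
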