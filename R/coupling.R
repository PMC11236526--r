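# Coupling statistics: shifted cross-correlation lags, simple linear
# regression, and the paired pre/post comparison.

#' Shifted cross-correlation between two traces
#'
#' Pearson correlation at every integer-volume shift within `max_lag`
#' seconds, using only the overlapping samples at each shift (no padding).
#' The returned lag (in seconds) is positive when the second signal lags
#' the first, i.e. `shifted_crosscorr(x, delay(x, k))` recovers `+k * tr`.
#' Ties break toward the smallest absolute lag.
#'
#' @param x,y numeric traces of equal length, both non-constant.
#' @param tr repetition time (s).
#' @param max_lag maximum lag magnitude searched (s).
#' @return an object of class `"lag_result"`: `lag` (s), `lag_volumes`,
#'   `r_max`, `max_lag`.
#' @export
shifted_crosscorr <- function(x, y, tr, max_lag = 30) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n, tr > 0, max_lag >= 0)
  kmax <- min(floor(max_lag / tr), n - 2L)
  b <- .best_shift(x, y, kmax)
  structure(list(lag = b$lag * tr, lag_volumes = b$lag, r_max = b$r,
                 max_lag = kmax * tr),
            class = "lag_result")
}

#' @export
print.lag_result <- function(x, digits = 3, ...) {
  cat(sprintf("Shifted cross-correlation: lag %.*f s (%d volumes), r = %.*f (searched +/- %.1f s)\n",
              digits, x$lag, x$lag_volumes, digits, x$r_max, x$max_lag))
  invisible(x)
}

#' Simple linear regression summary
#'
#' Ordinary least squares of `y` on `x` with the slope's two-sided p-value
#' from the t distribution on `n - 2` degrees of freedom; used for the
#' cohort-level relations of tau with inflow width and edema load.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, `x` non-constant.
#' @return list of class `"simple_regression"`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
regress <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("undefined fit: x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4], n = n),
            class = "simple_regression")
}

#' @export
print.simple_regression <- function(x, digits = 3, ...) {
  cat(sprintf("Linear regression (n = %d): slope %.*g, intercept %.*g, R2 = %.*f, p = %.*g\n",
              x$n, digits, x$slope, digits, x$intercept, digits,
              x$r_squared, digits, x$p_value))
  invisible(x)
}

#' Paired pre/post comparison
#'
#' Two-sided paired t test on the post-minus-pre differences.  Identical
#' vectors return `t = 0`, `p = 1` by convention; constant non-zero
#' differences (zero variance but non-zero mean) are degenerate and raise
#' an error.
#'
#' @param pre,post numeric vectors of equal length `>= 2`, paired by
#'   subject.
#' @return list with `t`, `p_value`, `mean_change`, `n`.
#' @export
paired_change_test <- function(pre, post) {
  pre <- as.numeric(pre); post <- as.numeric(post)
  n <- length(pre)
  stopifnot(length(post) == n, n >= 2L)
  d <- post - pre
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p_value = 1, mean_change = 0, n = n))
    stop("degenerate test: differences have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_change = unname(tt$estimate), n = n)
}
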