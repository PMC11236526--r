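# Vascular response time constant (tau): least-squares fit of the BOLD
# signal against the PetCO2 trace convolved with an exponential hemodynamic
# response function.

#' Convolve a trace with the exponential hemodynamic response function
#'
#' Causal discrete convolution with \eqn{h_\tau(t) = \tau^{-1} e^{-t/\tau}}
#' sampled at the repetition time and normalised to unit discrete sum, so a
#' sustained plateau passes through unchanged and the regression coefficient
#' on the convolved trace keeps the units of signal per mmHg regardless of
#' tau.  The output is truncated to the input length, and the input is
#' assumed to have sat at its initial value before the first sample
#' (steady-state initialisation), so a constant trace convolves to itself
#' exactly and no warm-up transient leaks into analysis windows.
#'
#' @param x numeric input (one value per volume).
#' @param tau time constant (s), positive.
#' @param tr repetition time (s).
#' @return numeric vector, same length as `x`.
#' @export
convolve_exponential <- function(x, tau, tr) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  stopifnot(tr > 0)
  x <- as.numeric(x)
  n <- length(x)
  h <- exp(-(seq_len(n) - 1L) * tr / tau)
  h <- h / sum(h)
  x[1] + .causal_conv(x - x[1], h)
}

# truncated causal convolution via FFT; both inputs length n, output first n
.causal_conv <- function(x, h) {
  n <- length(x)
  m <- stats::nextn(2L * n, 2)
  X <- stats::fft(c(x, numeric(m - n)))
  H <- stats::fft(c(h, numeric(m - n)))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n)] / m
}

#' Fit the vascular response time constant tau
#'
#' For each candidate tau on a grid, the CO2 trace is convolved with the
#' unit-sum exponential response function over the full scan (so the fit
#' window inherits the correct convolution history) and the BOLD trace is
#' regressed on `[1, convolved CO2]` (plus an optional linear drift) by
#' ordinary least squares over the analysis window.  The tau minimising the
#' residual sum of squares is returned; ties break toward the smaller tau.
#' An optional parabolic refinement interpolates the RSS profile around the
#' grid minimum.
#'
#' The default window, volumes 250-450 (262.5-472.5 s at TR = 1.05 s),
#' isolates the hypercapnic-block response; the gradual hypercapnic ramp is
#' excluded because slow CO2 increases do not probe the response dynamics.
#'
#' @param bold_gm regional BOLD trace (numeric or 1-D `"bold_series"`).
#' @param co2 PetCO2 values on the same volume grid (e.g. from
#'   [resample_trace()] and [bulk_align()]).
#' @param tr repetition time (s); taken from `bold_gm` if it is a
#'   `"bold_series"`.
#' @param window analysis window as 0-based volume indices
#'   `c(start, end)`, inclusive.
#' @param tau_grid candidate time constants (s).
#' @param drift include a linear drift regressor (default `FALSE`).
#' @param refine parabolic interpolation of the RSS minimum (default
#'   `FALSE`; the reported tau then leaves the grid).
#' @return an object of class `"tau_fit"` with components `tau`, `beta0`
#'   (offset), `beta1` (CVR amplitude, signal units/mmHg), `rss`, `fitted`
#'   (window-length model trace), `window`, `tau_grid`, `rss_grid`.
#' @examples
#' p <- default_protocol(n_volumes = 500L)
#' tr <- render_traces(p)
#' pars <- forward_model_params(tau_true = 12, noise_sd = 0)
#' b <- simulate_bold(tr$co2, pars, p)
#' co2v <- resample_trace(tr$co2, p$tr, p$n_volumes)
#' fit <- fit_tau(b, co2v, window = c(150, 450))
#' fit$tau
#' @export
fit_tau <- function(bold_gm, co2, tr = NULL, window = c(250L, 450L),
                    tau_grid = seq(0.5, 120, by = 0.5), drift = FALSE,
                    refine = FALSE) {
  if (inherits(bold_gm, "bold_series")) {
    if (is.null(tr)) tr <- bold_gm$tr
    bold_gm <- bold_gm$data
  }
  if (is.null(tr)) stop("tr is required for a plain numeric trace",
                        call. = FALSE)
  bold_gm <- as.numeric(bold_gm)
  co2 <- as.numeric(co2)
  n <- length(bold_gm)
  stopifnot(length(co2) == n)
  if (length(tau_grid) == 0L || any(tau_grid <= 0))
    stop("tau_grid must be nonempty and positive", call. = FALSE)
  tau_grid <- sort(unique(tau_grid))
  win <- .window_index(window, n)
  y <- bold_gm[win]
  tw <- volume_time(win - 1L, tr)
  # grid search: the exponential kernel is geometric, so its padded DFT has
  # a closed form; only one inverse FFT is needed per candidate tau
  m <- stats::nextn(2L * n, 2)
  co2_fft <- stats::fft(c(co2 - co2[1], numeric(m - n)))
  w <- exp(-2i * pi * seq(0, m - 1L) / m)
  wn <- exp(-2i * pi * seq(0, m - 1L) * (n / m))
  conv_tau <- function(tau) {
    r <- exp(-tr / tau)
    rn <- r^n
    H <- ((1 - r) / (1 - rn)) * (1 - rn * wn) / (1 - r * w)
    co2[1] + Re(stats::fft(co2_fft * H, inverse = TRUE))[seq_len(n)] / m
  }
  eval_tau <- function(tau) {
    reg <- conv_tau(tau)[win]
    if (stats::sd(reg) == 0)
      stop("undefined fit: CO2 regressor constant over the window",
           call. = FALSE)
    if (drift) {
      X <- cbind(1, reg, tw)
      beta <- qr.coef(qr(X), y)
      fit <- as.numeric(X %*% beta)
    } else {
      b1 <- stats::cov(reg, y) / stats::var(reg)
      b0 <- mean(y) - b1 * mean(reg)
      beta <- c(b0, b1)
      fit <- b0 + b1 * reg
    }
    list(rss = sum((y - fit)^2), beta = beta, fitted = fit)
  }
  fits <- lapply(tau_grid, eval_tau)
  rss_grid <- vapply(fits, `[[`, numeric(1), "rss")
  best <- which.min(rss_grid)          # which.min takes first = smaller tau
  tau_hat <- tau_grid[best]
  best_fit <- fits[[best]]
  if (refine && best > 1L && best < length(tau_grid)) {
    t3 <- tau_grid[(best - 1L):(best + 1L)]
    r3 <- rss_grid[(best - 1L):(best + 1L)]
    denom <- (t3[1] - t3[2]) * (t3[1] - t3[3]) * (t3[2] - t3[3])
    if (denom != 0) {
      a <- (t3[3] * (r3[2] - r3[1]) + t3[2] * (r3[1] - r3[3]) +
              t3[1] * (r3[3] - r3[2])) / denom
      b <- (t3[3]^2 * (r3[1] - r3[2]) + t3[2]^2 * (r3[3] - r3[1]) +
              t3[1]^2 * (r3[2] - r3[3])) / denom
      if (a > 0) {
        cand <- -b / (2 * a)
        if (cand > t3[1] && cand < t3[3]) {
          cf <- eval_tau(cand)
          if (cf$rss <= best_fit$rss) {
            tau_hat <- cand
            best_fit <- cf
          }
        }
      }
    }
  }
  structure(
    list(tau = tau_hat, beta0 = unname(best_fit$beta[1]),
         beta1 = unname(best_fit$beta[2]),
         drift = if (drift) unname(best_fit$beta[3]) else NULL,
         rss = best_fit$rss, fitted = best_fit$fitted,
         window = as.integer(window), tau_grid = tau_grid,
         rss_grid = rss_grid, tr = tr,
         data = list(y = y, co2 = co2, times = tw, n = n, win = win),
         call = match.call()),
    class = "tau_fit")
}

# 0-based inclusive volume window -> 1-based R indices, validated
.window_index <- function(window, n) {
  stopifnot(length(window) == 2L)
  w0 <- as.integer(window[1]); w1 <- as.integer(window[2])
  if (w0 < 0 || w1 >= n || w0 >= w1)
    stop("window [", w0, ", ", w1, "] outside series of ", n, " volumes",
         call. = FALSE)
  (w0:w1) + 1L
}

#' @export
print.tau_fit <- function(x, digits = 3, ...) {
  cat("Exponential hemodynamic response fit\n")
  cat(sprintf("  tau   = %.*f s\n", digits, x$tau))
  cat(sprintf("  CVR   = %.*g signal units/mmHg\n", digits, x$beta1))
  cat(sprintf("  rss   = %.*g over volumes %d-%d\n", digits, x$rss,
              x$window[1], x$window[2]))
  invisible(x)
}

#' @export
summary.tau_fit <- function(object, ...) {
  nw <- length(object$data$y)
  p <- 2L + !is.null(object$drift)
  sigma2 <- object$rss / (nw - p)
  r2 <- 1 - object$rss / sum((object$data$y - mean(object$data$y))^2)
  out <- list(tau = object$tau, beta0 = object$beta0, beta1 = object$beta1,
              drift = object$drift, rss = object$rss, sigma = sqrt(sigma2),
              r_squared = r2, n = nw, window = object$window,
              grid_range = range(object$tau_grid))
  class(out) <- "summary.tau_fit"
  out
}

#' @export
print.summary.tau_fit <- function(x, digits = 4, ...) {
  cat("Vascular response time-constant fit (exponential HRF)\n\n")
  cat(sprintf("  tau            %.*g s (grid %.3g-%.3g s)\n", digits, x$tau,
              x$grid_range[1], x$grid_range[2]))
  cat(sprintf("  offset (beta0) %.*g\n", digits, x$beta0))
  cat(sprintf("  CVR    (beta1) %.*g signal units/mmHg\n", digits, x$beta1))
  if (!is.null(x$drift))
    cat(sprintf("  drift          %.*g signal units/s\n", digits, x$drift))
  cat(sprintf("  window         volumes %d-%d (%d samples)\n",
              x$window[1], x$window[2], x$n))
  cat(sprintf("  RSS %.*g, residual SD %.*g, R-squared %.*f\n", digits,
              x$rss, digits, x$sigma, 3, x$r_squared))
  invisible(x)
}

#' @export
coef.tau_fit <- function(object, ...) {
  out <- c(tau = object$tau, beta0 = object$beta0, beta1 = object$beta1)
  if (!is.null(object$drift)) out <- c(out, drift = object$drift)
  out
}

#' Model predictions from a tau fit
#'
#' With no new data, returns the fitted values over the analysis window.
#' With `newdata` (a full-length CO2 trace on the volume grid), evaluates
#' the fitted model `beta0 + beta1 * (co2 conv h_tau)` over the whole
#' series.
#'
#' @param object a `"tau_fit"`.
#' @param newdata optional CO2 trace.
#' @param ... unused.
#' @export
predict.tau_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  reg <- convolve_exponential(as.numeric(newdata), object$tau, object$tr)
  out <- object$beta0 + object$beta1 * reg
  if (!is.null(object$drift))
    out <- out + object$drift *
      volume_time(seq_along(reg) - 1L, object$tr)
  out
}

#' @export
fitted.tau_fit <- function(object, ...) object$fitted

#' @export
residuals.tau_fit <- function(object, ...) object$data$y - object$fitted

#' @export
plot.tau_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$data$times, x$data$y, type = "l", col = "grey40",
                 xlab = "time (s)", ylab = "BOLD signal",
                 main = sprintf("tau = %.2f s", x$tau), ...)
  graphics::lines(x$data$times, x$fitted, col = "darkorange", lwd = 2)
  graphics::plot(x$tau_grid, x$rss_grid, type = "l", xlab = "tau (s)",
                 ylab = "RSS", main = "grid search profile")
  graphics::abline(v = x$tau, col = "darkorange", lty = 2)
  invisible(x)
}
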