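# CSF inflow: voxel selection in the bottom slices, skew-normal + linear
# peak fitting, and the right-sided half width at half maximum.

#' Skew-normal peak plus linear baseline
#'
#' The Azzalini skew-normal density scaled by an amplitude, on a linear
#' baseline:
#' \deqn{f(t) = A \frac{2}{\omega}\,\phi\!\left(\frac{t-\xi}{\omega}\right)
#'   \Phi\!\left(\alpha \frac{t-\xi}{\omega}\right) + a + b t}
#' with \eqn{\phi}/\eqn{\Phi} the standard normal density/CDF.  With
#' `alpha = 0` this reduces to a scaled Gaussian of SD `omega` centred at
#' `xi`.
#'
#' @param t time (s), vectorised.
#' @param amplitude peak area scale `A` (signal units x s).
#' @param xi location (s).
#' @param omega scale (s), positive.
#' @param alpha shape (dimensionless; positive = right skew).
#' @param a,b baseline intercept and slope.
#' @return model values at `t`.
#' @export
skew_normal_model <- function(t, amplitude, xi, omega, alpha, a = 0, b = 0) {
  if (any(omega <= 0)) stop("omega must be positive", call. = FALSE)
  z <- (t - xi) / omega
  amplitude * (2 / omega) * stats::dnorm(z) * stats::pnorm(alpha * z) +
    a + b * t
}

# baseline-free component
.sn_component <- function(t, amplitude, xi, omega, alpha)
  skew_normal_model(t, amplitude, xi, omega, alpha, 0, 0)

#' Select CSF inflow voxels from the bottom slices
#'
#' Within each of the `n_bottom_slices` lowest slices of the imaging stack,
#' voxel time courses are de-noised and ranked by signal contrast (max
#' minus min over the contrast window); the top `k_voxels` per slice are
#' averaged into a per-slice trace, and slices contributing voxels are
#' averaged into the final inflow trace.  This emulates the manual
#' selection of the brightest time-of-flight inflow voxels near the fourth
#' ventricle.  Ties in contrast break by ascending voxel index.
#'
#' @param bold a 4-D `"bold_series"` (slice axis = third dimension; slice 1
#'   is the bottom of the stack).
#' @param n_bottom_slices number of bottom slices searched (default 2).
#' @param contrast_window 0-based volume window for the contrast ranking
#'   (`NULL` = whole series).
#' @param k_voxels voxels retained per slice (default 5); clipped with a
#'   warning when a slice has fewer voxels.
#' @param denoise apply [denoise_wavelet()] to each candidate voxel before
#'   ranking (default `TRUE`).
#' @return list with `trace` (numeric inflow trace), `voxels` (data.frame
#'   of selected x/y/slice indices and contrasts), and `per_slice`
#'   (matrix of per-slice mean traces).
#' @export
select_inflow_voxels <- function(bold, n_bottom_slices = 2L,
                                 contrast_window = NULL, k_voxels = 5L,
                                 denoise = TRUE) {
  stopifnot(inherits(bold, "bold_series"))
  if (!is.array(bold$data) || length(dim(bold$data)) != 4L)
    stop("select_inflow_voxels expects 4-D BOLD data", call. = FALSE)
  d <- dim(bold$data)
  n_bottom_slices <- as.integer(n_bottom_slices)
  stopifnot(n_bottom_slices >= 1L, n_bottom_slices <= d[3])
  k_voxels <- as.integer(k_voxels)
  if (k_voxels > d[1] * d[2]) {
    warning("k_voxels exceeds the slice voxel count; clipping")
    k_voxels <- d[1] * d[2]
  }
  widx <- if (is.null(contrast_window)) seq_len(d[4])
  else .window_index(contrast_window, d[4])
  per_slice <- matrix(NA_real_, d[4], n_bottom_slices)
  picked <- list()
  for (s in seq_len(n_bottom_slices)) {
    sl <- matrix(bold$data[, , s, ], d[1] * d[2], d[4])
    traces <- if (denoise) t(apply(sl, 1, denoise_wavelet)) else sl
    contrast <- apply(traces[, widx, drop = FALSE], 1, function(v)
      max(v) - min(v))
    ord <- order(-contrast, seq_along(contrast))
    top <- ord[seq_len(k_voxels)]
    per_slice[, s] <- colMeans(sl[top, , drop = FALSE])
    ij <- arrayInd(top, d[1:2])
    picked[[s]] <- data.frame(x = ij[, 1], y = ij[, 2], slice = s,
                              contrast = contrast[top])
  }
  list(trace = rowMeans(per_slice), voxels = do.call(rbind, picked),
       per_slice = per_slice)
}

#' Fit a skew-normal peak to the CSF inflow trace
#'
#' Nonlinear least squares of [skew_normal_model()] over the analysis
#' window.  The default window runs from the end of the hypercapnic block
#' (volume 250) to the midpoint before the ramp peak (volume 525), so the
#' full tail of the inflow peak is included even for slow responses.
#'
#' Starting values: `xi` at the windowed maximum, `omega` = window span / 6,
#' `alpha` = 0, amplitude from the peak height, baseline from the window
#' endpoints; on failure the fit restarts from `alpha` in `{-2, 2}` and the
#' lowest-RSS convergent fit wins.  Bounds: `omega` in (tr, window span),
#' `|alpha| <= 20`, amplitude nonnegative (time-of-flight inflow cannot be
#' negative).
#'
#' @param inflow inflow trace (numeric or 1-D `"bold_series"`).
#' @param tr repetition time (s); taken from the series if available.
#' @param window 0-based volume window `c(start, end)`, inclusive; needs at
#'   least 7 samples.
#' @return an object of class `"inflow_fit"` with the fitted parameters
#'   (`amplitude`, `xi`, `omega`, `alpha`, `a`, `b`), `hwhm_right` (s),
#'   `rss`, `fitted`, and `window`.
#' @examples
#' tt <- seq(0, 120, by = 1.05)
#' y <- skew_normal_model(tt, 40, 50, 12, 2, a = 10, b = 0.01)
#' fit <- fit_inflow_peak(y, tr = 1.05, window = c(0, length(tt) - 1))
#' coef(fit)
#' @export
fit_inflow_peak <- function(inflow, tr = NULL, window = c(250L, 525L)) {
  if (inherits(inflow, "bold_series")) {
    if (is.null(tr)) tr <- inflow$tr
    inflow <- inflow$data
  }
  if (is.null(tr)) stop("tr is required for a plain numeric trace",
                        call. = FALSE)
  inflow <- as.numeric(inflow)
  win <- .window_index(window, length(inflow))
  if (length(win) < 7L)
    stop("window must contain at least 7 samples", call. = FALSE)
  y <- inflow[win]
  tt <- volume_time(win - 1L, tr)
  span <- diff(range(tt))
  b0 <- (y[length(y)] - y[1]) / span
  a0 <- y[1] - b0 * tt[1]
  base0 <- a0 + b0 * tt
  peak_h <- max(y - base0)
  xi0 <- tt[which.max(y - base0)]
  omega0 <- span / 6
  amp0 <- max(peak_h, 1e-8) * omega0 * sqrt(2 * pi)
  # xi may sit outside the window (the analysed peak can start at its very
  # edge); omega is bounded by the window span per the fit contract
  lower <- c(amplitude = 0, xi = min(tt) - span, omega = tr, alpha = -20,
             a = -Inf, b = -Inf)
  upper <- c(amplitude = Inf, xi = max(tt) + span, omega = span, alpha = 20,
             a = Inf, b = Inf)
  dat <- data.frame(t = tt, y = y)
  try_fit <- function(alpha0) {
    start <- list(amplitude = amp0, xi = xi0, omega = omega0,
                  alpha = alpha0, a = a0, b = b0)
    tryCatch(
      minpack.lm::nlsLM(
        y ~ skew_normal_model(t, amplitude, xi, omega, alpha, a, b),
        data = dat, start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fits <- Filter(Negate(is.null), lapply(c(0, -2, 2), try_fit))
  if (length(fits) == 0L)
    stop("inflow peak fit failed to converge from all starts (window ",
         window[1], "-", window[2], ", peak height ",
         signif(peak_h, 3), ")", call. = FALSE)
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  p <- as.list(stats::coef(best))
  out <- structure(
    list(amplitude = p$amplitude, xi = p$xi, omega = p$omega,
         alpha = p$alpha, a = p$a, b = p$b,
         rss = min(rss), fitted = as.numeric(stats::fitted(best)),
         window = as.integer(window), tr = tr,
         data = list(t = tt, y = y), call = match.call()),
    class = "inflow_fit")
  out$hwhm_right <- tryCatch(hwhm_right(out), error = function(e) NA_real_)
  out
}

#' Right-sided half width at half maximum of a fitted inflow peak
#'
#' Locates the mode of the baseline-free skew-normal component numerically
#' (the skew-normal mode has no closed form), then bisects on the falling
#' flank for the time where the component drops to half its peak value, to
#' a tolerance of `1e-6 * omega`.  For `alpha = 0` this equals
#' `omega * sqrt(2 * log(2))`.
#'
#' @param fit an `"inflow_fit"`, or a list with elements `amplitude`, `xi`,
#'   `omega`, `alpha`.
#' @return right HWHM in seconds.
#' @export
hwhm_right <- function(fit) {
  amplitude <- fit$amplitude; xi <- fit$xi
  omega <- fit$omega; alpha <- fit$alpha
  if (!is.finite(amplitude) || amplitude <= 0)
    stop("undefined width: fitted peak amplitude is not positive",
         call. = FALSE)
  stopifnot(omega > 0)
  f <- function(t) .sn_component(t, amplitude, xi, omega, alpha)
  opt <- stats::optimize(f, interval = c(xi - 4 * omega, xi + 4 * omega),
                         maximum = TRUE, tol = 1e-8 * omega)
  t_peak <- opt$maximum
  half <- opt$objective / 2
  hi <- t_peak + omega
  while (f(hi) > half && hi < t_peak + 100 * omega) hi <- hi + omega
  if (f(hi) > half)
    stop("half height not reached on the right flank", call. = FALSE)
  lo <- t_peak
  tol <- 1e-6 * omega
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > half) lo <- mid else hi <- mid
  }
  (lo + hi) / 2 - t_peak
}

#' @export
print.inflow_fit <- function(x, digits = 3, ...) {
  cat("CSF inflow peak fit (skew-normal + linear baseline)\n")
  cat(sprintf("  location xi = %.*f s, scale omega = %.*f s, shape alpha = %.*f\n",
              digits, x$xi, digits, x$omega, digits, x$alpha))
  cat(sprintf("  amplitude = %.*g, right HWHM = %.*f s\n", digits,
              x$amplitude, digits, x$hwhm_right))
  invisible(x)
}

#' @export
summary.inflow_fit <- function(object, ...) {
  nw <- length(object$data$y)
  out <- list(coef = coef(object), hwhm_right = object$hwhm_right,
              rss = object$rss, sigma = sqrt(object$rss / (nw - 6L)),
              n = nw, window = object$window)
  class(out) <- "summary.inflow_fit"
  out
}

#' @export
print.summary.inflow_fit <- function(x, digits = 4, ...) {
  cat("CSF inflow peak: skew-normal + linear baseline fit\n\n")
  print(signif(x$coef, digits))
  cat(sprintf("\n  right HWHM %.*g s over volumes %d-%d (%d samples)\n",
              digits, x$hwhm_right, x$window[1], x$window[2], x$n))
  cat(sprintf("  RSS %.*g, residual SD %.*g\n", digits, x$rss, digits,
              x$sigma))
  invisible(x)
}

#' @export
coef.inflow_fit <- function(object, ...) {
  c(amplitude = object$amplitude, xi = object$xi, omega = object$omega,
    alpha = object$alpha, a = object$a, b = object$b)
}

#' Model predictions from an inflow peak fit
#'
#' @param object an `"inflow_fit"`.
#' @param newdata optional vector of times (s); default: the fit window.
#' @param component `"full"` (peak + baseline) or `"peak"` (baseline-free
#'   skew-normal component).
#' @param ... unused.
#' @export
predict.inflow_fit <- function(object, newdata = NULL,
                               component = c("full", "peak"), ...) {
  component <- match.arg(component)
  tt <- if (is.null(newdata)) object$data$t else as.numeric(newdata)
  if (component == "peak")
    .sn_component(tt, object$amplitude, object$xi, object$omega,
                  object$alpha)
  else
    skew_normal_model(tt, object$amplitude, object$xi, object$omega,
                      object$alpha, object$a, object$b)
}

#' @export
fitted.inflow_fit <- function(object, ...) object$fitted

#' @export
residuals.inflow_fit <- function(object, ...) object$data$y - object$fitted

#' @export
plot.inflow_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$y, col = "grey40", pch = 16, cex = 0.5,
                 xlab = "time (s)", ylab = "inflow signal",
                 main = sprintf("right HWHM = %.2f s", x$hwhm_right), ...)
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 400)
  graphics::lines(tt, predict(x, tt), col = "darkorange", lwd = 2)
  graphics::lines(tt, x$a + x$b * tt, col = "steelblue", lty = 2)
  invisible(x)
}
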