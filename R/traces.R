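# End-tidal gas time series: construction from a protocol, resampling to the
# scan grid, and bulk alignment against the BOLD signal.

#' Construct an end-tidal gas time series
#'
#' @param times sample times (s), strictly increasing.
#' @param values partial pressures (mmHg), finite and positive.
#' @param gas `"CO2"` or `"O2"`.
#' @return an object of class `"physio_trace"`.
#' @export
physio_trace <- function(times, values, gas = c("CO2", "O2")) {
  gas <- match.arg(gas)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) == 0L) stop("empty trace", call. = FALSE)
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("values must be finite and positive", call. = FALSE)
  structure(list(times = times, values = values, gas = gas),
            class = "physio_trace")
}

#' @export
print.physio_trace <- function(x, ...) {
  cat(sprintf("Pet%s trace: %d samples, %.1f-%.1f s, %.1f-%.1f mmHg\n",
              x$gas, length(x$times), min(x$times), max(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

# piecewise delta profile of one epoch at times t (relative to epoch start).
# The entry transition rises inside the epoch; the return to baseline STARTS
# at the epoch end and decays over the next transition_time seconds (the
# targeting controller switches target at the boundary and needs a few
# breaths to reach it) -- so inflow-generating CO2 drops begin exactly at
# the block end.
.epoch_profile <- function(kind, t, dur, delta, tt) {
  tt <- min(tt, dur)
  core <- if (kind == "hypercapnic_ramp") pmin(pmax(t / dur, 0), 1)
  else if (tt > 0) pmin(pmax(t / tt, 0), 1)
  else as.numeric(t >= 0)
  down <- if (tt > 0) pmin(pmax(1 - (t - dur) / tt, 0), 1)
  else as.numeric(t < dur)
  delta * pmin(core, down)
}

#' Render idealised end-tidal traces from a protocol
#'
#' Produces the PetCO2 and PetO2 traces a prospective end-tidal targeting
#' system aims for: plateaus reached through linear transitions of length
#' `transition_time`, a linear rise over ramp epochs, and baseline values
#' everywhere else.  Breath-to-breath variability can be emulated with
#' additive Gaussian noise.
#'
#' @param protocol a [respiratory_protocol()].
#' @param dt sampling interval of the rendered traces (s).
#' @param transition_time length (s) of the linear transition into and out of
#'   plateau epochs (0 = ideal step).  The default of 10 s reflects the two
#'   to three breaths a prospective end-tidal targeting system needs to
#'   reach a new target.
#' @param noise_sd standard deviation (mmHg) of additive Gaussian noise;
#'   default 0 (ideal targeting).
#' @param seed optional seed for the noise.
#' @return list with components `co2` and `o2`, each a `"physio_trace"`
#'   covering the scan duration.
#' @export
render_traces <- function(protocol, dt = 0.1, transition_time = 10,
                          noise_sd = 0, seed = NULL) {
  stopifnot(inherits(protocol, "respiratory_protocol"))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (transition_time < 0)
    stop("transition_time must be nonnegative", call. = FALSE)
  ep <- .protocol_epoch_times(protocol)
  t_end <- max(max(ep$end), protocol$tr * (protocol$n_volumes - 1L))
  times <- seq(0, t_end + dt, by = dt)
  co2 <- rep(protocol$co2_baseline, length(times))
  o2 <- rep(protocol$o2_baseline, length(times))
  for (i in seq_len(nrow(ep))) {
    rel <- times - ep$start[i]
    dur <- ep$end[i] - ep$start[i]
    if (ep$kind[i] %in% c("hypercapnic_block", "hypercapnic_ramp")) {
      co2 <- co2 + .epoch_profile(ep$kind[i], rel, dur, ep$co2_delta[i],
                                  transition_time)
    } else if (ep$kind[i] == "hyperoxic_block") {
      o2 <- o2 + .epoch_profile(ep$kind[i], rel, dur,
                                ep$o2_target[i] - protocol$o2_baseline,
                                transition_time)
    }
  }
  if (noise_sd > 0) {
    with_seed(seed, {
      co2 <- co2 + stats::rnorm(length(co2), sd = noise_sd)
      o2 <- o2 + stats::rnorm(length(o2), sd = noise_sd)
    })
  }
  list(co2 = physio_trace(times, co2, "CO2"),
       o2 = physio_trace(times, o2, "O2"))
}

#' Resample a gas trace onto the scan volume grid
#'
#' Linear interpolation onto the volume acquisition times `k * tr`
#' (`k = 0 .. n_volumes - 1`); beyond the support of the trace the edge
#' values are held constant.
#'
#' @param trace a `"physio_trace"` (or a list with `times` and `values`).
#' @param tr repetition time (s).
#' @param n_volumes number of volumes.
#' @return numeric vector of length `n_volumes`.
#' @export
resample_trace <- function(trace, tr, n_volumes) {
  if (is.null(trace$times) || length(trace$times) == 0L)
    stop("empty trace", call. = FALSE)
  stopifnot(tr > 0, n_volumes >= 1)
  tt <- volume_time(seq_len(n_volumes) - 1L, tr)
  stats::approx(trace$times, trace$values, xout = tt, rule = 2)$y
}

# Pearson correlation of x against y advanced by k volumes, overlap only.
# k > 0 means y lags x by k (y must be shifted earlier to align).
.shift_cor <- function(x, y, k) {
  n <- length(x)
  # overlap may be constant at extreme shifts; treat as "no correlation"
  suppressWarnings(
    if (k >= 0) stats::cor(x[seq_len(n - k)], y[seq_len(n - k) + k])
    else stats::cor(x[seq_len(n + k) - k], y[seq_len(n + k)]))
}

# best integer shift over |k| <= max_lag, ties toward smallest |k|
.best_shift <- function(x, y, max_lag) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("cross-correlation undefined for constant input", call. = FALSE)
  ks <- seq(-max_lag, max_lag)
  ks <- ks[order(abs(ks), ks)]             # 0, -1, 1, -2, 2, ...
  r <- vapply(ks, function(k) .shift_cor(x, y, k), numeric(1))
  r[is.na(r)] <- -Inf                       # constant overlap at extreme lags
  best <- which.max(r)                      # first max wins -> smallest |k|
  list(lag = ks[best], r = r[best])
}

#' Bulk alignment of the CO2 trace to the BOLD signal
#'
#' Finds the integer volume shift that maximises the Pearson correlation
#' between the average BOLD signal and the resampled PetCO2 trace, and
#' returns the shifted CO2 trace.  A positive lag means the CO2 trace lags
#' the BOLD signal and is advanced to compensate; shifted-out samples are
#' filled by holding the edge value.  Ties are broken toward the smallest
#' absolute lag.
#'
#' @param bold_mean average BOLD time course (numeric, one value per volume).
#' @param co2_resampled PetCO2 values on the same volume grid.
#' @param max_lag maximum shift searched, in volumes (must be < length/2).
#' @return list with `co2` (aligned trace) and `lag` (volumes).
#' @export
bulk_align <- function(bold_mean, co2_resampled, max_lag = 30L) {
  n <- length(bold_mean)
  stopifnot(length(co2_resampled) == n)
  max_lag <- as.integer(max_lag)
  if (max_lag >= n / 2) stop("max_lag must be < length/2", call. = FALSE)
  b <- .best_shift(bold_mean, co2_resampled, max_lag)
  k <- b$lag
  idx <- pmin(pmax(seq_len(n) + k, 1L), n)  # advance by k, edge-hold
  list(co2 = co2_resampled[idx], lag = k)
}

# evaluate an expression with a temporary RNG state seeded by `seed`
# (NULL leaves the RNG alone)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
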