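# Forward model: BOLD response to a CO2 challenge via an exponential
# hemodynamic response function, and the coupled CSF inflow signal driven by
# the negative BOLD derivative (time-of-flight inflow sensitivity).

#' Ground-truth parameters for the forward model
#'
#' Houses the parameters of the synthetic-data generator so recovery tests
#' can compare estimates against known truth.
#'
#' @param tau_true vascular response time constant (s).
#' @param cvr_amplitude BOLD change per mmHg CO2 (signal units/mmHg).
#' @param inflow_gain inflow signal per unit negative BOLD derivative
#'   (signal units per (signal units/s)).
#' @param inflow_skew nonnegative right-skew factor for the inflow peak: the
#'   falling flank of the rectified-derivative peak is stretched by
#'   `1 + inflow_skew`, mimicking the slow tail of observed inflow peaks.
#' @param noise_sd additive Gaussian noise SD (signal units).
#' @param bold_baseline BOLD baseline signal `s0` (signal units).
#' @param inflow_baseline inflow-trace baseline (signal units).
#' @param o2_amplitude BOLD change per mmHg O2 (signal units/mmHg); the
#'   saturation-driven hyperoxic BOLD rise, 0 by default so hyperoxia is
#'   non-vasoactive and produces no inflow.
#' @param seed integer seed making the generator deterministic.
#' @return a list of class `"forward_model_params"`.
#' @export
forward_model_params <- function(tau_true = 20, cvr_amplitude = 0.2,
                                 inflow_gain = 50, inflow_skew = 0.5,
                                 noise_sd = 0.2, bold_baseline = 100,
                                 inflow_baseline = 10, o2_amplitude = 0,
                                 seed = 1L) {
  if (tau_true <= 0) stop("tau_true must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  if (inflow_skew < 0) stop("inflow_skew must be nonnegative", call. = FALSE)
  structure(list(tau_true = tau_true, cvr_amplitude = cvr_amplitude,
                 inflow_gain = inflow_gain, inflow_skew = inflow_skew,
                 noise_sd = noise_sd, bold_baseline = bold_baseline,
                 inflow_baseline = inflow_baseline,
                 o2_amplitude = o2_amplitude, seed = as.integer(seed)),
            class = "forward_model_params")
}

#' Construct a BOLD series object
#'
#' Wraps a 1-D regional trace or a 4-D voxel array together with its scan
#' timing.  The slice axis of 4-D data is the third array dimension.
#'
#' @param data numeric vector (regional trace) or 4-D array (x, y, slice,
#'   volume).
#' @param tr repetition time (s).
#' @return object of class `"bold_series"`.
#' @export
bold_series <- function(data, tr) {
  stopifnot(tr > 0)
  if (is.array(data) && length(dim(data)) == 4L) {
    n <- dim(data)[4L]
  } else {
    data <- as.numeric(data)
    n <- length(data)
  }
  if (n < 2L) stop("a BOLD series needs at least 2 volumes", call. = FALSE)
  structure(list(data = data, tr = tr, n_volumes = n, slice_axis = 3L),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  if (is.array(x$data))
    cat(sprintf("BOLD series: %s voxels x %d volumes, TR %.3f s\n",
                paste(dim(x$data)[1:3], collapse = "x"), x$n_volumes, x$tr))
  else
    cat(sprintf("BOLD series: regional trace, %d volumes, TR %.3f s\n",
                x$n_volumes, x$tr))
  invisible(x)
}

#' Simulate a regional BOLD response to a gas challenge
#'
#' The noiseless response is
#' \deqn{s(t) = s_0 + A \, (\Delta \mathrm{CO2} \otimes h_\tau)(t)}
#' with \eqn{h_\tau(t) = \tau^{-1} e^{-t/\tau}} the unit-area exponential
#' hemodynamic response function, \eqn{\Delta}CO2 the end-tidal trace minus
#' baseline, and `A` the CVR amplitude; optional hyperoxic sensitivity adds
#' `o2_amplitude * delta-O2` directly (saturation effect, not convolved with
#' the vascular kernel).  Gaussian noise of SD `noise_sd` is added with the
#' generator's seed, so output is reproducible.
#'
#' @param co2 a `"physio_trace"` (CO2).
#' @param params [forward_model_params()].
#' @param protocol the [respiratory_protocol()] providing baseline, TR and
#'   scan length.
#' @param o2 optional `"physio_trace"` (O2) for the hyperoxic saturation
#'   component.
#' @return a 1-D `"bold_series"`.
#' @export
simulate_bold <- function(co2, params, protocol, o2 = NULL) {
  stopifnot(inherits(params, "forward_model_params"),
            inherits(protocol, "respiratory_protocol"))
  tr <- protocol$tr
  n <- protocol$n_volumes
  dco2 <- resample_trace(co2, tr, n) - protocol$co2_baseline
  s <- params$bold_baseline +
    params$cvr_amplitude * convolve_exponential(dco2, params$tau_true, tr)
  if (!is.null(o2) && params$o2_amplitude != 0) {
    do2 <- resample_trace(o2, tr, n) - protocol$o2_baseline
    s <- s + params$o2_amplitude * do2
  }
  if (params$noise_sd > 0)
    s <- s + with_seed(params$seed, stats::rnorm(n, sd = params$noise_sd))
  bold_series(s, tr)
}

# reference inflow peak of a rectified-derivative trace: the first local
# maximum exceeding half the global maximum (the block-associated peak),
# and the next zero of the rectified signal after it
.inflow_reference_peak <- function(r, tt) {
  thr <- max(r) / 2
  n <- length(r)
  is_max <- c(FALSE, r[2:(n - 1)] >= r[1:(n - 2)] &
                r[2:(n - 1)] >= r[3:n], FALSE) & r >= thr
  ip <- which(is_max)[1L]
  if (is.na(ip)) ip <- which.max(r)
  after <- which(r[ip:n] <= 0)
  iz <- if (length(after)) ip + after[1L] - 1L else n
  list(tp = tt[ip], t0 = tt[iz])
}

# noiseless rectified + skew-warped inflow component of a regional trace;
# the falling flank of the reference peak is stretched by 1 + skew (up to
# the next zero of the rectified derivative, later samples shifted), and
# the component can be evaluated at arbitrary times via linear
# interpolation so the true peak width is computable on a dense grid
.inflow_component <- function(trace, tr, inflow_skew, query_times = NULL) {
  r <- pmax(0, -temporal_derivative(trace, tr))
  tt <- volume_time(seq_along(trace) - 1L, tr)
  if (is.null(query_times)) query_times <- tt
  if (max(r) == 0) return(rep(0, length(query_times)))
  ref <- .inflow_reference_peak(r, tt)
  s <- ref$t0 - ref$tp
  # stretch the early decay by 1 + skew and compress the near-zero late
  # decay so the mapping is the identity again beyond the next zero of the
  # rectified derivative -- later inflow events keep their true timing
  a <- min(0.6, 0.9 / (1 + inflow_skew))
  qa <- a * s * (1 + inflow_skew)          # query span of the stretched part
  q <- query_times
  rel <- q - ref$tp
  src <- ifelse(rel <= 0, q,
         ifelse(rel <= qa, ref$tp + rel / (1 + inflow_skew),
         ifelse(rel <= s,
                ref$tp + a * s + (rel - qa) * (1 - a) * s / (s - qa),
                q)))
  stats::approx(tt, r, xout = src, rule = 2)$y
}

#' Simulate the CSF inflow trace coupled to a BOLD response
#'
#' Time-of-flight CSF inflow responds to reductions in cerebral blood
#' volume only: the inflow component is the rectified negative temporal
#' derivative of the regional BOLD signal, `max(0, -ds/dt)`, scaled by
#' `inflow_gain`.  A right-skew is imposed by stretching the falling flank
#' of the dominant peak by `1 + inflow_skew` (slow return of displaced CSF),
#' and baseline plus Gaussian noise are added.  Epochs that do not change
#' the BOLD derivative (e.g. hyperoxia with zero vasoactivity) produce no
#' inflow, and rising BOLD never does (rectification).
#'
#' @param bold a 1-D `"bold_series"` (regional trace).
#' @param params [forward_model_params()].
#' @param noiseless logical; skip baseline noise (used by truth helpers).
#' @return a 1-D `"bold_series"` holding the inflow trace.
#' @seealso [true_inflow_hwhm()]
#' @export
simulate_csf_inflow <- function(bold, params, noiseless = FALSE) {
  stopifnot(inherits(bold, "bold_series"),
            inherits(params, "forward_model_params"))
  if (is.array(bold$data))
    stop("simulate_csf_inflow expects a regional (1-D) series",
         call. = FALSE)
  comp <- .inflow_component(bold$data, bold$tr, params$inflow_skew)
  s <- params$inflow_baseline + params$inflow_gain * comp
  if (!noiseless && params$noise_sd > 0)
    s <- s + with_seed(params$seed + 1L,
                       stats::rnorm(length(s), sd = params$noise_sd))
  bold_series(s, bold$tr)
}

#' True right-sided HWHM of the simulated inflow peak
#'
#' Evaluates the noiseless, skew-warped inflow component of a regional BOLD
#' trace on a dense time grid, locates the reference (block-associated)
#' peak, and measures the half-height width on its falling side.  This is
#' the generator-side ground truth that [hwhm_right()] estimates from
#' fitted peaks.
#'
#' @param bold a 1-D `"bold_series"` (noiseless regional trace).
#' @param params [forward_model_params()].
#' @param n_grid dense-grid resolution.
#' @return right HWHM in seconds.
#' @export
true_inflow_hwhm <- function(bold, params, n_grid = 1e5) {
  stopifnot(inherits(bold, "bold_series"))
  r <- pmax(0, -temporal_derivative(bold$data, bold$tr))
  if (max(r) == 0) stop("no inflow peak in the trace", call. = FALSE)
  tvol <- volume_time(seq_along(r) - 1L, bold$tr)
  ref <- .inflow_reference_peak(r, tvol)
  tt <- seq(0, volume_time(bold$n_volumes - 1L, bold$tr),
            length.out = n_grid)
  comp <- .inflow_component(bold$data, bold$tr, params$inflow_skew, tt)
  # the warp leaves the reference peak location fixed; search near it
  near <- which(abs(tt - ref$tp) <= 2 * bold$tr)
  ip <- near[which.max(comp[near])]
  half <- comp[ip] / 2
  if (comp[ip] <= 0) stop("no inflow peak in the trace", call. = FALSE)
  after <- comp[ip:length(comp)]
  cross <- which(after <= half)[1L]
  if (is.na(cross)) stop("half height never reached on the right",
                         call. = FALSE)
  tt[ip + cross - 1L] - tt[ip]
}

#' Inflow analysis window derived from the protocol
#'
#' The skew-normal fit window runs from the end of the hypercapnic block to
#' the midpoint between the block end and the peak of the hypercapnic ramp,
#' so the full tail of the block-associated inflow peak is captured while
#' the ramp-end inflow peak stays outside the window.
#'
#' @param protocol a [respiratory_protocol()].
#' @return integer `c(start, end)` of 0-based volume indices.
#' @export
inflow_window_from_protocol <- function(protocol) {
  ep <- protocol_epochs(protocol)
  blk <- ep[ep$kind == "hypercapnic_block", ][1, ]
  rmp <- ep[ep$kind == "hypercapnic_ramp", ][1, ]
  if (any(is.na(blk$end)) || any(is.na(rmp$end)))
    stop("protocol lacks a hypercapnic block or ramp", call. = FALSE)
  start <- round(blk$end / protocol$tr)
  mid <- (blk$end + rmp$end) / 2
  end <- min(floor(mid / protocol$tr), protocol$n_volumes - 1L)
  c(as.integer(start), as.integer(end))
}
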