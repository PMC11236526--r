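# Gas-challenge respiratory protocols: ordered epochs with end-tidal targets.

.epoch_kinds <- c("baseline", "hypercapnic_block", "hypercapnic_ramp",
                  "hyperoxic_block")

#' Construct a respiratory gas-challenge protocol
#'
#' A protocol is an ordered sequence of epochs, each a plateau or ramp in
#' end-tidal CO2 relative to the subject's baseline, or a hyperoxic plateau
#' with an absolute end-tidal O2 target.  The protocol also carries the scan
#' timing (repetition time and number of volumes); trailing epochs extending
#' past the scan are simply truncated, and scan time past the last epoch sits
#' at baseline.
#'
#' @param epochs data.frame with columns `kind` (one of `"baseline"`,
#'   `"hypercapnic_block"`, `"hypercapnic_ramp"`, `"hyperoxic_block"`),
#'   `duration` (s), `co2_delta` (mmHg above baseline; maximum delta for a
#'   ramp), `o2_target` (absolute mmHg, `NA` except for hyperoxic epochs).
#' @param co2_baseline,o2_baseline baseline end-tidal pressures (mmHg).
#' @param tr repetition time (s).
#' @param n_volumes number of acquired volumes.
#' @return an object of class `"respiratory_protocol"`.
#' @seealso [default_protocol()], [render_traces()]
#' @export
respiratory_protocol <- function(epochs, co2_baseline = 40, o2_baseline = 110,
                                 tr = 1.05, n_volumes = 1000L) {
  stopifnot(is.data.frame(epochs),
            all(c("kind", "duration", "co2_delta", "o2_target") %in%
                  names(epochs)))
  if (!all(epochs$kind %in% .epoch_kinds))
    stop("unknown epoch kind(s): ",
         paste(setdiff(epochs$kind, .epoch_kinds), collapse = ", "),
         call. = FALSE)
  if (any(epochs$duration <= 0))
    stop("epoch durations must be strictly positive", call. = FALSE)
  bad_delta <- epochs$kind %in% c("baseline", "hyperoxic_block") &
    epochs$co2_delta != 0
  if (any(bad_delta))
    stop("co2_delta must be 0 for baseline and hyperoxic epochs",
         call. = FALSE)
  if (any(!is.na(epochs$o2_target) & epochs$kind != "hyperoxic_block"))
    stop("o2_target may only be set for hyperoxic epochs", call. = FALSE)
  if (any(epochs$kind == "hyperoxic_block" & is.na(epochs$o2_target)))
    stop("hyperoxic epochs require an o2_target", call. = FALSE)
  if (tr <= 0) stop("tr must be positive", call. = FALSE)
  n_volumes <- as.integer(n_volumes)
  if (n_volumes < 1L) stop("protocol must cover at least one volume",
                           call. = FALSE)
  structure(
    list(epochs = epochs, co2_baseline = co2_baseline,
         o2_baseline = o2_baseline, tr = tr, n_volumes = n_volumes),
    class = "respiratory_protocol")
}

#' Default hypercapnic/hyperoxic gas-challenge protocol
#'
#' Builds the standard paradigm: a 90-s hypercapnic block (+10 mmHg), a 120-s
#' hypercapnic ramp rising to +12 mmHg, and a 180-s hyperoxic block targeting
#' 680 mmHg, each interleaved with 120-s baselines, at TR = 1.05 s over 1000
#' volumes.  The leading baseline defaults to 172.5 s so the hypercapnic
#' block ends exactly at volume 250 (262.5 s), the anchor used by the default
#' analysis windows; it is a parameter because acquisition setups differ.
#'
#' @param lead_baseline duration (s) of the baseline before the first block.
#' @param block_duration,block_delta hypercapnic block length (s) and CO2
#'   step (mmHg).
#' @param ramp_duration,ramp_delta hypercapnic ramp length (s) and maximum
#'   CO2 excursion (mmHg).
#' @param hyperoxia_duration,o2_target hyperoxic block length (s) and target
#'   end-tidal O2 (mmHg).
#' @param interleave_baseline duration (s) of each interleaved baseline.
#' @inheritParams respiratory_protocol
#' @return a `"respiratory_protocol"`.
#' @examples
#' p <- default_protocol()
#' volume_time(250, p$tr)  # end of the hypercapnic block, in seconds
#' @export
default_protocol <- function(lead_baseline = 172.5,
                             block_duration = 90, block_delta = 10,
                             ramp_duration = 120, ramp_delta = 12,
                             hyperoxia_duration = 180, o2_target = 680,
                             interleave_baseline = 120,
                             co2_baseline = 40, o2_baseline = 110,
                             tr = 1.05, n_volumes = 1000L) {
  epochs <- data.frame(
    kind = c("baseline", "hypercapnic_block", "baseline", "hypercapnic_ramp",
             "baseline", "hyperoxic_block", "baseline"),
    duration = c(lead_baseline, block_duration, interleave_baseline,
                 ramp_duration, interleave_baseline, hyperoxia_duration,
                 interleave_baseline),
    co2_delta = c(0, block_delta, 0, ramp_delta, 0, 0, 0),
    o2_target = c(NA, NA, NA, NA, NA, o2_target, NA))
  respiratory_protocol(epochs, co2_baseline = co2_baseline,
                       o2_baseline = o2_baseline, tr = tr,
                       n_volumes = n_volumes)
}

#' Time of an imaging volume
#'
#' Volumes are numbered from 0, so volume `k` is acquired at `k * tr`
#' seconds; with TR = 1.05 s, volume 250 maps to 262.5 s.
#'
#' @param volume volume index (0-based), vectorised.
#' @param tr repetition time (s).
#' @return acquisition time in seconds.
#' @export
volume_time <- function(volume, tr) {
  stopifnot(tr > 0, all(volume >= 0))
  volume * tr
}

#' @export
print.respiratory_protocol <- function(x, ...) {
  cat("Respiratory gas-challenge protocol\n")
  cat(sprintf("  TR %.3f s, %d volumes (%.1f s scan)\n", x$tr, x$n_volumes,
              x$tr * x$n_volumes))
  cat(sprintf("  baselines: PetCO2 %.0f mmHg, PetO2 %.0f mmHg\n",
              x$co2_baseline, x$o2_baseline))
  t0 <- cumsum(c(0, x$epochs$duration))
  for (i in seq_len(nrow(x$epochs))) {
    e <- x$epochs[i, ]
    extra <- switch(e$kind,
      hypercapnic_block = sprintf(" (+%g mmHg CO2)", e$co2_delta),
      hypercapnic_ramp  = sprintf(" (ramp to +%g mmHg CO2)", e$co2_delta),
      hyperoxic_block   = sprintf(" (O2 target %g mmHg)", e$o2_target),
      "")
    cat(sprintf("  %7.1f-%7.1f s  %s%s\n", t0[i], t0[i + 1], e$kind, extra))
  }
  invisible(x)
}

.protocol_epoch_times <- function(protocol) {
  t0 <- cumsum(c(0, protocol$epochs$duration))
  data.frame(kind = protocol$epochs$kind,
             start = t0[-length(t0)], end = t0[-1],
             co2_delta = protocol$epochs$co2_delta,
             o2_target = protocol$epochs$o2_target)
}

#' Epoch volume windows of a protocol
#'
#' Returns, for each epoch, its start/end times and the corresponding
#' (0-based) volume indices, useful for defining analysis windows.
#'
#' @param protocol a `"respiratory_protocol"`.
#' @return data.frame with columns kind, start, end, start_volume,
#'   end_volume.
#' @export
protocol_epochs <- function(protocol) {
  stopifnot(inherits(protocol, "respiratory_protocol"))
  ep <- .protocol_epoch_times(protocol)
  ep$start_volume <- ep$start / protocol$tr
  ep$end_volume <- ep$end / protocol$tr
  ep
}
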