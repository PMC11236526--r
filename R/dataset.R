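# Full synthetic dataset: 4-D BOLD volume, tissue/edema masks, end-tidal
# traces, and the generating truth, assembled from the forward model.

#' Simulate a complete gas-challenge dataset
#'
#' Assembles everything the analysis pipeline consumes: end-tidal CO2/O2
#' traces rendered from the protocol, a 4-D BOLD volume in which gray
#' matter carries the exponential-HRF CO2 response (attenuated in white
#' matter and in edematous tissue), CSF inflow voxels in the bottom two
#' slices carrying the rectified-derivative inflow signal, tissue and edema
#' masks, and per-voxel Gaussian noise.  The generating parameters and the
#' derived ground truth (edema fraction, dense-grid inflow HWHM) are
#' returned in `$truth`.
#'
#' @param protocol a [respiratory_protocol()].
#' @param params [forward_model_params()].
#' @param shape 3-D grid (kept deliberately small; the signal model, not
#'   the anatomy, is what downstream estimators consume).
#' @param edema_fraction_target target edema load.
#' @param n_inflow_voxels inflow-carrying voxels placed per bottom slice.
#' @param transition_time end-tidal transition length (s) passed to
#'   [render_traces()].
#' @param wm_gain,edema_gain CVR attenuation factors for white matter and
#'   edema-labelled voxels.
#' @return an object of class `"csf_dataset"`: list with `bold` (4-D
#'   `"bold_series"`), `masks`, `co2`, `o2`, `protocol`, `truth`.
#' @export
simulate_dataset <- function(protocol = default_protocol(),
                             params = forward_model_params(),
                             shape = c(12L, 12L, 6L),
                             edema_fraction_target = 0.05,
                             n_inflow_voxels = 5L,
                             transition_time = 10,
                             wm_gain = 0.4, edema_gain = 0.2) {
  stopifnot(inherits(protocol, "respiratory_protocol"),
            inherits(params, "forward_model_params"))
  tr <- protocol$tr
  n <- protocol$n_volumes
  traces <- render_traces(protocol, dt = 0.25,
                          transition_time = transition_time)
  masks <- simulate_masks(shape, edema_fraction_target,
                          seed = params$seed)
  # noiseless regional response and its inflow counterpart
  p0 <- params
  p0$noise_sd <- 0
  bold_clean <- simulate_bold(traces$co2, p0, protocol, o2 = traces$o2)
  response <- bold_clean$data - params$bold_baseline
  # CSF inflow is driven by CBV change, i.e. by the vasoactive (CO2)
  # component only -- the hyperoxic saturation effect raises BOLD without
  # moving blood volume and must not generate inflow
  bold_vaso <- simulate_bold(traces$co2, p0, protocol)
  inflow_clean <- simulate_csf_inflow(bold_vaso, p0, noiseless = TRUE)
  truth_hwhm <- if (max(inflow_clean$data) > params$inflow_baseline)
    true_inflow_hwhm(bold_vaso, params) else NA_real_
  tissue_base <- c(gm = 100, wm = 80, csf = 120, none = 50)
  vol <- with_seed(params$seed + 2L, {
    arr <- array(stats::rnorm(prod(shape) * n, sd = params$noise_sd),
                 c(shape, n))
    gain <- array(0, shape)
    base <- array(tissue_base["none"], shape)
    base[masks$gm] <- tissue_base["gm"]
    base[masks$wm] <- tissue_base["wm"]
    base[masks$csf] <- tissue_base["csf"]
    gain[masks$gm] <- 1
    gain[masks$wm] <- wm_gain
    gain[masks$edema] <- edema_gain
    idx <- which(array(TRUE, shape))
    for (v in seq_len(n))
      arr[idx + (v - 1L) * prod(shape)] <-
        arr[idx + (v - 1L) * prod(shape)] + base + gain * response[v]
    # place inflow voxels at the centre of the two bottom slices
    cx <- round(shape[1] / 2); cy <- round(shape[2] / 2)
    for (s in 1:2) {
      for (k in seq_len(n_inflow_voxels)) {
        arr[cx + k - 1L, cy, s, ] <- inflow_clean$data +
          stats::rnorm(n, sd = params$noise_sd)
      }
    }
    arr
  })
  truth <- list(params = params,
                edema_fraction = attr(masks, "true_edema_fraction"),
                hwhm_right = truth_hwhm,
                inflow_voxels = data.frame(
                  x = rep(round(shape[1] / 2) + seq_len(n_inflow_voxels) - 1L,
                          2),
                  y = round(shape[2] / 2),
                  slice = rep(1:2, each = n_inflow_voxels)))
  structure(list(bold = bold_series(vol, tr), masks = masks,
                 co2 = traces$co2, o2 = traces$o2, protocol = protocol,
                 gm_clean = bold_clean, inflow_clean = inflow_clean,
                 truth = truth),
            class = "csf_dataset")
}

#' @export
print.csf_dataset <- function(x, ...) {
  cat("Synthetic gas-challenge dataset\n")
  print(x$bold)
  print(x$masks)
  cat(sprintf("  truth: tau %.3g s, edema fraction %.3g, inflow HWHM %.3g s\n",
              x$truth$params$tau_true, x$truth$edema_fraction,
              x$truth$hwhm_right))
  invisible(x)
}
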