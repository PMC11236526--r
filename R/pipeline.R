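# Pipeline orchestration: per-subject analysis (preprocess -> tau fit ->
# inflow fit -> coupling lags) and cohort-level statistics.

#' Build and validate a pipeline configuration
#'
#' Paths may be omitted when an in-memory `dataset` (a `"csf_dataset"`) is
#' supplied instead.  All windows are 0-based volume indices, inclusive.
#'
#' @param bold,masks,co2,o2 input paths (NIfTI / NIfTI directory / CSV).
#' @param dataset optional in-memory `"csf_dataset"` replacing the paths.
#' @param out_dir output directory (`NULL` = write nothing).
#' @param id subject/dataset identifier.
#' @param timepoint `"pre"` or `"post"`.
#' @param tau_window,tau_grid tau-fit window and grid (see [fit_tau()]).
#' @param inflow_window skew-normal fit window (see [fit_inflow_peak()]).
#' @param contrast_window window for inflow-voxel contrast ranking
#'   (`NULL` = `inflow_window`).
#' @param k_voxels inflow voxels per slice.
#' @param baseline_window window used to estimate the inflow baseline noise
#'   for the presence screen.
#' @param presence_factor inflow declared present when the windowed peak
#'   exceeds `presence_factor` baseline SDs (default 3).
#' @param inflow_present manual override for the presence screen
#'   (`NULL` = automatic).
#' @param align_co2 bulk-align the CO2 trace to the whole-brain BOLD signal
#'   before fitting (default `TRUE`).  The alignment compensates the clock
#'   offset and gas transit of a real acquisition; disable it for synthetic
#'   data whose traces are already synchronised, where the max-correlation
#'   shift would instead absorb part of the response delay under study.
#' @param denoise_level wavelet decomposition depth.
#' @param dilate_edema edema-mask dilation steps before GM exclusion.
#' @param max_lag cross-correlation search range (s).
#' @param tr TR override when the NIfTI header lacks one.
#' @param seed recorded in every output.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(bold = NULL, masks = NULL, co2 = NULL, o2 = NULL,
                            dataset = NULL, out_dir = NULL, id = "subject",
                            timepoint = c("pre", "post"),
                            tau_window = c(250L, 450L),
                            tau_grid = seq(0.5, 120, by = 0.5),
                            inflow_window = c(250L, 525L),
                            contrast_window = NULL, k_voxels = 5L,
                            baseline_window = c(0L, 150L),
                            presence_factor = 3, inflow_present = NULL,
                            align_co2 = TRUE,
                            denoise_level = 2L, dilate_edema = 1L,
                            max_lag = 30, tr = NULL, seed = 1L) {
  timepoint <- match.arg(timepoint)
  if (is.null(dataset)) {
    missing_in <- c(bold = is.null(bold), masks = is.null(masks),
                    co2 = is.null(co2))
    if (any(missing_in))
      stop("missing input(s): ",
           paste(names(missing_in)[missing_in], collapse = ", "),
           " (or supply `dataset`)", call. = FALSE)
    for (f in c(bold, co2, o2))
      if (!file.exists(f)) stop("input not found: ", f, call. = FALSE)
    if (!dir.exists(masks)) stop("mask directory not found: ", masks,
                                 call. = FALSE)
  } else {
    stopifnot(inherits(dataset, "csf_dataset"))
  }
  structure(list(bold = bold, masks = masks, co2 = co2, o2 = o2,
                 dataset = dataset, out_dir = out_dir, id = id,
                 timepoint = timepoint, tau_window = as.integer(tau_window),
                 tau_grid = tau_grid,
                 inflow_window = as.integer(inflow_window),
                 contrast_window = contrast_window, k_voxels = k_voxels,
                 baseline_window = as.integer(baseline_window),
                 presence_factor = presence_factor,
                 inflow_present = inflow_present,
                 align_co2 = isTRUE(align_co2),
                 denoise_level = as.integer(denoise_level),
                 dilate_edema = as.integer(dilate_edema),
                 max_lag = max_lag, tr = tr, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips every scalar field of [pipeline_config()]; in-memory
#' datasets are not serialised.
#'
#' @param config a `"pipeline_config"`.
#' @param path YAML file path.
#' @return `read_config` returns a `"pipeline_config"`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$dataset <- NULL
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

# core per-subject computation on in-memory objects
.analyze_subject <- function(bold, masks, co2, o2, cfg) {
  tr <- bold$tr
  n <- bold$n_volumes
  for (w in list(cfg$tau_window, cfg$inflow_window, cfg$baseline_window))
    .window_index(w, n)                      # validate before computing
  t_all <- system.time({
    ef <- edema_fraction(masks)
    masks_d <- if (cfg$dilate_edema > 0)
      dilate_mask(masks, "edema", cfg$dilate_edema) else masks
    gm_mean <- extract_regional_mean(bold, masks_d, "gm", exclude = "edema")
    wb_mean <- extract_regional_mean(bold, masks_d, "brain")
    gm_dn <- denoise_wavelet(gm_mean, level = cfg$denoise_level)
    dbold <- temporal_derivative(gm_dn, tr)
    co2_rs <- resample_trace(co2, tr, n)
    max_lag_vol <- max(1L, floor(cfg$max_lag / tr))
    aligned <- if (cfg$align_co2)
      bulk_align(wb_mean, co2_rs, max_lag = max_lag_vol)
    else list(co2 = co2_rs, lag = 0L)
    tau_fit <- fit_tau(gm_dn, aligned$co2, tr, window = cfg$tau_window,
                       tau_grid = cfg$tau_grid)
    sel <- select_inflow_voxels(
      bold, n_bottom_slices = 2L,
      contrast_window = if (is.null(cfg$contrast_window)) cfg$inflow_window
      else cfg$contrast_window,
      k_voxels = cfg$k_voxels)
    inflow_dn <- denoise_wavelet(sel$trace, level = cfg$denoise_level)
    base_idx <- .window_index(cfg$baseline_window, n)
    # noise level of the raw trace; excursions of the de-noised trace are
    # screened against it
    base_sd <- stats::sd(sel$trace[base_idx])
    base_med <- stats::median(inflow_dn[base_idx])
    peak_idx <- .window_index(cfg$inflow_window, n)
    peak_excess <- max(inflow_dn[peak_idx]) - base_med
    present <- if (!is.null(cfg$inflow_present)) isTRUE(cfg$inflow_present)
    else is.finite(base_sd) && base_sd > 0 &&
      peak_excess > cfg$presence_factor * base_sd
    inflow_fit <- NULL
    if (present) {
      inflow_fit <- tryCatch(
        fit_inflow_peak(inflow_dn, tr, window = cfg$inflow_window),
        error = function(e) {
          warning("inflow peak fit failed: ", conditionMessage(e))
          NULL
        })
    }
    # the inflow peaks are analysed against the derivatives over the
    # inflow window, so the lag refers to the block-associated event
    dco2 <- temporal_derivative(aligned$co2, tr)
    wi <- .window_index(cfg$inflow_window, n)
    lag_cbv <- shifted_crosscorr(-dbold[wi], inflow_dn[wi], tr,
                                 cfg$max_lag)
    lag_co2 <- shifted_crosscorr(-dco2[wi], inflow_dn[wi], tr,
                                 cfg$max_lag)
  })
  list(id = cfg$id, timepoint = cfg$timepoint, seed = cfg$seed,
       n_volumes = n, tr = tr,
       parameters = list(tau_window = cfg$tau_window,
                         tau_grid_range = range(cfg$tau_grid),
                         inflow_window = cfg$inflow_window,
                         denoise_level = cfg$denoise_level,
                         dilate_edema = cfg$dilate_edema,
                         presence_factor = cfg$presence_factor,
                         max_lag = cfg$max_lag),
       bulk_lag_volumes = aligned$lag,
       tau = list(tau = tau_fit$tau, beta0 = tau_fit$beta0,
                  beta1 = tau_fit$beta1, rss = tau_fit$rss),
       inflow_present = present,
       inflow_peak_excess_sd = if (is.finite(base_sd) && base_sd > 0)
         peak_excess / base_sd else NA_real_,
       inflow = if (!is.null(inflow_fit))
         c(as.list(coef(inflow_fit)),
           list(hwhm_right = inflow_fit$hwhm_right,
                rss = inflow_fit$rss)) else NULL,
       lag_inflow_vs_cbv = list(lag_s = lag_cbv$lag, r = lag_cbv$r_max),
       lag_inflow_vs_co2 = list(lag_s = lag_co2$lag, r = lag_co2$r_max),
       edema_fraction = ef,
       elapsed_s = unname(t_all["elapsed"]),
       traces = list(gm_denoised = gm_dn, inflow_denoised = inflow_dn,
                     co2_aligned = aligned$co2, bold_derivative = dbold))
}

#' Run the per-subject analysis pipeline
#'
#' Loads the inputs named in the configuration (or uses its in-memory
#' dataset), runs signal conditioning, the tau fit, inflow-voxel selection
#' and peak fitting, the inflow-presence screen, and the coupling lags, and
#' writes a JSON report plus CSV trace exports when `out_dir` is set.  The
#' JSON report contains no timestamps, so identical configurations produce
#' byte-identical reports.
#'
#' @param config a [pipeline_config()].
#' @return the report, invisibly (a nested list; see the JSON layout).
#' @export
run_subject <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$dataset)) {
    ds <- config$dataset
    bold <- ds$bold; masks <- ds$masks; co2 <- ds$co2; o2 <- ds$o2
  } else {
    bold <- read_bold_nifti(config$bold, tr = config$tr)
    masks <- read_masks_nifti(config$masks)
    co2 <- read_trace_csv(config$co2, "CO2")
    o2 <- if (!is.null(config$o2)) read_trace_csv(config$o2, "O2") else NULL
    if (!identical(dim(bold$data)[1:3], as.integer(masks$dim)))
      stop("configuration error: BOLD grid ",
           paste(dim(bold$data)[1:3], collapse = "x"),
           " does not match mask grid ",
           paste(masks$dim, collapse = "x"), call. = FALSE)
  }
  report <- .analyze_subject(bold, masks, co2, o2, config)
  message(sprintf("[%s/%s] tau = %.2f s, inflow %s, edema %.3f (%.1f s)",
                  report$id, report$timepoint, report$tau$tau,
                  if (report$inflow_present) "present" else "absent",
                  report$edema_fraction, report$elapsed_s))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    traces <- report$traces
    out <- report
    out$traces <- NULL
    out$elapsed_s <- NULL                    # keep reports byte-identical
    jsonlite::write_json(
      out, file.path(config$out_dir,
                     paste0(report$id, "_", report$timepoint, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(
      as.data.frame(traces),
      file.path(config$out_dir,
                paste0(report$id, "_", report$timepoint, "_traces.csv")),
      row.names = FALSE)
  }
  invisible(report)
}

# one row of the cohort table from a subject report (robust to reports
# round-tripped through JSON, where an absent inflow fit may come back as
# an empty list)
.group_record <- function(r) {
  hw <- r$inflow$hwhm_right
  data.frame(id = r$id, timepoint = r$timepoint, tau = r$tau$tau,
             hwhm_right = if (length(hw) == 1L && is.finite(hw))
               as.numeric(hw) else NA_real_,
             edema_fraction = r$edema_fraction,
             inflow_present = isTRUE(r$inflow_present))
}

#' Cohort-level statistics over subject reports
#'
#' Collects subject reports (in-memory lists from [run_subject()] or paths
#' to their JSON files) into a cohort table, regresses tau on edema load
#' (all datasets) and on inflow HWHM (datasets with inflow only), and runs
#' the paired pre/post comparison of tau for subjects measured twice.
#' Analyses lacking enough data are omitted with an explanatory note rather
#' than failing.
#'
#' @param reports list of reports and/or JSON paths.
#' @param out_dir optional output directory for `cohort.csv` and
#'   `group.json`.
#' @return list with `table` (one row per dataset), `tau_vs_edema`,
#'   `tau_vs_hwhm`, `paired_tau`, and `notes`.
#' @export
run_cohort <- function(reports, out_dir = NULL) {
  reports <- lapply(reports, function(r) {
    if (is.character(r)) jsonlite::read_json(r, simplifyVector = TRUE)
    else r
  })
  tab <- do.call(rbind, lapply(reports, .group_record))
  notes <- character()
  tau_vs_edema <- tau_vs_hwhm <- paired_tau <- NULL
  if (nrow(tab) >= 3L && stats::sd(tab$edema_fraction) > 0) {
    tau_vs_edema <- regress(tab$edema_fraction, tab$tau)
  } else notes <- c(notes, "tau-vs-edema regression omitted: fewer than 3 datasets or constant edema load")
  infl <- tab[tab$inflow_present & is.finite(tab$hwhm_right), ]
  if (nrow(infl) >= 3L && stats::sd(infl$hwhm_right) > 0) {
    tau_vs_hwhm <- regress(infl$hwhm_right, infl$tau)
  } else notes <- c(notes, "tau-vs-HWHM regression omitted: fewer than 3 inflow datasets")
  pre <- tab[tab$timepoint == "pre", ]
  post <- tab[tab$timepoint == "post", ]
  both <- intersect(pre$id, post$id)
  if (length(both) >= 2L) {
    paired_tau <- tryCatch(
      paired_change_test(pre$tau[match(both, pre$id)],
                         post$tau[match(both, post$id)]),
      error = function(e) {
        notes <<- c(notes, paste("paired pre/post test omitted:",
                                 conditionMessage(e)))
        NULL
      })
  } else notes <- c(notes, "paired pre/post test omitted: fewer than 2 paired subjects")
  out <- list(table = tab, tau_vs_edema = tau_vs_edema,
              tau_vs_hwhm = tau_vs_hwhm, paired_tau = paired_tau,
              notes = notes)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    js <- out
    js$table <- NULL
    js$tau_vs_edema <- unclass(js$tau_vs_edema)
    js$tau_vs_hwhm <- unclass(js$tau_vs_hwhm)
    jsonlite::write_json(js, file.path(out_dir, "group.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
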