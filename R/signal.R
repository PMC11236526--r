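# Regional signal extraction and the temporal derivative used as a CBV
# change surrogate.

#' Mean regional time course with optional exclusion
#'
#' Averages the 4-D BOLD data over voxels carrying the `include` label and,
#' optionally, not carrying the `exclude` label (e.g. gray matter excluding
#' dilated edema, to restrict the fit to presumed healthy tissue).
#'
#' @param bold a 4-D `"bold_series"`.
#' @param mask a `"mask_volume"` on the same grid.
#' @param include label to average over.
#' @param exclude label to remove from the selection (or `NULL`).
#' @return numeric vector, one value per volume.
#' @export
extract_regional_mean <- function(bold, mask, include = "gm",
                                  exclude = NULL) {
  stopifnot(inherits(bold, "bold_series"), inherits(mask, "mask_volume"))
  if (!is.array(bold$data) || length(dim(bold$data)) != 4L)
    stop("extract_regional_mean expects 4-D BOLD data", call. = FALSE)
  if (!identical(dim(bold$data)[1:3], as.integer(mask$dim)))
    stop("BOLD and mask grids differ", call. = FALSE)
  if (!include %in% .mask_labels)
    stop("unknown label '", include, "'", call. = FALSE)
  sel <- mask[[include]]
  if (!is.null(exclude)) {
    if (!exclude %in% .mask_labels)
      stop("unknown label '", exclude, "'", call. = FALSE)
    sel <- sel & !mask[[exclude]]
  }
  if (!any(sel))
    stop("empty region: no voxels remain after exclusion", call. = FALSE)
  mat <- matrix(bold$data, prod(mask$dim), bold$n_volumes)
  colMeans(mat[as.vector(sel), , drop = FALSE])
}

#' Temporal derivative of a regional trace
#'
#' Central differences in the interior and one-sided differences at the
#' ends, divided by the repetition time; used as a surrogate for the rate of
#' cerebral blood volume change.  Output length equals input length.
#'
#' @param trace numeric vector (one value per volume).
#' @param tr repetition time (s).
#' @return numeric vector of derivatives (signal units per second).
#' @export
temporal_derivative <- function(trace, tr) {
  trace <- as.numeric(trace)
  n <- length(trace)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  stopifnot(tr > 0)
  d <- numeric(n)
  d[1] <- (trace[2] - trace[1]) / tr
  d[n] <- (trace[n] - trace[n - 1]) / tr
  if (n > 2L)
    d[2:(n - 1)] <- (trace[3:n] - trace[1:(n - 2)]) / (2 * tr)
  d
}
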