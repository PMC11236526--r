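# File interchange: NIfTI-1 volumes (TR in the header), two-column CSV gas
# traces, and flat JSON/YAML truth and config files.

#' Write a BOLD series as NIfTI-1
#'
#' The repetition time is recorded in `pixdim[4]` of the header.
#'
#' @param bold a `"bold_series"` (4-D, or 1-D written as a 1x1x1xT volume).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxdim voxel dimensions (mm).
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(bold, path, voxdim = c(2.3, 2.3, 2.5)) {
  stopifnot(inherits(bold, "bold_series"))
  arr <- bold$data
  if (!is.array(arr)) arr <- array(arr, c(1L, 1L, 1L, length(arr)))
  img <- RNifti::asNifti(arr)
  h <- RNifti::niftiHeader(img)
  h$pixdim[2:5] <- c(voxdim, bold$tr)
  RNifti::writeNifti(RNifti::asNifti(arr, reference = h), path)
  invisible(path)
}

#' Read a BOLD series from NIfTI-1
#'
#' @param path NIfTI file.
#' @param tr repetition time override (s); default: `pixdim[4]` from the
#'   header.
#' @return a `"bold_series"`.
#' @export
read_bold_nifti <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(tr)) {
    pd <- RNifti::pixdim(img)
    if (length(pd) < 4L || pd[4] <= 0)
      stop("no usable TR in the NIfTI header of ", path,
           "; pass tr explicitly", call. = FALSE)
    tr <- pd[4]
  }
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) == 4L && all(dim(arr)[1:3] == 1L))
    arr <- as.numeric(arr)
  bold_series(arr, tr)
}

#' Write mask volumes as NIfTI-1 files
#'
#' One file per label (`brain.nii.gz`, `gm.nii.gz`, ...) in `dir`.
#'
#' @param mask a `"mask_volume"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_masks_nifti <- function(mask, dir) {
  stopifnot(inherits(mask, "mask_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in .mask_labels) {
    arr <- array(as.integer(mask[[nm]]), mask$dim)
    img <- RNifti::asNifti(arr)
    h <- RNifti::niftiHeader(img)
    h$pixdim[2:4] <- mask$voxdim
    RNifti::writeNifti(RNifti::asNifti(arr, reference = h),
                       file.path(dir, paste0(nm, ".nii.gz")))
  }
  invisible(dir)
}

#' Read mask volumes written by [write_masks_nifti()]
#'
#' @param dir directory containing `brain/gm/wm/csf/edema` NIfTI files.
#' @return a `"mask_volume"`.
#' @export
read_masks_nifti <- function(dir) {
  get1 <- function(nm) {
    f <- file.path(dir, paste0(nm, c(".nii.gz", ".nii")))
    f <- f[file.exists(f)][1]
    if (is.na(f)) stop("mask file for '", nm, "' not found in ", dir,
                       call. = FALSE)
    img <- RNifti::readNifti(f)
    list(arr = array(as.numeric(img) != 0, dim(img)),
         voxdim = RNifti::pixdim(img)[1:3])
  }
  m <- lapply(.mask_labels, get1)
  names(m) <- .mask_labels
  mask_volume(m$brain$arr, m$gm$arr, m$wm$arr, m$csf$arr, m$edema$arr,
              voxdim = m$brain$voxdim)
}

#' Write a gas trace as two-column CSV
#'
#' Columns `time_s` and `mmHg`.
#'
#' @param trace a `"physio_trace"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$times, mmHg = trace$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a gas trace from a two-column file
#'
#' Accepts the `time_s,mmHg` CSV written by [write_trace_csv()] or any
#' two-column whitespace/comma-delimited time/value text file.
#'
#' @param path input file.
#' @param gas `"CO2"` or `"O2"`.
#' @return a `"physio_trace"`.
#' @export
read_trace_csv <- function(path, gas = c("CO2", "O2")) {
  gas <- match.arg(gas)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, header = header, sep = sep)
  physio_trace(df[[1]], df[[2]], gas)
}

#' Write a dataset to disk in interchange formats
#'
#' BOLD and masks as NIfTI-1, gas traces as CSV, the generating truth as
#' flat JSON (`truth.json`).
#'
#' @param dataset a `"csf_dataset"` from [simulate_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "csf_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bold_nifti(dataset$bold, file.path(dir, "bold.nii.gz"),
                   voxdim = dataset$masks$voxdim)
  write_masks_nifti(dataset$masks, file.path(dir, "masks"))
  write_trace_csv(dataset$co2, file.path(dir, "co2.csv"))
  write_trace_csv(dataset$o2, file.path(dir, "o2.csv"))
  truth <- dataset$truth
  flat <- c(unclass(truth$params),
            list(edema_fraction = truth$edema_fraction,
                 hwhm_right = truth$hwhm_right))
  jsonlite::write_json(flat, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
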