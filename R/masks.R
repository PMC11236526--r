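# Mask volumes: brain/tissue/edema label arrays, morphological dilation,
# and the synthetic anatomy generator.

.mask_labels <- c("brain", "gm", "wm", "csf", "edema")

#' Construct a mask volume
#'
#' A set of co-registered 3-D logical arrays: a whole-brain mask, a
#' GM/WM/CSF tissue partition (subsets of brain), and an edema mask (which
#' may overlap tissue labels).
#'
#' @param brain,gm,wm,csf,edema logical 3-D arrays of identical dimension.
#' @param voxdim voxel dimensions in mm (length 3).
#' @return object of class `"mask_volume"`.
#' @export
mask_volume <- function(brain, gm, wm, csf, edema = NULL,
                        voxdim = c(2.3, 2.3, 2.5)) {
  dims <- dim(brain)
  if (length(dims) != 3L) stop("masks must be 3-D arrays", call. = FALSE)
  if (is.null(edema)) edema <- array(FALSE, dims)
  m <- list(brain = brain, gm = gm, wm = wm, csf = csf, edema = edema)
  for (nm in names(m)) {
    if (!identical(dim(m[[nm]]), dims))
      stop("mask '", nm, "' dimension mismatch", call. = FALSE)
    storage.mode(m[[nm]]) <- "logical"
  }
  for (nm in c("gm", "wm", "csf"))
    if (any(m[[nm]] & !m$brain))
      stop("tissue mask '", nm, "' extends outside the brain mask",
           call. = FALSE)
  structure(c(m, list(dim = dims, voxdim = as.numeric(voxdim))),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("Mask volume %s (voxels %.2gx%.2gx%.2g mm)\n",
              paste(x$dim, collapse = "x"),
              x$voxdim[1], x$voxdim[2], x$voxdim[3]))
  for (nm in .mask_labels)
    cat(sprintf("  %-5s %d voxels\n", nm, sum(x[[nm]])))
  invisible(x)
}

# one face-connected (6-connectivity) dilation step of a logical array
.dilate6_once <- function(a) {
  d <- dim(a)
  out <- a
  shift <- function(a, axis, by) {
    idx <- lapply(d, seq_len)
    src <- idx
    src[[axis]] <- pmin(pmax(idx[[axis]] - by, 1L), d[axis])
    keep <- idx[[axis]] - by >= 1L & idx[[axis]] - by <= d[axis]
    r <- do.call(`[`, c(list(a), src, list(drop = FALSE)))
    # zero out wrapped positions
    zidx <- which(!keep)
    if (length(zidx)) {
      sel <- lapply(d, seq_len)
      sel[[axis]] <- zidx
      r <- do.call(`[<-`, c(list(r), sel, list(value = FALSE)))
    }
    r
  }
  for (axis in 1:3)
    for (by in c(-1L, 1L))
      out <- out | shift(a, axis, by)
  out
}

#' Dilate one label of a mask volume
#'
#' Morphological dilation by `voxels` steps of the face-adjacent
#' (6-connectivity) structuring element — one step turns an isolated voxel
#' into a 7-voxel cross.  Other labels are unchanged.
#'
#' @param mask a `"mask_volume"`.
#' @param label one of `"brain"`, `"gm"`, `"wm"`, `"csf"`, `"edema"`.
#' @param voxels number of dilation steps (0 = identity).
#' @return the mask volume with the named label dilated.
#' @export
dilate_mask <- function(mask, label = "edema", voxels = 1L) {
  stopifnot(inherits(mask, "mask_volume"))
  if (!label %in% .mask_labels)
    stop("unknown label '", label, "'", call. = FALSE)
  voxels <- as.integer(voxels)
  if (voxels < 0) stop("voxels must be nonnegative", call. = FALSE)
  a <- mask[[label]]
  for (i in seq_len(voxels)) a <- .dilate6_once(a)
  mask[[label]] <- a
  mask
}

#' Edema load of a mask volume
#'
#' The number of edema voxels relative to the number of whole-brain voxels.
#'
#' @param mask a `"mask_volume"`.
#' @return proportion in `[0, 1)`.
#' @export
edema_fraction <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  nb <- sum(mask$brain)
  if (nb == 0L) stop("empty brain mask", call. = FALSE)
  sum(mask$edema) / nb
}

#' Simulate brain, tissue, and edema masks
#'
#' Builds an ellipsoidal brain mask filling 90\% of the grid, partitions it
#' into CSF (core), WM, and GM (rind) by normalised ellipsoidal radius, and
#' grows a face-connected edema blob from a random white-matter seed until
#' its voxel count is `round(edema_fraction_target * brain voxels)` (within
#' one voxel of the target fraction).
#'
#' @param shape 3-D grid dimensions.
#' @param edema_fraction_target target edema/brain voxel ratio, in `[0, 1)`.
#' @param seed integer seed; identical seeds give identical masks.
#' @param voxdim voxel dimensions (mm).
#' @return a `"mask_volume"`; the achieved fraction is in
#'   `attr(, "true_edema_fraction")`.
#' @export
simulate_masks <- function(shape = c(32L, 32L, 16L),
                           edema_fraction_target = 0.05, seed = 1L,
                           voxdim = c(2.3, 2.3, 2.5)) {
  if (edema_fraction_target < 0 || edema_fraction_target >= 1)
    stop("edema_fraction_target must be in [0, 1)", call. = FALSE)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 3L))
  ctr <- (shape + 1) / 2
  ax <- pmax(shape / 2 * 0.9, 1)
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  r <- sqrt(((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
              ((g$z - ctr[3]) / ax[3])^2)
  r <- array(r, shape)
  brain <- r <= 1
  csf <- r <= 0.25
  wm <- r > 0.25 & r <= 0.65
  gm <- r > 0.65 & r <= 1
  edema <- array(FALSE, shape)
  n_target <- round(edema_fraction_target * sum(brain))
  if (n_target > 0) {
    edema <- with_seed(seed, .grow_blob(wm | gm, wm, n_target, shape))
  }
  m <- mask_volume(brain, gm, wm, csf, edema, voxdim)
  attr(m, "true_edema_fraction") <- sum(m$edema) / sum(m$brain)
  m
}

# grow a 6-connected blob of n voxels inside `allowed`, seeded in `prefer`
.grow_blob <- function(allowed, prefer, n, shape) {
  blob <- array(FALSE, shape)
  pool <- which(prefer)
  if (length(pool) == 0L) pool <- which(allowed)
  seed_vox <- pool[sample.int(length(pool), 1L)]
  frontier <- seed_vox
  blob[seed_vox] <- TRUE
  count <- 1L
  nxyz <- shape
  neighbours <- function(i) {
    iz <- (i - 1L) %/% (nxyz[1] * nxyz[2])
    rem <- (i - 1L) %% (nxyz[1] * nxyz[2])
    iy <- rem %/% nxyz[1]
    ix <- rem %% nxyz[1]
    cand <- rbind(c(ix - 1L, iy, iz), c(ix + 1L, iy, iz),
                  c(ix, iy - 1L, iz), c(ix, iy + 1L, iz),
                  c(ix, iy, iz - 1L), c(ix, iy, iz + 1L))
    ok <- cand[, 1] >= 0 & cand[, 1] < nxyz[1] &
      cand[, 2] >= 0 & cand[, 2] < nxyz[2] &
      cand[, 3] >= 0 & cand[, 3] < nxyz[3]
    cand <- cand[ok, , drop = FALSE]
    cand[, 1] + cand[, 2] * nxyz[1] + cand[, 3] * nxyz[1] * nxyz[2] + 1L
  }
  while (count < n && length(frontier) > 0L) {
    nb <- unique(unlist(lapply(frontier, neighbours)))
    nb <- nb[allowed[nb] & !blob[nb]]
    if (length(nb) == 0L) break
    take <- min(length(nb), n - count)
    nb <- nb[order(nb)][seq_len(take)]   # deterministic growth order
    blob[nb] <- TRUE
    count <- count + take
    frontier <- nb
  }
  blob
}
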