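#' Build the digital tMCAO phantom
#'
#' Constructs a labelled 3-D grid standing in for a rat brain with a focal
#' ischemic lesion: a mirror-symmetric brain mask, an ipsilesional lesion ROI
#' in one hemisphere, its mirrored contralesional homologue, a small cluster
#' of arterial voxels in the contralesional hemisphere, a vessel-fraction map
#' `v(x)` in `[0, 1]` (zero outside the brain) and a baseline blood-velocity
#' map (mm/s). The left-right midline lies between the two central voxel
#' columns so that reflection `x -> nx - 1 - x` (0-based) is exact.
#'
#' Label codes: 0 background, 1 brain, 2 ipsilesional lesion ROI,
#' 3 contralesional homologous ROI, 4 arterial voxels.
#'
#' @param nx,ny,nz grid size in voxels (each >= 16; `nz >= 3`). Defaults match
#'   the whole-brain ultrafast-ultrasound scan: 64 x 64 in-plane, 21
#'   elevational slices.
#' @param voxel_mm voxel size per axis (mm). Default encodes a
#'   14.1 x 14.2 mm in-plane field of view and the 0.3 mm elevational pitch.
#' @param lesion_frac target lesion size as a fraction of brain voxels,
#'   in (0, 0.5).
#' @param roi_velocity baseline blood velocity (mm/s) assigned to both ROIs.
#' @param seed integer seed; the phantom is deterministic given the seed.
#' @return An object of class `perf_phantom`.
#' @export
build_phantom <- function(nx = 64, ny = 64, nz = 21,
                          voxel_mm = c(14.1 / 64, 14.2 / 64, 0.3),
                          lesion_frac = 0.15, roi_velocity = 14.6,
                          seed = 1L) {
  if (nx < 16 || ny < 16) stopf("grid dimensions must be >= 16 in-plane")
  if (nz < 3) stopf("need at least 3 slices")
  if (nx %% 2 != 0) stopf("nx must be even so the midline falls between voxels")
  if (lesion_frac <= 0 || lesion_frac >= 0.5)
    stopf("lesion_frac must lie in (0, 0.5)")

  d <- c(nx, ny, nz)
  midline <- (nx - 1) / 2  # 0-based half-integer plane

  # Brain: stack of ellipses, slightly tapered toward the first/last slices,
  # symmetric in x by construction.
  x0 <- (seq_len(nx) - 1 - midline)            # centred, symmetric
  y0 <- (seq_len(ny) - 1 - (ny - 1) / 2)
  zmid <- (nz - 1) / 2
  brain <- array(FALSE, d)
  for (k in seq_len(nz)) {
    taper <- sqrt(pmax(0.35, 1 - 0.5 * ((k - 1 - zmid) / max(zmid, 1))^2))
    ax <- 0.44 * nx * taper
    ay <- 0.42 * ny * taper
    brain[, , k] <- outer(x0, y0, function(x, y) (x / ax)^2 + (y / ay)^2 <= 1)
  }

  # Lesion: sphere-like region in the x > midline hemisphere, sized to the
  # requested fraction of brain voxels by a distance quantile (exact count).
  n_lesion <- round(lesion_frac * sum(brain))
  cx <- midline + 0.24 * nx
  cy <- (ny - 1) / 2 - 0.05 * ny
  cz <- zmid
  coords <- which(brain, arr.ind = TRUE)
  px <- coords[, 1] - 1; py <- coords[, 2] - 1; pz <- coords[, 3] - 1
  ipsi <- px > midline + 1       # one-voxel moat so closing never crosses
  # anisotropic distance so the lesion spans several slices without touching
  # the first/last one
  dist2 <- (px - cx)^2 + (py - cy)^2 + (2.2 * (pz - cz))^2
  dist2[!ipsi] <- Inf
  if (sum(ipsi) < n_lesion) stopf("lesion_frac too large for this geometry")
  ord <- order(dist2)
  lesion_idx <- coords[ord[seq_len(n_lesion)], , drop = FALSE]
  lesion <- array(FALSE, d)
  lesion[lesion_idx] <- TRUE
  # mirroring must be well defined
  mx <- which(lesion, arr.ind = TRUE)[, 1] - 1
  if (any(mx <= midline)) stopf("lesion crosses the midline; mirroring undefined")

  contra <- mirror_mask_x(lesion, midline)
  if (any(lesion & contra)) stopf("lesion and contralesional ROI overlap")

  # Arterial voxels: 2 x 2 x 2 block in the contralesional hemisphere, fully
  # inside the brain and clear of the contra ROI; located by a deterministic
  # scan starting near the ventral midline region.
  artery <- array(FALSE, d)
  azi <- round(zmid) + 1L
  found <- FALSE
  for (ayi in c(round(0.30 * ny), round(0.40 * ny), round(0.55 * ny),
                round(0.65 * ny))) {
    for (axi in seq(round(midline) - 2L, 2L, by = -1L)) {
      blk_ok <- all(brain[axi:(axi + 1), ayi:(ayi + 1), azi:(azi + 1)]) &&
        !any(contra[axi:(axi + 1), ayi:(ayi + 1), azi:(azi + 1)])
      if (blk_ok) { found <- TRUE; break }
    }
    if (found) break
  }
  if (!found) stopf("could not place arterial voxels in the contralesional hemisphere")
  artery[axi:(axi + 1), ayi:(ayi + 1), azi:(azi + 1)] <- TRUE

  labels <- array(0L, d)
  labels[brain] <- 1L
  labels[lesion] <- 2L
  labels[contra] <- 3L
  labels[artery] <- 4L

  # Vessel fraction: smooth random field, mirrored in x so baseline statistics
  # are hemisphere-symmetric; ROIs share one mean level.
  vf <- with_seed(derive_seed(seed, stage = STAGE[["phantom"]]), {
    f <- smooth3(array(stats::runif(prod(d)), d), w = 3)
    f <- (f - min(f)) / (max(f) - min(f))
    0.25 + 0.5 * f
  })
  half <- seq_len(nx / 2)
  vf[nx + 1 - half, , ] <- vf[half, , ]     # enforce mirror symmetry
  vf[!brain] <- 0
  vf[artery] <- 1

  vel <- array(0, d)
  vel[brain] <- 10 + 10 * vf[brain]
  vel[lesion | contra] <- roi_velocity
  vel[artery] <- 30

  structure(list(
    dim = d, voxel_mm = voxel_mm, midline = midline,
    labels = labels, vessel_frac = vf, velocity = vel,
    lesion_frac = lesion_frac, seed = as.integer(seed)
  ), class = "perf_phantom")
}

#' Extract a named mask from a phantom
#'
#' @param phantom a `perf_phantom`.
#' @param which one of `"brain"`, `"lesion"`, `"contra"`, `"artery"`.
#' @return logical array of the phantom's dimensions.
#' @export
phantom_mask <- function(phantom, which = c("brain", "lesion", "contra", "artery")) {
  which <- match.arg(which)
  lab <- phantom$labels
  switch(which,
    brain  = lab >= 1L,
    lesion = lab == 2L,
    contra = lab == 3L,
    artery = lab == 4L)
}

# Reflect a logical mask across the half-integer midline plane (0-based
# x -> 2*midline - x).
mirror_mask_x <- function(mask, midline) {
  d <- dim(mask)
  out <- array(FALSE, d)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out)
  xr <- round(2 * midline - (idx[, 1] - 1)) + 1
  if (any(xr < 1 | xr > d[1])) stopf("mirrored mask falls outside the grid")
  out[cbind(xr, idx[, 2], idx[, 3])] <- TRUE
  out
}

#' Mirror an ROI across the mid-sagittal plane
#'
#' Geometric reflection producing the contralesional homologous mask. The
#' phantom is built mirror-symmetric, so reflection replaces the image-based
#' co-registration used on real animals.
#'
#' @param mask logical 3-D array.
#' @param midline 0-based midline plane index (may be half-integer).
#' @return reflected logical array with the same voxel count.
#' @export
mirror_roi <- function(mask, midline) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    x0 <- idx[, 1] - 1
    if (any(abs(x0 - midline) < 0.5))
      stopf("mask crosses the midline; mirroring is not defined")
  }
  mirror_mask_x(mask, midline)
}

#' @export
print.perf_phantom <- function(x, ...) {
  cat(sprintf("perfusim phantom: %d x %d x %d voxels (%.2f x %.2f x %.2f mm)\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3]))
  cat(sprintf("  brain %d vox | lesion %d | contra %d | artery %d\n",
              sum(x$labels >= 1), sum(x$labels == 2),
              sum(x$labels == 3), sum(x$labels == 4)))
  invisible(x)
}
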