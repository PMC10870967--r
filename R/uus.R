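#' SVD clutter filter
#'
#' Removes the `n_remove` largest singular components of the Casorati matrix
#' (pixels x frames), the standard tissue-clutter rejection for ultrafast
#' Doppler. Tissue motion is high-amplitude and low-rank, so it concentrates
#' in the leading singular subspace; blood speckle and noise dominate the
#' remainder. The default removes the first 60 singular values of a 200-frame
#' stack.
#'
#' The truncation is computed from the eigendecomposition of the frames x
#' frames Hermitian cross-product, which equals the right-singular subspace of
#' the Casorati matrix; the filtered stack is the residual after projecting
#' the frame dimension out of that subspace. The output is orthogonal (zero
#' Frobenius inner product) to the removed component.
#'
#' @param stack a `perf_framestack`.
#' @param n_remove number of leading singular components to zero;
#'   `0 <= n_remove < frames`.
#' @return a `perf_framestack` of identical shape.
#' @export
svd_clutter_filter <- function(stack, n_remove = 60L) {
  X <- stack$data
  Fn <- ncol(X)
  if (n_remove < 0 || n_remove >= Fn)
    stopf("n_remove must satisfy 0 <= n_remove < frames (%d)", Fn)
  if (n_remove == 0) return(stack)
  M <- crossprod(Conj(X), X)               # frames x frames, Hermitian
  e <- eigen(M, symmetric = TRUE)
  V <- e$vectors[, seq_len(n_remove), drop = FALSE]
  out <- stack
  out$data <- X - (X %*% V) %*% Conj(t(V))
  out
}

#' Power Doppler image from a clutter-filtered stack
#'
#' Per pixel, the mean over frames of the squared magnitude. The mean (rather
#' than the sum) makes values invariant to stack length. Power Doppler
#' intensity is proportional to moving red-blood-cell content, i.e. to local
#' blood volume. The stack is expected to be clutter-filtered already
#' (documented contract, not enforced).
#'
#' @param stack a `perf_framestack`.
#' @return list of class `perf_pd_slice` with the non-negative intensity
#'   image and acquisition metadata.
#' @export
power_doppler <- function(stack) {
  if (ncol(stack$data) < 1) stopf("empty frame stack")
  img <- matrix(rowMeans(Mod(stack$data)^2), stack$dim_px[1], stack$dim_px[2])
  structure(list(img = img, pixel_mm = stack$pixel_mm,
                 slice_pos_mm = stack$slice_pos_mm, t_min = stack$t_min),
            class = "perf_pd_slice")
}

#' Assemble power-Doppler slices into a whole-brain volume
#'
#' Slices are sorted posterior-to-anterior by elevational position; the pitch
#' must be uniform. The recorded elevational extent is `n_slices * pitch`
#' (each slice representing one pitch of tissue).
#'
#' @param slices list of `perf_pd_slice`.
#' @return list of class `perf_pd_volume`: intensity array, voxel size (mm),
#'   per-slice acquisition times, acquisition time of the volume (mean of the
#'   slice times).
#' @export
assemble_wb_volume <- function(slices) {
  if (!length(slices)) stopf("no slices supplied")
  pos <- vapply(slices, function(s) s$slice_pos_mm, numeric(1))
  ord <- order(pos)
  pos <- pos[ord]; slices <- slices[ord]
  if (anyDuplicated(pos)) stopf("slice positions must be strictly monotonic")
  pitch <- if (length(pos) > 1) diff(pos) else NULL
  if (!is.null(pitch) && diff(range(pitch)) > 1e-9 * max(abs(pitch)))
    stopf("non-uniform slice pitch")
  step <- if (is.null(pitch)) 1 else pitch[1]
  d2 <- dim(slices[[1]]$img)
  vol <- array(NA_real_, c(d2, length(slices)))
  for (k in seq_along(slices)) vol[, , k] <- slices[[k]]$img
  structure(list(
    vol = vol,
    voxel_mm = c(slices[[1]]$pixel_mm, step),
    slice_pos_mm = pos,
    slice_t_min = vapply(slices, function(s) s$t_min, numeric(1)),
    t_min = mean(vapply(slices, function(s) s$t_min, numeric(1))),
    extent_mm = c(d2 * slices[[1]]$pixel_mm, length(slices) * step)
  ), class = "perf_pd_volume")
}

#' Interpolate time-stamped volumes onto the common experimental timeline
#'
#' Voxel-wise linear interpolation between bracketing acquisitions on a
#' regular grid (one-minute resolution in the study protocol). Grid points
#' outside the acquired span, and points inside declared no-acquisition gaps,
#' are filled by linear extrapolation from the two nearest acquisitions on
#' the near side of the gap. Values are clipped at zero (negative blood
#' volume is unphysical).
#'
#' @param volumes list of numeric arrays (identical dimensions) or
#'   `perf_pd_volume` objects.
#' @param times acquisition times (minutes), strictly increasing; defaults to
#'   the volumes' own time stamps.
#' @param grid timeline grid (minutes).
#' @param gaps optional list of `c(start, end)` no-acquisition intervals.
#' @return list of class `perf_series`: `series` (grid x voxels matrix),
#'   `grid`, `dim` of the source volumes.
#' @export
build_timeline_series <- function(volumes, times = NULL, grid, gaps = NULL) {
  if (length(volumes) < 2) stopf("need at least 2 acquisitions to interpolate")
  if (is.null(times))
    times <- vapply(volumes, function(v)
      if (inherits(v, "perf_pd_volume")) v$t_min else stop("times required"),
      numeric(1))
  if (any(diff(times) <= 0)) stopf("acquisition times must be strictly increasing")
  arrs <- lapply(volumes, function(v) if (inherits(v, "perf_pd_volume")) v$vol else v)
  dims <- dim(arrs[[1]])
  A <- vapply(arrs, as.vector, numeric(prod(dims)))   # voxels x n_acq
  nA <- length(times)

  in_any_gap <- function(t) {
    if (is.null(gaps)) return(FALSE)
    any(vapply(gaps, function(g) t >= g[1] && t < g[2], logical(1)))
  }

  # two support acquisitions + linear weight per grid point
  W <- matrix(0, length(grid), nA)
  for (gi in seq_along(grid)) {
    t <- grid[gi]
    gap <- in_any_gap(t)
    if (t <= times[1]) {
      i <- 1L; j <- 2L
    } else if (t >= times[nA]) {
      i <- nA - 1L; j <- nA
    } else if (!gap) {
      i <- findInterval(t, times); j <- i + 1L
    } else {
      # inside a declared gap: extrapolate from the nearer side
      g <- gaps[[which(vapply(gaps, function(g) t >= g[1] && t < g[2], logical(1)))[1]]]
      before <- which(times < t); after <- which(times > t)
      use_left <- length(before) >= 2 &&
        (length(after) < 2 || (t - max(times[before])) <= (min(times[after]) - t))
      if (use_left) {
        i <- before[length(before) - 1L]; j <- before[length(before)]
      } else {
        i <- after[1L]; j <- after[2L]
      }
    }
    w <- (t - times[i]) / (times[j] - times[i])
    W[gi, i] <- 1 - w
    W[gi, j] <- w
  }
  S <- W %*% t(A)                       # grid x voxels
  S[S < 0] <- 0
  structure(list(series = S, grid = grid, dim = dims, times = times),
            class = "perf_series")
}

#' Voxel-wise relative CBV against the baseline median
#'
#' Divides each voxel's time course by its temporal median over the baseline
#' window, producing rCBV (1 at baseline by construction). Voxels whose
#' baseline median is at or below `eps` are masked with `NA`.
#'
#' @param series a `perf_series`.
#' @param baseline_window `c(start, end)` minutes (inclusive).
#' @param eps smallest admissible baseline median.
#' @return list of class `perf_rcbv`: normalized `series`, `grid`, `valid`
#'   voxel mask, `baseline_window`.
#' @export
relative_cbv <- function(series, baseline_window, eps = 1e-10) {
  idx <- which(series$grid >= baseline_window[1] & series$grid <= baseline_window[2])
  if (!length(idx)) stopf("baseline window contains no grid point")
  base <- apply(series$series[idx, , drop = FALSE], 2, stats::median)
  valid <- is.finite(base) & base > eps
  R <- sweep(series$series, 2, ifelse(valid, base, NA_real_), "/")
  R[, !valid] <- NA_real_
  structure(list(series = R, grid = series$grid, dim = series$dim,
                 valid = valid, baseline_window = baseline_window),
            class = "perf_rcbv")
}

#' Coefficient-of-variation vessel mask
#'
#' Voxels belong to the cerebral vasculature only if their signal varies
#' sufficiently over the whole experiment: a voxel is retained iff its
#' population coefficient of variation (sd/mean, n-denominator) over the full
#' series exceeds the threshold (0.15 in the study protocol). Voxels with
#' non-positive mean are excluded.
#'
#' @param series a `perf_series` (raw, pre-normalization).
#' @param threshold CoV cut-off.
#' @return logical voxel vector.
#' @export
cov_mask <- function(series, threshold = 0.15) {
  S <- series$series
  m <- colMeans(S)
  s <- sqrt(colMeans(S^2) - m^2)
  ok <- m > 0 & (s / m) > threshold
  ok[!is.finite(ok)] <- FALSE
  ok
}

#' Reject flash-artifact values from an ROI sample
#'
#' Transient high-intensity flash artifacts corrupt Doppler averages. Values
#' strictly exceeding `factor` times the ROI mean at that time point are
#' rejected; the mean is computed once, before any removal.
#'
#' @param values numeric vector of ROI voxel values at one time point.
#' @param factor rejection multiple of the mean (3 in the study protocol).
#' @return the retained values.
#' @export
flash_reject <- function(values, factor = 3) {
  if (!length(values)) stopf("flash rejection needs at least one value")
  values[values <= factor * mean(values)]
}
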