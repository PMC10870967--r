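#' Fit a quantitative T2 map by nonlinear monoexponential regression
#'
#' Per voxel, least-squares fit of `S(TE) = S0 * exp(-TE/T2)` by a
#' Levenberg-Marquardt iteration, initialized from the log-linear closed
#' form. The solver is vectorised over voxels (per-voxel damping, shared
#' matrix operations); voxels that fail to converge or have non-positive
#' signal at every echo are flagged and carry `NA`.
#'
#' @param series a `perf_multiecho`, or a numeric matrix (echoes x voxels)
#'   with `te_ms` supplied.
#' @param te_ms echo times (ms) when `series` is a bare matrix.
#' @param mask optional logical array restricting the fit (default: voxels
#'   with all-positive signal).
#' @param max_iter,tol iteration cap and relative-change tolerance.
#' @return list of class `perf_t2map`: `t2` (ms), `s0`, `rss`, `converged`
#'   arrays (or vectors when the input was a matrix).
#' @export
fit_t2_map <- function(series, te_ms = NULL, mask = NULL, max_iter = 30L,
                       tol = 1e-10) {
  if (inherits(series, "perf_multiecho")) {
    te <- series$te_ms
    d <- dim(series$echoes)[1:3]
    S <- t(matrix(series$echoes, prod(d), length(te)))  # echoes x voxels
  } else {
    te <- te_ms
    if (is.null(te)) stopf("te_ms required for matrix input")
    S <- series
    d <- NULL
  }
  if (length(te) < 2) stopf("need at least 2 echoes")
  nv <- ncol(S)
  fit_ok <- colSums(S > 0) == length(te)
  if (!is.null(mask)) fit_ok <- fit_ok & as.vector(mask)

  t2 <- rep(NA_real_, nv); s0 <- rep(NA_real_, nv)
  rss <- rep(NA_real_, nv); conv <- rep(FALSE, nv)
  idx <- which(fit_ok)
  if (length(idx)) {
    Sf <- S[, idx, drop = FALSE]
    # log-linear initialization: ln S = ln S0 - TE * R
    L <- log(Sf)
    mt <- mean(te); ml <- colMeans(L)
    R <- -(colSums((te - mt) * L) - 0) / sum((te - mt)^2)
    R <- pmax(R, 1e-6)
    A <- exp(ml + R * mt)
    lam <- rep(1e-3, length(idx))
    model <- function(A, R) sweep(exp(-outer(te, R)), 2, A, "*")
    sse <- colSums((Sf - model(A, R))^2)
    for (it in seq_len(max_iter)) {
      E <- exp(-outer(te, R))                 # echoes x voxels
      res <- Sf - sweep(E, 2, A, "*")
      # J columns per voxel: d/dS0 = E ; d/dR = -S0 * TE * E
      ATE <- sweep(te * E, 2, A, "*")         # S0 * TE * E
      j11 <- colSums(E * E)
      j12 <- -colSums(E * ATE)
      j22 <- colSums(ATE^2)
      g1 <- colSums(E * res)
      g2 <- -colSums(ATE * res)
      a11 <- j11 * (1 + lam); a22 <- j22 * (1 + lam)
      det <- a11 * a22 - j12^2
      dA <- (a22 * g1 - j12 * g2) / det
      dR <- (a11 * g2 - j12 * g1) / det
      A2 <- A + dA; R2 <- pmax(R + dR, 1e-8)
      sse2 <- colSums((Sf - model(A2, R2))^2)
      better <- is.finite(sse2) & sse2 <= sse
      A[better] <- A2[better]; R[better] <- R2[better]
      lam <- ifelse(better, pmax(lam * 0.3, 1e-12), lam * 10)
      moved <- better & (abs(dA) > tol * pmax(abs(A), 1) |
                         abs(dR) > tol * pmax(abs(R), 1e-8))
      sse[better] <- sse2[better]
      if (!any(moved) && it > 2) break
    }
    t2[idx] <- 1 / R
    s0[idx] <- A
    rss[idx] <- sse
    conv[idx] <- is.finite(R) & R > 1e-8
  }
  if (!is.null(d)) {
    t2 <- array(t2, d); s0 <- array(s0, d)
    rss <- array(rss, d); conv <- array(conv, d)
  }
  structure(list(t2 = t2, s0 = s0, rss = rss, converged = conv, te_ms = te),
            class = "perf_t2map")
}

#' Segment the edematous lesion from a T2 map
#'
#' Voxels whose T2 exceeds the contralesional reference mean by more than
#' `k` reference standard deviations are candidate edema; the largest
#' 6-connected component is kept and morphologically closed. An empty result
#' is allowed (no lesion).
#'
#' @param t2map a `perf_t2map` with array maps.
#' @param contra_ref logical array defining the contralesional reference
#'   tissue.
#' @param k threshold in reference standard deviations.
#' @param min_size components smaller than this are discarded.
#' @return logical lesion mask array.
#' @export
segment_lesion <- function(t2map, contra_ref, k = 2, min_size = 10L) {
  if (is.null(contra_ref) || !any(contra_ref))
    stopf("contralesional reference region undefined")
  vals <- t2map$t2[contra_ref]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stopf("no finite T2 in the reference region")
  thr <- mean(vals) + k * stats::sd(vals)
  cand <- !is.na(t2map$t2) & t2map$t2 > thr
  if (!any(cand)) return(cand)
  comp <- largest_component3(cand)
  if (sum(comp) < min_size) return(array(FALSE, dim(cand)))
  close3(comp)
}

#' Convert a DSC signal series to a concentration series
#'
#' Per voxel, `S0` is the mean over the pre-bolus baseline window and
#' `C(t) = -ln(S(t)/S0) / TE` (proportional to the R2* change and so to
#' contrast-agent concentration). Non-positive samples are clipped to the
#' smallest positive observed signal before the log; the clip count is
#' reported.
#'
#' @param dsc a `perf_dsc` (or a list with `signal`, `tr_s`, `te_s`,
#'   `injection_index`).
#' @param baseline_window `c(first, last)` image indices (1-based, inclusive);
#'   must end before the injection index.
#' @return list of class `perf_conc`: `conc` (images x voxels, 1/s), timing
#'   constants, `n_clipped`.
#' @export
signal_to_concentration <- function(dsc, baseline_window = c(50, 170)) {
  if (baseline_window[2] >= dsc$injection_index)
    stopf("baseline window must end before the injection index (%d)",
          dsc$injection_index)
  S <- dsc$signal
  bw <- baseline_window[1]:baseline_window[2]
  s0 <- colMeans(S[bw, , drop = FALSE])
  n_clipped <- sum(S <= 0)
  if (n_clipped > 0) {
    floorv <- min(S[S > 0])
    S[S <= 0] <- floorv
    warning(sprintf("%d non-positive signal samples clipped", n_clipped))
  }
  conc <- -log(sweep(S, 2, s0, "/")) / dsc$te_s
  structure(list(conc = conc, tr_s = dsc$tr_s, te_s = dsc$te_s,
                 injection_index = dsc$injection_index,
                 baseline_window = baseline_window,
                 voxels = dsc$voxels %||% seq_len(ncol(S)),
                 dim = dsc$dim, n_clipped = n_clipped),
            class = "perf_conc")
}

#' CBV-weighted map by truncated numeric integration
#'
#' Per voxel, the trapezoidal integral of the concentration curve times TR
#' from the first image through the truncation index (the 400th image in the
#' study protocol, bounding recirculation); negative results are clipped at
#' zero. Values are an index in arbitrary units — the analysis uses
#' ipsi/contralesional ratios.
#'
#' @param conc a `perf_conc`.
#' @param truncation 1-based inclusive upper image index.
#' @return numeric vector of CBV-weighted values per voxel.
#' @export
compute_cbv_map <- function(conc, truncation = 400L) {
  n <- nrow(conc$conc)
  if (truncation > n) stopf("truncation index (%d) exceeds image count (%d)",
                            truncation, n)
  C <- conc$conc[seq_len(truncation), , drop = FALSE]
  cbv <- (colSums(C) - (C[1, ] + C[truncation, ]) / 2) * conc$tr_s
  unname(pmax(cbv, 0))
}

#' Select a contralesional arterial reference curve
#'
#' Ranks contralesional voxels by peak concentration (descending), breaking
#' ties by bolus arrival time (ascending), and averages the top `n` curves.
#' Arrival time and peak width QC metrics are returned so the selection can
#' be audited; on the phantom the selected voxels should be the labelled
#' arterial ones.
#'
#' @param conc a `perf_conc`.
#' @param contra_mask logical vector over the concentration voxels marking
#'   the contralesional search region.
#' @param n number of voxels averaged.
#' @return list: `curve`, `voxels` (indices into the conc columns), `qc`
#'   data frame (peak, arrival index, fwhm images).
#' @export
select_aif <- function(conc, contra_mask, n = 5L) {
  if (!any(contra_mask)) stopf("contralesional mask is empty")
  cols <- which(contra_mask)
  Cm <- conc$conc[, cols, drop = FALSE]
  pk <- apply(Cm, 2, max)
  noise_floor <- 3 * stats::median(apply(
    conc$conc[seq_len(conc$injection_index), , drop = FALSE], 2, stats::sd))
  if (max(pk) <= noise_floor)
    stopf("no arterial candidate above the noise floor")
  arrival <- vapply(seq_along(cols), function(j) {
    which(Cm[, j] > 0.1 * pk[j])[1]
  }, numeric(1))
  ord <- order(-pk, arrival)
  sel <- ord[seq_len(min(n, length(ord)))]
  curve <- rowMeans(Cm[, sel, drop = FALSE])
  fwhm <- vapply(sel, function(j) sum(Cm[, j] > pk[j] / 2), numeric(1))
  list(curve = curve, voxels = cols[sel],
       qc = data.frame(peak = pk[sel], arrival_index = arrival[sel],
                       fwhm_images = fwhm))
}

#' CBF-weighted map by block-circulant SVD deconvolution
#'
#' Tissue curves are deconvolved against the arterial reference with the
#' circular (block-circulant) formulation: both curves are zero-padded to
#' twice their length, an `L x L` circulant matrix is built from the padded
#' AIF scaled by TR, and its SVD pseudo-inverse — keeping singular values at
#' or above `lambda` times the largest — is applied to the padded tissue
#' curves. The deconvolved curve is the flow-scaled residue function
#' `k(t) = CBF * R(t)`; CBF is its maximum, clipped at zero.
#'
#' @param conc a `perf_conc`.
#' @param aif arterial reference curve (same length as the series) or the
#'   list returned by [select_aif()].
#' @param lambda singular-value threshold as a fraction of the largest.
#' @return list of class `perf_cbf`: `cbf` per voxel, `tmax` (index of the
#'   residue peak), `lambda`, `singular_values`.
#' @export
compute_cbf_map <- function(conc, aif, lambda = 0.10) {
  if (is.list(aif)) aif <- aif$curve
  N <- nrow(conc$conc)
  if (length(aif) != N) stopf("AIF and tissue curves must have equal length")
  if (all(aif == 0)) stopf("all-zero AIF")
  L <- 2L * N
  a <- c(aif, numeric(L - N)) * conc$tr_s
  # circulant: A[i, j] = a[(i - j) mod L + 1]
  A <- matrix(a[(outer(seq_len(L), seq_len(L), `-`) %% L) + 1L], L, L)
  sv <- svd(A)
  keep <- sv$d >= lambda * sv$d[1]
  dinv <- ifelse(keep, 1 / sv$d, 0)
  Ginv <- sv$v %*% (dinv * t(sv$u))
  Cp <- rbind(conc$conc, matrix(0, L - N, ncol(conc$conc)))
  K <- Ginv %*% Cp
  cbf <- unname(pmax(apply(K, 2, max), 0))
  tmax <- unname(apply(K, 2, which.max))
  structure(list(cbf = cbf, tmax = tmax, lambda = lambda,
                 singular_values = sv$d),
            class = "perf_cbf")
}
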