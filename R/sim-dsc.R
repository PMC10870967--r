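#' Gamma-variate bolus curve
#'
#' `g(t) = A * (t - t0)^alpha * exp(-(t - t0) / beta)` for `t > t0`, zero
#' before arrival. Its time integral has the closed form
#' `A * beta^(alpha+1) * Gamma(alpha+1)`.
#'
#' @param t time (s), vector.
#' @param A amplitude.
#' @param t0 arrival time (s).
#' @param alpha shape parameter (> 0).
#' @param beta scale parameter (s, > 0).
#' @return concentration values.
#' @export
gamma_variate <- function(t, A, t0, alpha, beta) {
  stopifnot(A > 0, alpha > 0, beta > 0)
  out <- numeric(length(t))
  up <- t > t0
  out[up] <- A * (t[up] - t0)^alpha * exp(-(t[up] - t0) / beta)
  out
}

#' Parameters for DSC-MRI bolus simulation
#'
#' Defaults reproduce the dynamic gradient-echo protocol: TR 164 ms, TE
#' 13 ms, 500 dynamic images with the contrast bolus injected at the 180th
#' image. The arterial input is a gamma-variate; tissue concentration follows
#' the indicator-dilution forward model
#' `C(t) = CBF * (AIF convolved with exp(-t/MTT))(t) * TR`, and signal
#' `S(t) = S0 * exp(-k * C(t) * TE) + noise`.
#'
#' @param tr_s repetition time (s).
#' @param te_s echo time (s).
#' @param n_images dynamic images.
#' @param injection_index 1-based image index of the injection.
#' @param aif_amp,aif_alpha,aif_beta gamma-variate amplitude, shape, scale.
#' @param arrival_delay_s bolus arrival delay after injection (s).
#' @param k relaxivity constant linking concentration to R2* change.
#' @param s0 pre-bolus signal level.
#' @param noise_sd additive signal noise standard deviation.
#' @param cbf0 baseline tissue flow index; baseline CBV is `cbf0 * mtt0`.
#' @param mtt0 baseline mean transit time (s).
#' @param inj_sdlog lognormal sd of the per-experiment injection-efficiency
#'   factor (scales artery and tissue curves alike, mimicking variable
#'   injection speed).
#' @return list of class `dsc_params`.
#' @export
dsc_params <- function(tr_s = 0.164, te_s = 0.013, n_images = 500L,
                       injection_index = 180L, aif_amp = 87, aif_alpha = 3,
                       aif_beta = 0.8, arrival_delay_s = 2, k = 1,
                       s0 = 1000, noise_sd = 4, cbf0 = 0.2, mtt0 = 1.2,
                       inj_sdlog = 0.15) {
  stopifnot(injection_index < n_images, aif_alpha > 0, aif_beta > 0,
            aif_amp > 0, tr_s > 0, te_s > 0, cbf0 > 0, mtt0 > 0)
  structure(as.list(environment()), class = "dsc_params")
}

#' Simulate a DSC-MRI bolus-passage series
#'
#' Evaluates the forward model on the requested voxels of the phantom at the
#' hemodynamic state of time `t_min`: true `CBV = cbv0 * factor * w(x)` per
#' voxel (with `w(x)` the normalized vessel fraction), true
#' `MTT = mtt0 * cbv_factor / cbf_factor`, `CBF = CBV / MTT`, and labelled
#' arterial voxels carrying the arterial input curve itself. Ground-truth
#' CBV/CBF/MTT maps accompany the signal.
#'
#' @param phantom a `perf_phantom`.
#' @param timeline a `perf_timeline`.
#' @param t_min experiment time (minutes) of this bolus injection.
#' @param params a `dsc_params`.
#' @param seed integer seed.
#' @param voxels integer vector of linear voxel indices to simulate; default
#'   lesion + contralesional ROI + arterial voxels + a subsample of remaining
#'   brain.
#' @param ipsi_scale subject-level scaling of the ipsilesional deviation from
#'   baseline (`factor' = 1 + (factor - 1) * ipsi_scale`).
#' @return list of class `perf_dsc`: `signal` (images x voxels), `voxels`,
#'   `dim`, acquisition constants, and `truth` (per-voxel cbv, cbf, mtt,
#'   labels, plus the noiseless concentration curves and the true AIF).
#' @export
simulate_dsc_series <- function(phantom, timeline, t_min, params = dsc_params(),
                                seed = 1L, voxels = NULL, ipsi_scale = 1) {
  f <- epoch_factors(timeline, t_min)
  lab <- phantom$labels
  if (is.null(voxels)) {
    core <- which(lab == 2L | lab == 3L | lab == 4L)
    rest <- which(lab == 1L)
    take <- with_seed(derive_seed(seed, stage = STAGE[["dsc"]], counter = 99L),
                      sample(rest, min(length(rest), 1500L)))
    voxels <- sort(c(core, take))
  }
  labv <- lab[voxels]
  if (any(labv == 0L)) stopf("requested voxels outside the brain")

  scl <- function(x) pmax(0, 1 + (x - 1) * ipsi_scale)
  cbv_fac <- ifelse(labv == 2L, scl(f$dsc_cbv_ipsi), f$dsc_cbv_contra)
  cbf_fac <- ifelse(labv == 2L, scl(f$dsc_cbf_ipsi), f$dsc_cbf_contra)
  if (any(cbf_fac <= 0 & cbv_fac > 0))
    stopf("MTT undefined: CBV > 0 with CBF <= 0")

  w <- phantom$vessel_frac[voxels]
  w <- w / mean(w[labv != 4L])
  cbv <- params$cbf0 * params$mtt0 * w * cbv_fac
  mtt <- params$mtt0 * cbv_fac / cbf_fac
  cbf <- cbv / mtt
  # arterial voxels: pure blood reference
  is_art <- labv == 4L

  n <- params$n_images
  tt <- (seq_len(n) - 1) * params$tr_s
  t0 <- (params$injection_index - 1) * params$tr_s + params$arrival_delay_s

  with_seed(derive_seed(seed, stage = STAGE[["dsc"]]), {
    inj <- stats::rlnorm(1, -params$inj_sdlog^2 / 2, params$inj_sdlog)
    aif <- gamma_variate(tt, params$aif_amp * inj, t0, params$aif_alpha,
                         params$aif_beta)
    # one convolution per distinct MTT (regions are piecewise uniform)
    conc <- matrix(0, n, length(voxels))
    for (m in unique(mtt)) {
      res <- exp(-tt / m)
      shape <- conv_causal(aif, res) * params$tr_s
      sel <- mtt == m & !is_art
      conc[, sel] <- outer(shape, cbf[sel])
    }
    conc[, is_art] <- aif
    sig <- params$s0 * exp(-params$k * conc * params$te_s)
    if (params$noise_sd > 0)
      sig <- sig + stats::rnorm(length(sig), 0, params$noise_sd)

    structure(list(signal = sig, voxels = voxels, dim = phantom$dim,
                   tr_s = params$tr_s, te_s = params$te_s,
                   injection_index = params$injection_index,
                   t_min = t_min,
                   truth = list(cbv = cbv, cbf = cbf, mtt = mtt,
                                labels = labv, conc = conc, aif = aif,
                                factors = f, injection_factor = inj)),
              class = "perf_dsc")
  })
}

# linear (causal) convolution truncated to the length of x
conv_causal <- function(x, y) {
  n <- length(x)
  L <- 2 * n
  X <- stats::fft(c(x, numeric(L - n)))
  Y <- stats::fft(c(y, numeric(L - n)))
  Re(stats::fft(X * Y, inverse = TRUE))[seq_len(n)] / L
}

#' Parameters for multi-echo T2-weighted simulation
#'
#' Defaults follow the spin-echo EPI protocol: TR 3000 ms, echo times 30, 50,
#' 80 and 190 ms. Lesion voxels carry elevated T2 (vasogenic edema), the
#' contralesional tissue the normal value.
#'
#' @param te_ms echo times (ms), strictly increasing.
#' @param tr_ms repetition time (ms).
#' @param t2_normal,t2_lesion tissue T2 values (ms).
#' @param t2_spread voxel-wise smooth T2 variation (ms, sd-like amplitude).
#' @param s0 proton-density signal level.
#' @param noise_sd additive noise standard deviation.
#' @return list of class `t2_params`.
#' @export
t2_params <- function(te_ms = c(30, 50, 80, 190), tr_ms = 3000,
                      t2_normal = 50, t2_lesion = 68, t2_spread = 2,
                      s0 = 1000, noise_sd = 10) {
  if (length(te_ms) < 2) stopf("need at least 2 echo times")
  if (any(diff(te_ms) <= 0)) stopf("echo times must be strictly increasing (no duplicates)")
  structure(as.list(environment()), class = "t2_params")
}

#' Simulate a multi-echo T2-weighted acquisition
#'
#' Monoexponential decay `S(TE) = S0 * exp(-TE/T2)` per voxel with additive
#' Gaussian noise; the lesion carries elevated true T2 relative to the
#' contralesional tissue (edema). The true T2 map is returned as ground
#' truth.
#'
#' @param phantom a `perf_phantom`.
#' @param params a `t2_params`.
#' @param seed integer seed.
#' @return list of class `perf_multiecho`: `echoes` (4-D array x,y,z,echo),
#'   `te_ms`, `tr_ms`, `truth` (true T2 array, ms; `NA` outside the brain).
#' @export
simulate_multiecho_t2 <- function(phantom, params = t2_params(), seed = 1L) {
  d <- phantom$dim
  brain <- phantom$labels >= 1L
  lesion <- phantom$labels == 2L
  with_seed(derive_seed(seed, stage = STAGE[["t2"]]), {
    t2 <- array(NA_real_, d)
    varfield <- smooth3(array(stats::rnorm(prod(d)), d), w = 2)
    varfield <- varfield / stats::sd(varfield)
    t2[brain] <- params$t2_normal + params$t2_spread * varfield[brain]
    t2[lesion] <- params$t2_lesion + params$t2_spread * varfield[lesion]
    ne <- length(params$te_ms)
    echoes <- array(NA_real_, c(d, ne))
    for (e in seq_len(ne)) {
      s <- array(0, d)
      s[brain] <- params$s0 * exp(-params$te_ms[e] / t2[brain])
      if (params$noise_sd > 0) s <- s + array(stats::rnorm(prod(d), 0, params$noise_sd), d)
      echoes[, , , e] <- s
    }
    structure(list(echoes = echoes, te_ms = params$te_ms, tr_ms = params$tr_ms,
                   truth = list(t2 = t2)),
              class = "perf_multiecho")
  })
}

#' Simulate the single-slice 0.5 Hz Doppler series at recanalization
#'
#' The filament is retracted under continuous single-slice imaging; the
#' ipsilesional rCBV follows the scenario's recanalization transient (an
#' overshoot intercept decaying linearly), the contralesional side stays at
#' baseline. The series is generated at the relative-CBV level (per-pixel
#' multiplicative noise), which is the quantity the pixel-wise intercept fit
#' consumes.
#'
#' @param phantom a `perf_phantom`.
#' @param timeline a `perf_timeline` whose transient is defined.
#' @param slice imaged slice (1-based); defaults to the central slice.
#' @param rate_hz sampling rate (Hz).
#' @param duration_s acquisition length after retraction (s).
#' @param noise_sd multiplicative noise sd.
#' @param seed integer seed.
#' @return list: `rcbv` (samples x pixels), `times_s` (0 at retraction),
#'   `dim_px`, `lesion_px`, `contra_px`, `truth` (intercept/slope per region).
#' @export
simulate_ss_doppler <- function(phantom, timeline, slice = NULL, rate_hz = 0.5,
                                duration_s = 300, noise_sd = 0.08, seed = 1L) {
  tr <- timeline$transient
  if (is.null(tr)) stopf("timeline has no recanalization transient")
  z <- slice %||% ((phantom$dim[3] + 1) %/% 2)
  lab <- phantom$labels[, , z]
  times <- seq(0, duration_s, by = 1 / rate_hz)
  slope_s <- tr$slope_per_min / 60
  ipsi_line <- tr$intercept + slope_s * times
  P <- length(lab)
  base <- matrix(1, length(times), P)
  lesion <- as.vector(lab == 2L)
  base[, lesion] <- matrix(ipsi_line, length(times), sum(lesion))
  base[, as.vector(lab == 0L)] <- 0
  with_seed(derive_seed(seed, stage = STAGE[["ss"]]), {
    noisy <- base * matrix(stats::rlnorm(length(base), -noise_sd^2 / 2, noise_sd),
                           nrow(base), ncol(base))
    list(rcbv = noisy, times_s = times, dim_px = dim(lab),
         lesion_px = lab == 2L, contra_px = lab == 3L,
         truth = list(intercept_ipsi = tr$intercept,
                      slope_ipsi_per_s = slope_s,
                      intercept_contra = 1, slope_contra_per_s = 0))
  })
}
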