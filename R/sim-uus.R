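#' Acquisition parameters for ultrafast-ultrasound simulation
#'
#' Defaults reproduce the whole-brain scan protocol: 200 compounded frames per
#' slice at a 500 Hz pulse repetition frequency, 21 elevational slices at a
#' 0.3 mm pitch (6.3 mm elevational extent). The signal model is beamformed
#' complex IQ per pixel: a low-rank, high-amplitude tissue clutter component;
#' a blood component whose power is proportional to the local vessel fraction
#' times the epoch CBV factor, modelled in the many-scatterer (Gaussian
#' speckle) limit as a complex first-order autoregressive process with a
#' Doppler rotation proportional to local velocity and a transit-time
#' decorrelation bandwidth — blood speckle in microvasculature decorrelates
#' within milliseconds, which is what makes the frame-averaged power estimate
#' well conditioned; and circular complex white noise. Slow vasomotion is
#' modelled as a per-acquisition lognormal modulation of blood power, and
#' rare transient flash artifacts as brief high-amplitude broadband bursts.
#'
#' @param n_frames frames per stack.
#' @param prf pulse repetition frequency (Hz).
#' @param n_slices elevational slices per whole-brain volume.
#' @param slice_step_mm elevational pitch (mm).
#' @param clutter_amp,clutter_rank tissue clutter amplitude and rank.
#' @param blood_amp blood scattering amplitude scale; expected blood power per
#'   pixel is `blood_amp^2 * v(x) * cbv_factor`.
#' @param doppler_hz_per_mms Doppler shift per unit velocity (Hz/(mm/s)).
#' @param doppler_bw_hz blood speckle decorrelation bandwidth (Hz); the AR(1)
#'   pole is `exp(-2*pi*bw/prf)`, so the default decorrelates within a couple
#'   of frames (transit-time broadening).
#' @param noise_sd circular complex noise standard deviation.
#' @param vaso_sdlog lognormal sd of slow per-voxel blood-volume fluctuation
#'   between acquisitions (vasomotion); gives contralesional voxels the
#'   temporal variability real vasculature shows.
#' @param flash_prob per-pixel probability of a flash artifact per acquisition.
#' @param flash_amp flash amplitude as a multiple of `blood_amp`.
#' @return list of class `uus_params`.
#' @export
uus_params <- function(n_frames = 200L, prf = 500, n_slices = 21L,
                       slice_step_mm = 0.3, clutter_amp = 100, clutter_rank = 5L,
                       blood_amp = 5,
                       doppler_hz_per_mms = 10, doppler_bw_hz = 120,
                       noise_sd = 0.3, vaso_sdlog = 0.18,
                       flash_prob = 0.002, flash_amp = 8) {
  stopifnot(n_frames >= 1, clutter_rank < n_frames, clutter_amp >= 0,
            blood_amp >= 0, noise_sd >= 0, prf > 0)
  structure(as.list(environment()), class = "uus_params")
}

# CBV factor map at time t: lesion ROI takes the ipsilesional factor,
# all other brain voxels the contralesional factor.
cbv_factor_map <- function(phantom, timeline, t_min, what = c("cbv", "dsc_cbv", "dsc_cbf")) {
  what <- match.arg(what)
  f <- epoch_factors(timeline, t_min)
  ipsi <- switch(what, cbv = f$cbv_ipsi, dsc_cbv = f$dsc_cbv_ipsi,
                 dsc_cbf = f$dsc_cbf_ipsi)
  contra <- switch(what, cbv = f$cbv_contra, dsc_cbv = f$dsc_cbv_contra,
                   dsc_cbf = f$dsc_cbf_contra)
  m <- array(contra, phantom$dim)
  m[phantom$labels == 2L] <- ipsi
  m[phantom$labels == 0L] <- 0
  m
}

#' Simulate one whole-brain ultrafast-ultrasound acquisition
#'
#' Generates the per-slice complex frame stacks for a whole-brain sweep at
#' time `t_min` under the scenario's hemodynamic state, together with the
#' ground truth needed by downstream recovery tests.
#'
#' @param phantom a `perf_phantom`.
#' @param timeline a `perf_timeline`.
#' @param t_min acquisition time (minutes); must lie inside the timeline.
#' @param params a `uus_params` list.
#' @param seed integer seed; output is deterministic given the seed.
#' @param ipsi_scale subject-level scaling of the ipsilesional deviation from
#'   baseline, `factor' = 1 + (factor - 1) * ipsi_scale` (between-animal
#'   variability of the insult; identity scenarios are unaffected).
#' @return list with `stacks` (one `perf_framestack` per slice, Casorati
#'   orientation pixels x frames), `truth` (expected blood power per voxel,
#'   nominal `v(x) * factor` map, epoch factors) and `t_min`.
#' @export
simulate_uus_acquisition <- function(phantom, timeline, t_min,
                                     params = uus_params(), seed = 1L,
                                     ipsi_scale = 1) {
  f <- epoch_factors(timeline, t_min)  # errors if t_min outside timeline
  d <- phantom$dim
  if (params$n_slices != d[3])
    stopf("params$n_slices (%d) must match the phantom grid (%d slices)",
          params$n_slices, d[3])
  fac_map <- cbv_factor_map(phantom, timeline, t_min, "cbv")
  if (ipsi_scale != 1) {
    les <- phantom$labels == 2L
    fac_map[les] <- pmax(0, 1 + (fac_map[les] - 1) * ipsi_scale)
  }
  P <- d[1] * d[2]; Fn <- params$n_frames

  stacks <- vector("list", d[3])
  b2_truth <- array(0, d)
  with_seed(seed, {
    for (z in seq_len(d[3])) {
      v <- as.vector(phantom$vessel_frac[, , z])
      fac <- as.vector(fac_map[, , z])
      vel <- as.vector(phantom$velocity[, , z])
      X <- matrix(0i, P, Fn)

      # tissue clutter: rank <= clutter_rank, smooth in space, slow in time
      r <- params$clutter_rank
      if (r > 0 && params$clutter_amp > 0) {
        U <- matrix(complex(real = stats::rnorm(P * r),
                            imaginary = stats::rnorm(P * r)), P, r)
        U <- matrix(complex(
          real = as.vector(smooth3(array(Re(U), c(d[1], d[2], r)), 2)),
          imaginary = as.vector(smooth3(array(Im(U), c(d[1], d[2], r)), 2))), P, r)
        U <- sweep(U, 2, sqrt(colMeans(Mod(U)^2)), "/")
        fr <- stats::runif(r, 0.2, 5)         # Hz, slow tissue motion
        ph <- stats::runif(r, 0, 2 * pi)
        n01 <- seq_len(Fn) - 1
        C <- exp(1i * (outer(2 * pi * fr / params$prf, n01) + ph))
        X <- X + params$clutter_amp * (U %*% C)
      }

      # blood: Gaussian speckle (many-scatterer limit) — complex AR(1) with
      # Doppler rotation and transit-time decorrelation; unit power
      pb <- which(v > 0)
      if (length(pb)) {
        np <- length(pb)
        vaso <- stats::rlnorm(np, 0, params$vaso_sdlog)
        b2 <- params$blood_amp^2 * v[pb] * fac[pb] * vaso
        b <- sqrt(b2)
        fd <- pmin(params$doppler_hz_per_mms * vel[pb], 0.45 * params$prf)
        rho <- exp(-2 * pi * params$doppler_bw_hz / params$prf)
        pole <- rho * exp(1i * 2 * pi * fd / params$prf)
        innov_sd <- sqrt((1 - rho^2) / 2)
        g <- complex(real = stats::rnorm(np), imaginary = stats::rnorm(np)) / sqrt(2)
        blood <- matrix(0i, np, Fn)
        for (n in seq_len(Fn)) {
          blood[, n] <- g
          g <- g * pole + complex(real = stats::rnorm(np, 0, innov_sd),
                                  imaginary = stats::rnorm(np, 0, innov_sd))
        }
        X[pb, ] <- X[pb, ] + b * blood
        tmp <- numeric(P); tmp[pb] <- b2
        b2_truth[, , z] <- tmp
      }

      # flash artifacts: brief broadband high-amplitude bursts
      if (params$flash_prob > 0) {
        fl <- which(stats::runif(P) < params$flash_prob)
        for (p in fl) {
          len <- max(4L, round(Fn / 10))
          st <- sample.int(Fn - len + 1L, 1L)
          idx <- st:(st + len - 1L)
          amp <- params$flash_amp * params$blood_amp
          X[p, idx] <- X[p, idx] + amp * complex(
            real = stats::rnorm(len), imaginary = stats::rnorm(len)) / sqrt(2)
        }
      }

      if (params$noise_sd > 0)
        X <- X + complex(real = stats::rnorm(P * Fn),
                         imaginary = stats::rnorm(P * Fn)) * (params$noise_sd / sqrt(2))

      stacks[[z]] <- framestack(X, dim_px = d[1:2], frame_rate = params$prf,
                                slice_pos_mm = (z - 1) * params$slice_step_mm,
                                t_min = t_min, pixel_mm = phantom$voxel_mm[1:2])
    }
  })

  list(stacks = stacks,
       truth = list(blood_power = b2_truth,
                    nominal = phantom$vessel_frac * fac_map,
                    factors = f),
       t_min = t_min,
       elevational_extent_mm = params$n_slices * params$slice_step_mm)
}

#' Construct a frame-stack container
#'
#' @param data complex matrix in Casorati orientation (pixels x frames).
#' @param dim_px in-plane image dimensions `c(nx, ny)`.
#' @param frame_rate frames per second (Hz).
#' @param slice_pos_mm elevational slice position (mm).
#' @param t_min acquisition time on the experimental timeline (minutes).
#' @param pixel_mm in-plane pixel size (mm).
#' @return object of class `perf_framestack`.
#' @export
framestack <- function(data, dim_px, frame_rate, slice_pos_mm = 0,
                       t_min = 0, pixel_mm = c(1, 1)) {
  if (!is.matrix(data)) stopf("frame-stack data must be a pixels x frames matrix")
  if (ncol(data) < 1) stopf("a frame stack needs at least one frame")
  if (nrow(data) != prod(dim_px)) stopf("data rows must equal prod(dim_px)")
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stopf("frame stack contains non-finite samples")
  structure(list(data = data, dim_px = as.integer(dim_px),
                 frame_rate = frame_rate, slice_pos_mm = slice_pos_mm,
                 t_min = t_min, pixel_mm = pixel_mm),
            class = "perf_framestack")
}

#' @export
print.perf_framestack <- function(x, ...) {
  cat(sprintf("perfusim frame stack: %d x %d px, %d frames @ %g Hz, slice %.2f mm, t = %g min\n",
              x$dim_px[1], x$dim_px[2], ncol(x$data), x$frame_rate,
              x$slice_pos_mm, x$t_min))
  invisible(x)
}
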