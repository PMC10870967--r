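#' Parameters for microbubble (ULM) sequence simulation
#'
#' Microbubbles are sparse point scatterers imaged as isotropic Gaussian
#' blobs on a beamformed grid twice as fine as the Doppler grid (0.11 mm,
#' the probe pitch). Bubbles travel along straight paths at the epoch's
#' regional blood-flow velocity; their concentration is proportional to local
#' blood volume, so hypoperfused territory produces fewer detectable bubbles.
#'
#' @param frame_rate frames per second (Hz).
#' @param n_frames frames per sequence.
#' @param upsample beamforming refinement relative to the phantom in-plane
#'   grid.
#' @param psf_sigma_px point-spread-function sigma in pixels. The default
#'   (0.65 px) keeps the 3x3 weighted-centroid localization error below
#'   0.1 px everywhere in the subpixel cell.
#' @param bubble_amp blob peak amplitude (post-filter background is ~1).
#' @param noise_sd complex noise standard deviation.
#' @param clutter_amp,clutter_rank residual tissue clutter (removed by the
#'   SVD filter before detection).
#' @param concurrent mean number of bubbles visible per frame at baseline.
#' @param lifetime_frames mean bubble transit duration in frames.
#' @param speed_cv per-bubble lognormal speed spread around the regional mean.
#' @param slice phantom slice (1-based) imaged by the ULM plane; defaults to
#'   the central slice.
#' @return list of class `ulm_params`.
#' @export
ulm_params <- function(frame_rate = 200, n_frames = 200L, upsample = 2L,
                       psf_sigma_px = 0.65, bubble_amp = 60, noise_sd = 1,
                       clutter_amp = 40, clutter_rank = 3L,
                       concurrent = 14, lifetime_frames = 60,
                       speed_cv = 0.10, slice = NULL) {
  stopifnot(frame_rate > 0, n_frames >= 2, psf_sigma_px > 0, bubble_amp > 0)
  structure(as.list(environment()), class = "ulm_params")
}

#' Simulate a microbubble imaging sequence
#'
#' Generates a complex frame stack of the ULM imaging plane containing
#' tissue clutter, noise, and moving Gaussian bubbles, together with the
#' ground-truth per-frame subpixel positions and velocities of every bubble.
#' Bubble speeds follow the epoch's regional CBFv (ipsilesional value inside
#' the lesion ROI, contralesional elsewhere); spawn density is proportional
#' to local blood volume so the occluded territory carries fewer bubbles.
#'
#' @param phantom a `perf_phantom`.
#' @param timeline a `perf_timeline`.
#' @param t_min acquisition time (minutes).
#' @param params a `ulm_params`.
#' @param seed integer seed.
#' @param speed_scale subject-level multiplier on all bubble speeds.
#' @return list with `stack` (a `perf_framestack` on the refined grid),
#'   `tracks` (ground-truth data frame: `track_id, frame, x_px, y_px, x_mm,
#'   y_mm, vx, vy, speed`), and the factors used.
#' @export
simulate_ulm_sequence <- function(phantom, timeline, t_min,
                                  params = ulm_params(), seed = 1L,
                                  speed_scale = 1) {
  f <- epoch_factors(timeline, t_min)
  z <- params$slice %||% ((phantom$dim[3] + 1) %/% 2)
  up <- params$upsample
  nx <- phantom$dim[1] * up; ny <- phantom$dim[2] * up
  px_mm <- phantom$voxel_mm[1:2] / up

  lab2 <- phantom$labels[, , z]
  brain2 <- kron_upsample(lab2 >= 1L, up)
  lesion2 <- kron_upsample(lab2 == 2L, up)
  v2 <- kron_upsample_num(phantom$vessel_frac[, , z], up)
  fac2 <- matrix(f$cbv_contra, nx, ny)
  fac2[lesion2] <- f$cbv_ipsi
  speed2 <- matrix(f$cbfv_contra * speed_scale, nx, ny)
  speed2[lesion2] <- f$cbfv_ipsi * speed_scale

  # expected nearest-neighbour spacing must exceed 2 PSF widths for
  # localization to be well posed
  dens <- params$concurrent / sum(brain2)
  if (0.5 / sqrt(dens) < 2 * params$psf_sigma_px)
    stopf("bubble density too high: expected spacing %.2f px < %.2f px",
          0.5 / sqrt(dens), 2 * params$psf_sigma_px)

  Fn <- params$n_frames
  out <- with_seed(seed, {
    # spawn weights: blood volume (vessel fraction x CBV factor)
    w <- as.vector(v2 * fac2 * brain2)
    w <- w / sum(w)
    # births per frame; scaled by the mean CBV factor so occlusion lowers
    # total bubble flux
    birth_rate <- params$concurrent / params$lifetime_frames * mean(fac2[brain2])

    tracks <- list(); tid <- 0L
    events <- list()
    n0 <- stats::rpois(1, params$concurrent * mean(fac2[brain2]))
    births <- c(rep(1L, n0), rep(seq_len(Fn), stats::rpois(Fn, birth_rate)))
    for (b in births) {
      tid <- tid + 1L
      cell <- sample.int(length(w), 1L, prob = w)
      cx <- (cell - 1) %% nx; cy <- (cell - 1) %/% nx
      pos <- c(cx, cy) + stats::runif(2, -0.5, 0.5)     # 0-based px
      ang <- stats::runif(1, 0, 2 * pi)
      dirv <- c(cos(ang), sin(ang))
      pfac <- stats::rlnorm(1, -params$speed_cv^2 / 2, params$speed_cv)
      life <- max(4L, stats::rpois(1, params$lifetime_frames))
      rows <- vector("list", life)
      fr <- b
      for (s in seq_len(life)) {
        ix <- floor(pos[1] + 0.5) + 1; iy <- floor(pos[2] + 0.5) + 1
        if (fr > Fn || ix < 1 || ix > nx || iy < 1 || iy > ny ||
            !brain2[ix, iy]) break
        sp <- speed2[ix, iy] * pfac                      # mm/s
        step_px <- sp / params$frame_rate / px_mm        # per-axis px/frame
        rows[[s]] <- c(fr, pos, sp * dirv, sp)
        pos <- pos + dirv * step_px
        fr <- fr + 1L
      }
      rows <- rows[!vapply(rows, is.null, logical(1))]
      if (length(rows) >= 2) {
        m <- do.call(rbind, rows)
        events[[length(events) + 1L]] <- cbind(tid, m)
      }
    }
    truth <- if (length(events)) {
      m <- do.call(rbind, events)
      data.frame(track_id = m[, 1], frame = m[, 2], x_px = m[, 3], y_px = m[, 4],
                 vx = m[, 5], vy = m[, 6], speed = m[, 7])
    } else data.frame(track_id = integer(), frame = integer(), x_px = numeric(),
                      y_px = numeric(), vx = numeric(), vy = numeric(),
                      speed = numeric())
    truth$x_mm <- truth$x_px * px_mm[1]
    truth$y_mm <- truth$y_px * px_mm[2]

    # render frames
    P <- nx * ny
    X <- matrix(0i, P, Fn)
    if (params$clutter_rank > 0 && params$clutter_amp > 0) {
      r <- params$clutter_rank
      U <- matrix(complex(real = stats::rnorm(P * r), imaginary = stats::rnorm(P * r)), P, r)
      fr_hz <- stats::runif(r, 0.2, 4); ph <- stats::runif(r, 0, 2 * pi)
      C <- exp(1i * (outer(2 * pi * fr_hz / params$frame_rate, seq_len(Fn) - 1) + ph))
      X <- X + params$clutter_amp * (U %*% C)
    }
    if (nrow(truth)) {
      phase <- stats::runif(max(truth$track_id), 0, 2 * pi)
      s2 <- 2 * params$psf_sigma_px^2
      hw <- 3L
      for (i in seq_len(nrow(truth))) {
        cx <- truth$x_px[i]; cy <- truth$y_px[i]; frm <- truth$frame[i]
        ix <- (floor(cx) - hw):(floor(cx) + hw + 1L)
        iy <- (floor(cy) - hw):(floor(cy) + hw + 1L)
        ix <- ix[ix >= 0 & ix < nx]; iy <- iy[iy >= 0 & iy < ny]
        if (!length(ix) || !length(iy)) next
        blob <- params$bubble_amp *
          outer(exp(-(ix - cx)^2 / s2), exp(-(iy - cy)^2 / s2)) *
          exp(1i * phase[truth$track_id[i]])
        lin <- outer(ix + 1, (iy) * nx, `+`)
        X[lin, frm] <- X[lin, frm] + as.vector(blob)
      }
    }
    if (params$noise_sd > 0)
      X <- X + complex(real = stats::rnorm(P * Fn), imaginary = stats::rnorm(P * Fn)) *
        (params$noise_sd / sqrt(2))
    list(truth = truth, X = X)
  })

  stack <- framestack(out$X, dim_px = c(nx, ny), frame_rate = params$frame_rate,
                      slice_pos_mm = (z - 1) * phantom$voxel_mm[3],
                      t_min = t_min, pixel_mm = px_mm)
  list(stack = stack, tracks = out$truth, factors = f, slice = z,
       lesion_px = lesion2, contra_px = kron_upsample(lab2 == 3L, up),
       brain_px = brain2)
}

kron_upsample <- function(mask, up) {
  if (up == 1) return(mask)
  kronecker(mask, matrix(TRUE, up, up)) & TRUE
}

kron_upsample_num <- function(m, up) {
  if (up == 1) return(m)
  kronecker(m, matrix(1, up, up))
}
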