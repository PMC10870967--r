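#' Detect microbubbles in a clutter-filtered frame stack
#'
#' Per frame, local magnitude maxima above an intensity threshold are
#' localized to subpixel precision by an intensity-weighted centroid over a
#' 3x3 window. Maxima closer than the window size are merged into the
#' brighter peak. Border pixels (where the window would be clipped) are not
#' localized.
#'
#' @param stack a clutter-filtered `perf_framestack`.
#' @param threshold positive detection threshold on magnitude.
#' @param window merge radius in pixels (also the centroid window width).
#' @return data frame of class `perf_localizations`: `frame, x_px, y_px,
#'   x_mm, y_mm, intensity` (positions 0-based pixels).
#' @export
detect_bubbles <- function(stack, threshold, window = 3) {
  if (threshold <= 0) stopf("detection threshold must be positive")
  nx <- stack$dim_px[1]; ny <- stack$dim_px[2]; Fn <- ncol(stack$data)
  A <- array(Mod(stack$data), c(nx, ny, Fn))
  core_x <- 2:(nx - 1); core_y <- 2:(ny - 1)
  C <- A[core_x, core_y, , drop = FALSE]
  ismax <- C > threshold
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    ismax <- ismax & (C >= A[core_x + dx, core_y + dy, , drop = FALSE])
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (!nrow(idx)) {
    out <- data.frame(frame = integer(), x_px = numeric(), y_px = numeric(),
                      x_mm = numeric(), y_mm = numeric(), intensity = numeric())
    class(out) <- c("perf_localizations", "data.frame")
    return(out)
  }
  px <- idx[, 1] + 1L; py <- idx[, 2] + 1L; fr <- idx[, 3]  # 1-based grid
  inten <- A[cbind(px, py, fr)]

  # merge maxima closer than `window` within a frame, keeping the brighter
  keep <- rep(TRUE, length(fr))
  ord <- order(fr, -inten)
  i <- 1L
  while (i <= length(ord)) {
    j <- i + 1L
    oi <- ord[i]
    if (keep[oi]) {
      while (j <= length(ord) && fr[ord[j]] == fr[oi]) {
        oj <- ord[j]
        if (keep[oj] &&
            abs(px[oj] - px[oi]) < window && abs(py[oj] - py[oi]) < window)
          keep[oj] <- FALSE
        j <- j + 1L
      }
    }
    i <- i + 1L
  }
  px <- px[keep]; py <- py[keep]; fr <- fr[keep]; inten <- inten[keep]

  # 3x3 intensity-weighted centroid around each peak
  n <- length(px)
  sx <- numeric(n); sy <- numeric(n); sw <- numeric(n)
  for (dx in -1:1) for (dy in -1:1) {
    w <- A[cbind(px + dx, py + dy, fr)]
    sw <- sw + w
    sx <- sx + w * dx
    sy <- sy + w * dy
  }
  x0 <- (px - 1) + sx / sw   # 0-based subpixel
  y0 <- (py - 1) + sy / sw
  out <- data.frame(frame = fr, x_px = x0, y_px = y0,
                    x_mm = x0 * stack$pixel_mm[1], y_mm = y0 * stack$pixel_mm[2],
                    intensity = inten)
  out <- out[order(out$frame, out$x_px), ]
  rownames(out) <- NULL
  class(out) <- c("perf_localizations", "data.frame")
  attr(out, "pixel_mm") <- stack$pixel_mm
  attr(out, "frame_rate") <- stack$frame_rate
  attr(out, "dim_px") <- stack$dim_px
  out
}

#' Link localizations into bubble tracks
#'
#' Greedy nearest-neighbour linking: for each frame transition, candidate
#' pairs (active track end, new detection) within the velocity gate
#' `v_max / frame_rate` (scaled by the frame gap) are assigned in ascending
#' distance order; ties are broken deterministically by track then detection
#' order. Unmatched detections seed new tracks; a track may bridge up to
#' `max_gap` missing frames, with the skipped position filled by linear
#' interpolation. Tracks shorter than `min_len` localizations are discarded.
#'
#' @param locs a `perf_localizations` data frame.
#' @param frame_rate frames per second; defaults to the attribute carried by
#'   `locs`.
#' @param v_max gating speed (mm/s).
#' @param max_gap maximum number of bridged missing frames.
#' @param min_len minimum retained track length (localizations).
#' @return list of class `perf_tracks`; each element a data frame
#'   `frame, x_mm, y_mm, interpolated`.
#' @export
link_tracks <- function(locs, frame_rate = attr(locs, "frame_rate"),
                        v_max = 50, max_gap = 1L, min_len = 4L) {
  if (is.null(frame_rate)) stopf("frame rate unknown")
  if (v_max <= 0) stopf("v_max must be positive")
  gate <- v_max / frame_rate      # mm per frame
  done <- list()
  active <- list()                # each: list(rows, last_frame)
  frames <- sort(unique(locs$frame))
  for (f in frames) {
    det <- locs[locs$frame == f, , drop = FALSE]
    nd <- nrow(det)
    if (length(active)) {
      lastf <- vapply(active, function(a) a$last_frame, numeric(1))
      expired <- f - lastf > max_gap + 1L
      done <- c(done, active[expired])
      active <- active[!expired]
    }
    na <- length(active)
    if (na && nd) {
      lastx <- vapply(active, function(a) a$x, numeric(1))
      lasty <- vapply(active, function(a) a$y, numeric(1))
      lastf <- vapply(active, function(a) a$last_frame, numeric(1))
      dgap <- f - lastf
      D <- sqrt(outer(lastx, det$x_mm, `-`)^2 + outer(lasty, det$y_mm, `-`)^2)
      lim <- gate * dgap
      cand <- which(D <= matrix(lim, na, nd), arr.ind = TRUE)
      if (nrow(cand)) {
        o <- order(D[cand], cand[, 1], cand[, 2])   # distance, then track, then detection
        usedA <- rep(FALSE, na); usedD <- rep(FALSE, nd)
        for (ci in o) {
          a <- cand[ci, 1]; dj <- cand[ci, 2]
          if (usedA[a] || usedD[dj]) next
          usedA[a] <- TRUE; usedD[dj] <- TRUE
          tr <- active[[a]]
          if (f - tr$last_frame > 1L) {
            # bridge a single missing frame by linear interpolation
            for (g in seq_len(f - tr$last_frame - 1L)) {
              w <- g / (f - tr$last_frame)
              tr$rows[[length(tr$rows) + 1L]] <-
                c(tr$last_frame + g,
                  tr$x + w * (det$x_mm[dj] - tr$x),
                  tr$y + w * (det$y_mm[dj] - tr$y), 1)
            }
          }
          tr$rows[[length(tr$rows) + 1L]] <- c(f, det$x_mm[dj], det$y_mm[dj], 0)
          tr$x <- det$x_mm[dj]; tr$y <- det$y_mm[dj]; tr$last_frame <- f
          active[[a]] <- tr
        }
        unmatched <- which(!usedD)
      } else unmatched <- seq_len(nd)
    } else unmatched <- seq_len(nd)
    for (dj in unmatched) {
      active[[length(active) + 1L]] <-
        list(rows = list(c(f, det$x_mm[dj], det$y_mm[dj], 0)),
             x = det$x_mm[dj], y = det$y_mm[dj], last_frame = f)
    }
  }
  done <- c(done, active)
  tracks <- lapply(done, function(a) {
    m <- do.call(rbind, a$rows)
    data.frame(frame = m[, 1], x_mm = m[, 2], y_mm = m[, 3],
               interpolated = m[, 4] == 1)
  })
  tracks <- tracks[vapply(tracks, nrow, integer(1)) >= min_len]
  structure(tracks, class = "perf_tracks", frame_rate = frame_rate)
}

#' Per-step and mean speed of a track
#'
#' Step speed is the Euclidean displacement between consecutive localizations
#' times the frame rate; the track speed is the mean over steps.
#'
#' @param track one track data frame (`frame, x_mm, y_mm`).
#' @param frame_rate frames per second.
#' @return list with `step_speeds` (mm/s) and `mean_speed`.
#' @export
track_velocity <- function(track, frame_rate) {
  if (nrow(track) < 2) stopf("a single-point track has no velocity")
  dx <- diff(track$x_mm); dy <- diff(track$y_mm); df <- diff(track$frame)
  sp <- sqrt(dx^2 + dy^2) / df * frame_rate
  list(step_speeds = sp, mean_speed = mean(sp))
}

#' Accumulate tracks into density and velocity maps
#'
#' Each track step deposits its step speed at the refined-grid pixel of the
#' step's starting localization; the velocity map is the per-pixel mean of
#' deposits and the count map the number of deposits.
#'
#' @param tracks a `perf_tracks` list.
#' @param dim_px acquisition grid dimensions `c(nx, ny)`.
#' @param pixel_mm acquisition pixel size (mm).
#' @param upsample refinement factor (>= 1) of the output grid.
#' @return list of class `perf_cbfv_map`: `velocity` (mm/s, `NA` where no
#'   deposits), `count`, `pixel_mm`, `upsample`.
#' @export
accumulate_maps <- function(tracks, dim_px, pixel_mm, upsample = 8) {
  if (upsample < 1) stopf("upsample factor must be >= 1")
  frame_rate <- attr(tracks, "frame_rate")
  nxr <- dim_px[1] * upsample; nyr <- dim_px[2] * upsample
  cnt <- matrix(0, nxr, nyr); vsum <- matrix(0, nxr, nyr)
  for (tr in tracks) {
    v <- track_velocity(tr, frame_rate)
    n <- nrow(tr)
    ix <- floor(tr$x_mm[-n] / pixel_mm[1] * upsample + 0.5) + 1L
    iy <- floor(tr$y_mm[-n] / pixel_mm[2] * upsample + 0.5) + 1L
    ok <- ix >= 1 & ix <= nxr & iy >= 1 & iy <= nyr
    lin <- (iy[ok] - 1L) * nxr + ix[ok]
    for (k in seq_along(lin)) {       # duplicates must each deposit
      cnt[lin[k]] <- cnt[lin[k]] + 1
      vsum[lin[k]] <- vsum[lin[k]] + v$step_speeds[ok][k]
    }
  }
  vel <- vsum / cnt
  vel[cnt == 0] <- NA_real_
  structure(list(velocity = vel, count = cnt,
                 pixel_mm = pixel_mm / upsample, upsample = upsample),
            class = "perf_cbfv_map")
}

#' ROI mean blood-flow velocity over detected pixels
#'
#' Averages the velocity map over ROI pixels with at least one deposit
#' (non-zero pixels only); pixels without detections are excluded rather
#' than counted as zero. If the ROI contains no detected pixel the mean is
#' `NA` and the zero-pixel fraction is 1 (hypoperfused territory is often
#' below the detection limit).
#'
#' @param map a `perf_cbfv_map`.
#' @param roi logical matrix on the map's refined grid.
#' @return list: `mean_cbfv`, `zero_fraction`, `n_used`.
#' @export
roi_cbfv <- function(map, roi) {
  if (!any(roi)) stopf("empty ROI mask")
  inroi <- roi & map$count > 0
  n <- sum(inroi)
  list(mean_cbfv = if (n) mean(map$velocity[inroi]) else NA_real_,
       zero_fraction = 1 - n / sum(roi),
       n_used = n)
}
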