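test_that("noiseless Gaussian blobs localize to within 0.1 px", {
  offs <- expand.grid(dx = c(-0.4, -0.2, 0, 0.25, 0.45), dy = c(-0.3, 0.1, 0.4))
  centers <- lapply(seq_len(nrow(offs)), function(i)
    cbind(12 + offs$dx[i], 7 + offs$dy[i]))
  st <- blob_stack(centers)
  locs <- detect_bubbles(st, threshold = 10)
  expect_equal(nrow(locs), nrow(offs))
  err <- sqrt((locs$x_px - (12 + offs$dx[locs$frame]))^2 +
              (locs$y_px - (7 + offs$dy[locs$frame]))^2)
  expect_lt(max(err), 0.1)
})

test_that("detection handles empty frames, close pairs and separated pairs", {
  noise <- framestack(matrix(complex(real = rnorm(32 * 32 * 5),
                                     imaginary = rnorm(32 * 32 * 5)) * 0.1,
                             1024, 5), dim_px = c(32, 32), frame_rate = 200,
                      pixel_mm = c(0.1, 0.1))
  expect_equal(nrow(detect_bubbles(noise, threshold = 10)), 0)

  two <- blob_stack(list(rbind(c(8.2, 8.4), c(18.2, 8.4))))   # 10 px apart
  expect_equal(nrow(detect_bubbles(two, threshold = 10)), 2)

  close_pair <- blob_stack(list(rbind(c(10, 10), c(11.6, 10))))
  got <- detect_bubbles(close_pair, threshold = 10)
  expect_equal(nrow(got), 1)                                   # merged

  expect_error(detect_bubbles(two, threshold = 0), "positive")
})

test_that("greedy linking follows isolated bubbles and respects the gate", {
  # one bubble moving 0.02 mm/frame: one track containing all frames
  fr <- 200
  locs <- data.frame(frame = 1:20, x_px = 10 + 0.2 * (0:19), y_px = 5,
                     x_mm = (10 + 0.2 * (0:19)) * 0.1, y_mm = 0.5,
                     intensity = 1)
  attr(locs, "frame_rate") <- fr
  tr <- link_tracks(locs, v_max = 10, min_len = 4)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]), 20)

  # displacement beyond the gate splits the trajectory
  jump <- locs
  jump$x_mm[11:20] <- jump$x_mm[11:20] + 5
  tr2 <- link_tracks(jump, v_max = 10, min_len = 4)
  expect_length(tr2, 2)
})

test_that("greedy assignment equals exhaustive minimum-cost matching (<= 3 bubbles)", {
  # brute-force oracle over frame pairs; compare matched pairs
  set.seed(42)
  perms <- list(1L, rbind(c(1, 2), c(2, 1)),
                rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                      c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
  for (rep in 1:25) {
    n <- sample(2:3, 1)
    p0 <- matrix(runif(n * 2, 0, 3), n, 2)
    step <- matrix(runif(n * 2, -0.04, 0.04), n, 2)
    p1 <- p0 + step
    D <- as.matrix(stats::dist(rbind(p0, p1)))[1:n, (n + 1):(2 * n), drop = FALSE]
    pm <- perms[[n]]
    if (n == 1) best <- 1L else {
      costs <- apply(pm, 1, function(pp) sum(D[cbind(1:n, pp)]))
      best <- pm[which.min(costs), ]
    }
    locs <- data.frame(frame = rep(1:2, each = n),
                       x_mm = c(p0[, 1], p1[, 1]), y_mm = c(p0[, 2], p1[, 2]),
                       x_px = 0, y_px = 0, intensity = 1)
    attr(locs, "frame_rate") <- 200
    trs <- link_tracks(locs, v_max = 50, min_len = 2)
    expect_length(trs, n)
    for (i in 1:n) {
      tr <- Filter(function(t) isTRUE(all.equal(t$x_mm[1], p0[i, 1])), trs)[[1]]
      expect_equal(tr$x_mm[2], p1[best[i], 1], tolerance = 1e-12)
    }
  }
})

test_that("track velocity is displacement times frame rate", {
  tr <- data.frame(frame = 1:3, x_mm = c(0, 0.0292, 0.0584), y_mm = 0)
  v <- track_velocity(tr, 500)
  expect_equal(v$mean_speed, 14.6)

  still <- data.frame(frame = 1:5, x_mm = 1, y_mm = 2)
  expect_equal(track_velocity(still, 500)$mean_speed, 0)

  two <- data.frame(frame = 1:3, x_mm = c(0, 0.01, 0.04), y_mm = 0)
  expect_equal(track_velocity(two, 500)$mean_speed, 10)  # steps 5 and 15 mm/s

  expect_error(track_velocity(data.frame(frame = 1, x_mm = 0, y_mm = 0), 500),
               "single-point")
})

test_that("map accumulation deposits step speeds on the refined grid", {
  empty <- structure(list(), class = "perf_tracks", frame_rate = 200)
  m0 <- accumulate_maps(empty, dim_px = c(8, 8), pixel_mm = c(0.1, 0.1),
                        upsample = 4)
  expect_true(all(m0$count == 0))
  expect_true(all(is.na(m0$velocity)))

  tr <- data.frame(frame = 1:10, x_mm = seq(0.1, 0.55, by = 0.05), y_mm = 0.4)
  trs <- structure(list(tr), class = "perf_tracks", frame_rate = 200)
  m <- accumulate_maps(trs, dim_px = c(8, 8), pixel_mm = c(0.1, 0.1),
                       upsample = 4)
  v <- track_velocity(tr, 200)
  expect_equal(mean(m$velocity[m$count > 0]), v$mean_speed)
  # deposits trace the motion axis
  hit <- which(m$count > 0, arr.ind = TRUE)
  expect_equal(length(unique(hit[, 2])), 1)
})

test_that("ROI averaging uses only detected pixels and ignores added empty ones", {
  vel <- matrix(NA_real_, 4, 4); cnt <- matrix(0, 4, 4)
  vel[1, 1] <- 10; cnt[1, 1] <- 2
  vel[2, 1] <- 20; cnt[2, 1] <- 1
  map <- structure(list(velocity = vel, count = cnt, pixel_mm = c(.1, .1),
                        upsample = 1), class = "perf_cbfv_map")
  roi <- matrix(FALSE, 4, 4); roi[1:3, 1] <- TRUE   # one empty pixel included
  r <- roi_cbfv(map, roi)
  expect_equal(r$mean_cbfv, 15)
  expect_equal(r$zero_fraction, 1 / 3)

  bigger <- roi; bigger[, 3] <- TRUE                 # only empty pixels added
  expect_equal(roi_cbfv(map, bigger)$mean_cbfv, 15)

  none <- matrix(FALSE, 4, 4); none[4, 4] <- TRUE
  rn <- roi_cbfv(map, none)
  expect_true(is.na(rn$mean_cbfv))
  expect_equal(rn$zero_fraction, 1)
  expect_error(roi_cbfv(map, matrix(FALSE, 4, 4)), "empty")
})

test_that("bubble simulation: spacing precondition, kinematics and determinism", {
  ph <- tiny_phantom()
  tl <- tmcao_timeline()
  p <- ulm_params(n_frames = 40, concurrent = 6)
  a <- simulate_ulm_sequence(ph, tl, -20, p, seed = 3)
  b <- simulate_ulm_sequence(ph, tl, -20, p, seed = 3)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$tracks, b$tracks)

  # consecutive true positions advance by speed / frame rate
  tr1 <- a$tracks[a$tracks$track_id == a$tracks$track_id[1], ]
  if (nrow(tr1) >= 2) {
    d_mm <- sqrt(diff(tr1$x_mm)^2 + diff(tr1$y_mm)^2)
    expect_equal(d_mm, tr1$speed[-nrow(tr1)] / p$frame_rate, tolerance = 1e-8)
  }

  # at 500 Hz a 14.6 mm/s bubble advances 0.0292 mm per frame
  p500 <- ulm_params(frame_rate = 500, n_frames = 30, concurrent = 6)
  s5 <- simulate_ulm_sequence(ph, build_scenario("null"), -20, p500, seed = 9)
  tr <- s5$tracks[s5$tracks$track_id == s5$tracks$track_id[1], ]
  step <- sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2)
  expect_equal(step, rep(tr$speed[1] / 500, length(step)), tolerance = 1e-8)

  dense <- ulm_params(n_frames = 10, concurrent = 4000)
  expect_error(simulate_ulm_sequence(ph, tl, -20, dense, seed = 1), "density")

  # occlusion epoch: lesion-resident bubbles move at the reduced ipsi CBFv
  pocc <- ulm_params(n_frames = 40, concurrent = 10, speed_cv = 0)
  so <- simulate_ulm_sequence(ph, tl, 45, pocc, seed = 11)
  lx <- floor(so$tracks$x_px + 0.5) + 1; ly <- floor(so$tracks$y_px + 0.5) + 1
  in_les <- so$lesion_px[cbind(lx, ly)]
  if (any(in_les)) expect_equal(unique(so$tracks$speed[in_les]), 9.1)
  if (any(!in_les)) expect_true(all(so$tracks$speed[!in_les] %in% c(15.9)))
})

test_that("isolated-bubble speed recovery is within 5 percent", {
  ph <- tiny_phantom()
  nullsc <- build_scenario("null")
  p <- ulm_params(n_frames = 120, concurrent = 4, clutter_amp = 0,
                  noise_sd = 0.5, speed_cv = 0)
  ests <- truths <- numeric(0)
  for (s in 1:4) {
    sim <- simulate_ulm_sequence(ph, nullsc, -20, p, seed = s)
    locs <- detect_bubbles(sim$stack, 12)
    trs <- link_tracks(locs, v_max = 50, min_len = 6)
    if (!length(trs)) next
    ests <- c(ests, vapply(trs, function(t)
      track_velocity(t, p$frame_rate)$mean_speed, numeric(1)))
    truths <- c(truths, mean(sim$tracks$speed))
  }
  expect_gt(length(ests), 5)
  expect_lt(abs(mean(ests) - 14.6) / 14.6, 0.05)
})
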