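test_that("T2 fit recovers noiseless decay exactly and matches the 2-echo closed form", {
  te <- c(30, 50, 80, 190)
  S <- cbind(1000 * exp(-te / 70))
  f <- fit_t2_map(S, te_ms = te)
  expect_equal(f$t2[1], 70, tolerance = 1e-4)
  expect_equal(f$s0[1], 1000, tolerance = 1e-3)
  expect_true(f$converged[1])

  # two echoes: T2 = (TE2 - TE1) / ln(S1/S2), exactly
  te2 <- c(40, 110)
  s2 <- cbind(c(850, 400), c(620, 180))
  f2 <- fit_t2_map(s2, te_ms = te2)
  closed <- (te2[2] - te2[1]) / log(s2[1, ] / s2[2, ])
  expect_equal(f2$t2, closed, tolerance = 1e-6)

  # all-zero voxel flagged, not fatal
  s3 <- cbind(1000 * exp(-te / 60), rep(0, 4))
  f3 <- fit_t2_map(s3, te_ms = te)
  expect_false(f3$converged[2])
  expect_true(is.na(f3$t2[2]))
  expect_equal(f3$t2[1], 60, tolerance = 1e-4)
})

test_that("T2 fit error stays small at realistic noise", {
  set.seed(7)
  te <- c(30, 50, 80, 190)
  n <- 1000
  t2_true <- runif(n, 40, 90)
  S <- vapply(t2_true, function(tt) 1000 * exp(-te / tt), numeric(4))
  sdn <- mean(S) / 50                         # SNR 50 on the measured signal
  S <- S + rnorm(length(S), 0, sdn)
  f <- fit_t2_map(S, te_ms = te)
  ok <- f$converged                           # rare negative-signal voxels flagged
  expect_gt(mean(ok), 0.9)
  expect_lt(median(abs(f$t2[ok] - t2_true[ok]) / t2_true[ok]), 0.03)
})

test_that("vectorised Levenberg-Marquardt agrees with minpack.lm per voxel", {
  skip_if_not_installed("minpack.lm")
  set.seed(11)
  te <- c(30, 50, 80, 190)
  for (i in 1:12) {
    t2t <- runif(1, 35, 95)
    y <- 1000 * exp(-te / t2t) + rnorm(4, 0, 15)
    if (any(y <= 0)) next
    ours <- fit_t2_map(cbind(y), te_ms = te)
    ref <- minpack.lm::nlsLM(y ~ S0 * exp(-te / T2),
                             start = list(S0 = 900, T2 = 60))
    expect_equal(ours$t2[1], coef(ref)[["T2"]], tolerance = 1e-4)
    expect_equal(ours$s0[1], coef(ref)[["S0"]], tolerance = 1e-4)
  }
})

test_that("lesion segmentation finds the edematous region and obeys its rules", {
  # study-size grid: the false-positive budget scales with the lesion
  # surface-to-volume ratio, so the check runs at protocol scale
  ph <- build_phantom(nx = 64, ny = 64, nz = 21, lesion_frac = 0.15, seed = 2)
  me <- simulate_multiecho_t2(ph, t2_params(noise_sd = 5), seed = 4)
  t2map <- fit_t2_map(me, mask = phantom_mask(ph, "brain"))
  d <- ph$dim
  xs <- array(rep(seq_len(d[1]) - 1, times = d[2] * d[3]), d)
  contra_hemi <- phantom_mask(ph, "brain") & xs < ph$midline
  seg <- segment_lesion(t2map, contra_hemi, k = 2)
  truth <- phantom_mask(ph, "lesion")
  expect_gt(sum(seg & truth) / sum(truth), 0.95)
  expect_lt(sum(seg & !truth) / sum(seg), 0.05)

  # uniform map: empty result
  flat <- t2map
  flat$t2[phantom_mask(ph, "brain")] <- 55
  expect_equal(sum(segment_lesion(flat, contra_hemi)), 0)

  # two disjoint hot regions: only the larger survives
  two <- flat
  two$t2[5:9, 5:9, 2] <- 90
  two$t2[20:21, 20:21, 4] <- 90
  seg2 <- segment_lesion(two, contra_hemi)
  expect_true(all(which(seg2, arr.ind = TRUE)[, 3] == 2))

  expect_error(segment_lesion(t2map, array(FALSE, d)), "reference")
})

test_that("multi-echo simulation follows the monoexponential forward model", {
  ph <- tiny_phantom()
  p <- t2_params(noise_sd = 0)
  me <- simulate_multiecho_t2(ph, p, seed = 1)
  les <- phantom_mask(ph, "lesion")
  con <- phantom_mask(ph, "contra")
  expect_gt(mean(me$truth$t2[les]), mean(me$truth$t2[con]))

  # log-signal is exactly linear in TE with slope -1/T2
  v <- which(les)[1]
  sig <- vapply(seq_along(p$te_ms), function(e)
    me$echoes[, , , e][v], numeric(1))
  fit <- stats::lm(log(sig) ~ me$te_ms)
  expect_equal(unname(coef(fit)[2]), -1 / me$truth$t2[v], tolerance = 1e-9)

  expect_error(t2_params(te_ms = c(30, 30, 80)), "strictly increasing")
  expect_error(t2_params(te_ms = 30), "at least 2")
})

test_that("signal-to-concentration inverts the forward model", {
  ph <- tiny_phantom()
  tl <- tmcao_timeline()
  p <- dsc_params(n_images = 300, injection_index = 100, noise_sd = 0)
  d <- simulate_dsc_series(ph, tl, 45, p, seed = 2,
                           voxels = which(ph$labels >= 1L)[1:50])
  # pre-bolus images sit exactly at S0
  expect_equal(unique(as.vector(d$signal[1:99, ])), p$s0)
  conc <- signal_to_concentration(d, baseline_window = c(10, 90))
  expect_equal(conc$conc, p$k * d$truth$conc, tolerance = 1e-10)

  # S = S0 * exp(-0.13) at TE 13 ms -> C = 0.01 / ms = 10 / s
  toy <- list(signal = cbind(c(rep(1000, 5), 1000 * exp(-0.13))),
              tr_s = 0.1, te_s = 0.013, injection_index = 6, voxels = 1,
              dim = NULL)
  ctoy <- signal_to_concentration(toy, baseline_window = c(1, 5))
  expect_equal(ctoy$conc[6, 1], 10, tolerance = 1e-12)

  expect_error(signal_to_concentration(d, baseline_window = c(10, 150)),
               "before the injection")
})

test_that("truncated trapezoidal CBV matches the gamma-variate closed form", {
  tr <- 0.164
  tt <- (0:499) * tr
  A <- 5; t0 <- 8; al <- 3; be <- 0.8
  g <- gamma_variate(tt, A, t0, al, be)
  conc <- structure(list(conc = cbind(g, 0 * g), tr_s = tr, te_s = 0.013,
                         injection_index = 40, voxels = 1:2, dim = NULL),
                    class = "perf_conc")
  cbv <- compute_cbv_map(conc, truncation = 400)
  area <- A * be^(al + 1) * gamma(al + 1)
  expect_lt(abs(cbv[1] - area) / area, 0.005)
  expect_equal(cbv[2], 0)
  expect_error(compute_cbv_map(conc, truncation = 600), "exceeds")

  # non-decreasing in the truncation index for non-negative concentration
  cbvs <- vapply(c(100, 200, 300, 400, 500), function(k)
    compute_cbv_map(conc, k)[1], numeric(1))
  expect_true(all(diff(cbvs) >= -1e-12))
})

test_that("arterial reference selection picks the labelled artery", {
  ph <- tiny_phantom()
  tl <- tmcao_timeline()
  p <- dsc_params(n_images = 300, injection_index = 100, noise_sd = 1)
  d <- simulate_dsc_series(ph, tl, 45, p, seed = 6)
  conc <- signal_to_concentration(d, baseline_window = c(10, 90))
  dm <- ph$dim
  xs <- array(rep(seq_len(dm[1]) - 1, times = dm[2] * dm[3]), dm)
  contra_hemi <- (xs < ph$midline)[d$voxels]
  aif <- select_aif(conc, contra_hemi, n = 5)
  expect_true(all(ph$labels[d$voxels[aif$voxels]] == 4L))

  # n = 1 returns exactly the strongest arterial curve
  a1 <- select_aif(conc, contra_hemi, n = 1)
  expect_equal(a1$curve, conc$conc[, a1$voxels])

  # excluding the artery yields a visibly delayed, weaker reference
  no_art <- contra_hemi & d$truth$labels != 4L
  a2 <- select_aif(conc, no_art, n = 3)
  expect_gt(min(a2$qc$arrival_index), min(aif$qc$arrival_index))
  expect_error(select_aif(conc, rep(FALSE, length(d$voxels))), "empty")
})

test_that("circulant deconvolution recovers flow, residue and transit time", {
  tr <- 0.164
  n <- 400
  tt <- (0:(n - 1)) * tr
  aif <- gamma_variate(tt, 60, 5, 3, 0.8)
  conv_ref <- function(x, y) {
    L <- 2 * length(x)
    Re(stats::fft(stats::fft(c(x, numeric(L - length(x)))) *
                  stats::fft(c(y, numeric(L - length(y)))),
                  inverse = TRUE))[seq_along(x)] / L
  }
  cbf_true <- 0.7; mtt <- 1.8
  ct <- cbf_true * conv_ref(aif, exp(-tt / mtt)) * tr
  conc <- structure(list(conc = cbind(ct), tr_s = tr, te_s = 0.013,
                         injection_index = 30, voxels = 1, dim = NULL),
                    class = "perf_conc")
  out <- compute_cbf_map(conc, aif, lambda = 1e-8)
  expect_lt(abs(out$cbf - cbf_true) / cbf_true, 0.05)

  # central volume theorem: CBV / CBF ~ MTT (the CBV index carries the AIF
  # area since both maps are in arbitrary units)
  cbv <- compute_cbv_map(conc, truncation = n)
  aif_area <- (sum(aif) - (aif[1] + aif[n]) / 2) * tr
  expect_lt(abs(cbv / (out$cbf * aif_area) - mtt) / mtt, 0.10)

  # tissue = AIF (delta residue): peak at the origin, CBF consistent with 1/TR
  conc2 <- structure(list(conc = cbind(aif), tr_s = tr, te_s = 0.013,
                          injection_index = 30, voxels = 1, dim = NULL),
                     class = "perf_conc")
  out2 <- compute_cbf_map(conc2, aif, lambda = 1e-8)
  expect_equal(out2$tmax[1], 1)
  expect_equal(out2$cbf[1], 1 / tr, tolerance = 1e-6)

  expect_error(compute_cbf_map(conc, rep(0, n)), "all-zero")
  expect_error(compute_cbf_map(conc, aif[1:100]), "equal length")
})

test_that("deconvolution at vanishing threshold equals Fourier-domain division", {
  tr <- 0.2; n <- 150
  tt <- (0:(n - 1)) * tr
  aif <- gamma_variate(tt, 40, 3, 2.5, 0.9)
  set.seed(3)
  resid <- exp(-tt / 2.1)
  L <- 2 * n
  ct <- Re(stats::fft(stats::fft(c(aif, numeric(n))) *
                      stats::fft(c(resid, numeric(n))), inverse = TRUE))[1:n] / L * tr * 0.5
  conc <- structure(list(conc = cbind(ct), tr_s = tr, te_s = 0.013,
                         injection_index = 10, voxels = 1, dim = NULL),
                    class = "perf_conc")
  out <- compute_cbf_map(conc, aif, lambda = 1e-12)
  kf <- Re(stats::fft(stats::fft(c(ct, numeric(n))) /
                      (tr * stats::fft(c(aif, numeric(n)))), inverse = TRUE)) / L
  expect_lt(max(abs(apply(cbind(out$cbf), 2, max) - max(kf))) / max(kf), 1e-6)
})

test_that("DSC simulation enforces physiological preconditions", {
  ph <- tiny_phantom()
  # a scenario with CBV > 0 but CBF = 0 is rejected (undefined transit time)
  ep <- data.frame(name = "x", t_start = 0, t_end = 10,
                   cbv_ipsi = 1, cbv_contra = 1, cbfv_ipsi = 10,
                   cbfv_contra = 10, dsc_cbv_ipsi = 0.5, dsc_cbv_contra = 1,
                   dsc_cbf_ipsi = 0, dsc_cbf_contra = 1)
  tl <- build_scenario(ep)
  expect_error(simulate_dsc_series(ph, tl, 5, dsc_params(), seed = 1),
               "MTT")
  expect_error(dsc_params(injection_index = 600, n_images = 500))
})
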