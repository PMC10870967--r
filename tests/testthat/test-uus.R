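test_that("SVD clutter filter matches an explicit full-SVD reconstruction", {
  # oracle: zero the leading singular values of an independent La.svd
  for (seed in 1:4) {
    st <- random_stack(P = 60, F = 40, seed = seed)
    k <- c(1, 5, 12, 30)[seed]
    sv <- La.svd(st$data)
    ref <- sv$u[, (k + 1):40, drop = FALSE] %*%
      (sv$d[(k + 1):40] * sv$vt[(k + 1):40, , drop = FALSE])
    out <- svd_clutter_filter(st, k)$data
    expect_lt(sqrt(sum(Mod(out - ref)^2)) / sqrt(sum(Mod(ref)^2)), 1e-8)
  }
})

test_that("filter limiting cases: identity, full removal, residual energy", {
  st <- random_stack(P = 50, F = 40, seed = 3)
  expect_equal(svd_clutter_filter(st, 0)$data, st$data)

  # rank-1 stack is annihilated by removing one component
  u <- complex(real = rnorm(50), imaginary = rnorm(50))
  v <- complex(real = rnorm(40), imaginary = rnorm(40))
  r1 <- framestack(u %*% t(v), dim_px = c(50, 1), frame_rate = 500)
  out <- svd_clutter_filter(r1, 1)$data
  expect_lt(sqrt(sum(Mod(out)^2)), 1e-10 * sqrt(sum(Mod(r1$data)^2)))

  # residual Frobenius norm^2 equals the sum of squared trailing singular values
  sv <- La.svd(st$data, nu = 0, nv = 0)
  res <- svd_clutter_filter(st, 5)$data
  expect_equal(sum(Mod(res)^2), sum(sv$d[6:40]^2), tolerance = 1e-10)

  # output orthogonal to the removed component
  removed <- st$data - res
  expect_lt(Mod(sum(Conj(removed) * res)), 1e-6 * sum(Mod(st$data)^2))

  expect_error(svd_clutter_filter(st, 40), "n_remove")
})

test_that("residual energy is non-increasing in the number of removed components", {
  st <- random_stack(P = 45, F = 30, seed = 9)
  en <- vapply(0:29, function(k) sum(Mod(svd_clutter_filter(st, k)$data)^2),
               numeric(1))
  expect_true(all(diff(en) <= 1e-8))
})

test_that("power Doppler is the mean squared magnitude per pixel", {
  z <- framestack(matrix(0i, 12, 6), dim_px = c(4, 3), frame_rate = 500)
  expect_true(all(power_doppler(z)$img == 0))

  m <- 3.5
  const <- framestack(matrix(m * exp(1i * runif(60)), 10, 6),
                      dim_px = c(5, 2), frame_rate = 500)
  expect_equal(as.vector(power_doppler(const)$img), rep(m^2, 10))
})

test_that("whole-brain assembly records the scan geometry and is sort-invariant", {
  mk <- function(z, t) structure(list(img = matrix(z, 4, 4),
                                      pixel_mm = c(0.22, 0.222),
                                      slice_pos_mm = z * 0.3, t_min = t),
                                 class = "perf_pd_slice")
  slices <- lapply(0:20, function(z) mk(z, t = z * 0.01))
  vol <- assemble_wb_volume(slices)
  expect_equal(vol$extent_mm[3], 21 * 0.3)        # 6.3 mm elevational extent
  expect_equal(vol$voxel_mm[3], 0.3)
  shuffled <- assemble_wb_volume(slices[sample(21)])
  expect_equal(shuffled$vol, vol$vol)
  expect_equal(shuffled$slice_pos_mm, vol$slice_pos_mm)

  one <- assemble_wb_volume(slices[1])
  expect_equal(dim(one$vol)[3], 1)
  expect_equal(one$vol[, , 1], slices[[1]]$img)

  bad <- slices[c(1, 2, 4)]                        # pitch 0.3 then 0.6
  expect_error(assemble_wb_volume(bad), "pitch")
})

test_that("timeline interpolation, extrapolation and clipping follow the line", {
  v1 <- array(2, c(2, 2, 1)); v2 <- array(4, c(2, 2, 1))
  s <- build_timeline_series(list(v1, v2), times = c(0, 10), grid = c(5, 15))
  expect_equal(unique(as.vector(s$series[1, ])), 3)    # midpoint
  expect_equal(unique(as.vector(s$series[2, ])), 5)    # extrapolated

  # negative extrapolation clipped at zero
  v3 <- array(1, c(2, 2, 1))
  s2 <- build_timeline_series(list(v2, v3), times = c(0, 10), grid = c(25))
  expect_equal(unique(as.vector(s2$series)), 0)        # 4 - 0.3*25 < 0

  # constant acquisitions stay constant through declared gaps
  s3 <- build_timeline_series(list(v1, v1, v1), times = c(0, 10, 40),
                              grid = 0:40, gaps = list(c(15, 35)))
  expect_true(all(s3$series == 2))

  expect_error(build_timeline_series(list(v1), times = 0, grid = 0:5), "2")
})

test_that("relative CBV normalizes by the baseline median and masks dead voxels", {
  S <- rbind(c(2, 0), c(2, 0), c(4, 0), c(6, 0))
  ser <- structure(list(series = S, grid = c(-2, -1, 5, 10), dim = c(2, 1, 1)),
                   class = "perf_series")
  r <- relative_cbv(ser, baseline_window = c(-2, -1))
  expect_equal(r$series[, 1], c(1, 1, 2, 3))
  expect_true(is.na(r$series[1, 2]))                  # zero baseline masked
  expect_equal(r$valid, c(TRUE, FALSE))
  expect_error(relative_cbv(ser, baseline_window = c(-9, -8)), "baseline")
})

test_that("coefficient-of-variation mask uses the population sd over mean", {
  a <- 7
  S <- cbind(rep(a, 10),                              # constant: excluded
             rep(c(0.8, 1.2) * a, 5),                 # CoV 0.2: included
             rep(c(0.9, 1.1) * a, 5))                 # CoV 0.1: excluded
  ser <- structure(list(series = S, grid = 1:10, dim = c(3, 1, 1)),
                   class = "perf_series")
  expect_identical(cov_mask(ser, 0.15), c(FALSE, TRUE, FALSE))
})

test_that("flash rejection removes values above factor x pre-removal mean", {
  expect_equal(flash_reject(c(1, 1, 1, 10), 3), c(1, 1, 1))  # mean 3.25 -> 9.75
  x <- rep(4.2, 6)
  expect_equal(flash_reject(x, 3), x)
  expect_equal(flash_reject(c(0, 0, 12), 3), c(0, 0, 12))    # 12 == 3 * mean, kept
  expect_error(flash_reject(numeric(0)), "one value")
})
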