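# Small shared fixtures: everything is generated in code at test time.

tiny_phantom <- function(seed = 2L, nz = 5L)
  build_phantom(nx = 32, ny = 32, nz = nz, lesion_frac = 0.15, seed = seed)

tmcao_timeline <- function() build_scenario("paper_tmcao")

# deterministic complex test stack (pixels x frames)
random_stack <- function(P = 50, F = 40, seed = 1L, dim_px = NULL) {
  set.seed(seed)
  X <- matrix(complex(real = rnorm(P * F), imaginary = rnorm(P * F)), P, F)
  dim_px <- dim_px %||% c(P, 1L)
  framestack(X, dim_px = dim_px, frame_rate = 500)
}

# render noiseless Gaussian blobs into a framestack; centers is a list of
# per-frame matrices (n x 2, 0-based px)
blob_stack <- function(centers, nx = 32, ny = 32, sigma = 0.65, amp = 100,
                       frame_rate = 200, pixel_mm = c(0.1, 0.1)) {
  Fn <- length(centers)
  X <- matrix(0i, nx * ny, Fn)
  s2 <- 2 * sigma^2
  for (f in seq_len(Fn)) {
    cc <- centers[[f]]
    if (is.null(cc) || nrow(cc) == 0) next
    img <- matrix(0, nx, ny)
    for (b in seq_len(nrow(cc))) {
      gx <- exp(-((0:(nx - 1)) - cc[b, 1])^2 / s2)
      gy <- exp(-((0:(ny - 1)) - cc[b, 2])^2 / s2)
      img <- img + amp * outer(gx, gy)
    }
    X[, f] <- as.vector(img) + 0i
  }
  framestack(X, dim_px = c(nx, ny), frame_rate = frame_rate,
             pixel_mm = pixel_mm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
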