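#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation: one master seed expands to per-subject,
# per-stage streams via a counter scheme, so adding subjects or stages never
# perturbs existing ones. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(master, subject = 0L, stage = 0L, counter = 0L) {
  master <- as.double(master)
  s <- (master * 2654435.0 + subject * 97561.0 + stage * 1013.0 + counter * 7.0)
  as.integer(s %% 2147483629)
}

# Stage codes used throughout the pipeline drivers.
STAGE <- c(phantom = 1L, uus = 2L, ulm = 3L, dsc = 4L, t2 = 5L, ss = 6L,
           subject = 7L)

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Population (n-denominator) standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# --- small 3-D morphology helpers (6-connectivity), used by lesion segmentation ---

shift_arr <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  sx <- xs - dx; sy <- ys - dy; sz <- zs - dz
  okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]; okz <- sz >= 1 & sz <= d[3]
  out[xs[okx], ys[oky], zs[okz]] <- a[sx[okx], sy[oky], sz[okz]]
  out
}

dilate3 <- function(mask) {
  out <- mask
  for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    out <- out | shift_arr(mask, s[1], s[2], s[3])
  out
}

erode3 <- function(mask) {
  out <- mask
  for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    out <- out & shift_arr(mask, s[1], s[2], s[3])
  out
}

# closing with an in-plane structuring element: slices are thicker than the
# in-plane voxel size, so closing across slices would bridge the lesion caps
dilate2 <- function(mask) {
  out <- mask
  for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0)))
    out <- out | shift_arr(mask, s[1], s[2], s[3])
  out
}

erode2 <- function(mask) {
  out <- mask
  for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0)))
    out <- out & shift_arr(mask, s[1], s[2], s[3])
  out
}

close3 <- function(mask) erode2(dilate2(mask))

# 6-connected component labelling by repeated label propagation (minimum-label
# flooding); adequate for the small masks this package segments.
label_components3 <- function(mask) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    new <- lab
    for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      nb <- array(0, d)
      src <- shift_arr_num(lab, s[1], s[2], s[3])
      upd <- mask & src > 0 & (new == 0 | src < new)
      new[upd] <- src[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # compact label ids
  ids <- sort(unique(lab[lab > 0]))
  out <- array(0L, d)
  out[lab > 0] <- match(lab[lab > 0], ids)
  out
}

shift_arr_num <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(0, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  sx <- xs - dx; sy <- ys - dy; sz <- zs - dz
  okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]; okz <- sz >= 1 & sz <= d[3]
  out[xs[okx], ys[oky], zs[okz]] <- a[sx[okx], sy[oky], sz[okz]]
  out
}

largest_component3 <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- label_components3(mask)
  tab <- tabulate(lab[lab > 0])
  lab == which.max(tab)
}

# Separable smoothing of a 3-D array with a simple box kernel, mirrored edges.
smooth3 <- function(a, w = 2) {
  k <- 2 * w + 1
  sm1 <- function(m) {
    n <- nrow(m)
    idx <- outer(seq_len(n), -w:w, `+`)
    idx[idx < 1] <- 1; idx[idx > n] <- n
    out <- 0
    for (j in seq_len(k)) out <- out + m[idx[, j], , drop = FALSE]
    out / k
  }
  d <- dim(a)
  m <- matrix(a, d[1], d[2] * d[3])
  m <- sm1(m)
  a <- array(m, d)
  a <- aperm(a, c(2, 1, 3))
  m <- matrix(a, d[2], d[1] * d[3])
  m <- sm1(m)
  a <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  if (d[3] > 2) {
    a <- aperm(a, c(3, 2, 1))
    m <- matrix(a, d[3], d[2] * d[1])
    m <- sm1(m)
    a <- aperm(array(m, c(d[3], d[2], d[1])), c(3, 2, 1))
  }
  a
}
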