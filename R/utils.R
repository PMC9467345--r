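# Internal helpers: scoped RNG, mirror padding, bilinear warping.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators are pure functions of (seed, params).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-item 31-bit seed stream from a master seed.
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647
}

# Mirror (symmetric, edge duplicated) padding of a matrix by `r` pixels.
pad_mirror <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc)
    stop("padding radius must be smaller than the image")
  ri <- c(r:1, 1:nr, nr:(nr - r + 1))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1))
  m[ri, ci, drop = FALSE]
}

# Truncated-at-zero normal draws (vectorized rejection; exact for sd = 0).
rtnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

# Sample an image at real-valued (row, col) coordinates with bilinear
# interpolation; coordinates outside [1, n] give NA.
bilinear_sample <- function(m, ri, ci) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(ri))
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  r <- ri[ok]; c <- ci[ok]
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- r0 + (c0 - 1) * nr
  v <- (1 - fr) * (1 - fc) * m[i00] +
    fr * (1 - fc) * m[i00 + 1] +
    (1 - fr) * fc * m[i00 + nr] +
    fr * fc * m[i00 + nr + 1]
  out[ok] <- v
  out
}

# Rigid warp of a matrix. With direction "forward" the content moves by the
# transform t (rotation theta about the grid centre, then translation by
# (dx, dy) in row/col pixels); with direction "inverse" the motion is undone,
# so inverse-warping a forward-warped image recovers the original. Out-of-field
# pixels are NA.
warp_rigid <- function(m, dx, dy, theta_deg, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  nr <- nrow(m); nc <- ncol(m)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  th <- theta_deg * pi / 180
  if (direction == "forward") {
    # out(x) = in(R^{-1}(x - c - d) + c)
    xr <- g$r - cr - dx; xc <- g$c - cc - dy
    sr <- cos(th) * xr + sin(th) * xc + cr
    sc <- -sin(th) * xr + cos(th) * xc + cc
  } else {
    # out(x) = in(R(x - c) + c + d)
    xr <- g$r - cr; xc <- g$c - cc
    sr <- cos(th) * xr - sin(th) * xc + cr + dx
    sc <- sin(th) * xr + cos(th) * xc + cc + dy
  }
  matrix(bilinear_sample(m, sr, sc), nr, nc)
}
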