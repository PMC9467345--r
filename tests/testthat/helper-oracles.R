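# Independent brute-force oracles and small fixture builders. The oracles
# deliberately share no code with the implementation: plain per-pixel loops
# and textbook formulas.

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Naive per-pixel Phansalkar: double loop, explicit mirror indexing.
phansalkar_oracle <- function(x, radius = 15, k = 0.25, r_norm = 0.5,
                              p = 2, q = 10, shape = "disk") {
  nr <- nrow(x); nc <- ncol(x)
  mirror <- function(i, n) {
    # symmetric reflection with edge duplicated: ..3 2 1 | 1 2 3.. n | n n-1..
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- c()
      for (a in -radius:radius) {
        for (b in -radius:radius) {
          if (shape == "disk" && a * a + b * b > radius * radius) next
          vals <- c(vals, x[mirror(i + a, nr), mirror(j + b, nc)])
        }
      }
      m <- mean(vals)
      s <- sqrt(mean(vals^2) - m^2)      # population SD
      thr <- m * (1 + p * exp(-q * m) + k * (s / r_norm - 1))
      out[i, j] <- x[i, j] > thr
    }
  }
  out
}

# Stack-based flood-fill component labeling (independent of the package's
# label-propagation scheme).
floodfill_label_oracle <- function(v, connectivity = 8) {
  nr <- nrow(v); nc <- ncol(v)
  lab <- matrix(0L, nr, nc)
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  nl <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!v[i, j] || lab[i, j] > 0) next
    nl <- nl + 1L
    stack <- list(c(i, j))
    lab[i, j] <- nl
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in seq_len(nrow(offs))) {
        ni <- cur[1] + offs[o, 1]; nj <- cur[2] + offs[o, 2]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
            v[ni, nj] && lab[ni, nj] == 0) {
          lab[ni, nj] <- nl
          stack[[length(stack) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# Pearson chi-square by the direct sum over observed/expected cells.
chisq_oracle <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    stat <- stat + (tab[i, j] - e)^2 / e
  }
  list(chisq = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Recursive partial-correlation formula from the pairwise correlation
# matrix, for one or two covariates.
partial_r_oracle <- function(x, y, z) {
  r1 <- function(a, b, c) {
    (stats::cor(a, b) - stats::cor(a, c) * stats::cor(b, c)) /
      sqrt((1 - stats::cor(a, c)^2) * (1 - stats::cor(b, c)^2))
  }
  if (NCOL(z) == 1) return(r1(x, y, as.numeric(z)))
  z1 <- z[, 1]; z2 <- z[, 2]
  rxy_1 <- r1(x, y, z1); rxz2_1 <- r1(x, z2, z1); ryz2_1 <- r1(y, z2, z1)
  (rxy_1 - rxz2_1 * ryz2_1) / sqrt((1 - rxz2_1^2) * (1 - ryz2_1^2))
}

# Circularly shift a matrix (content moves by +dr rows, +dc cols).
circshift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dr) %% nr) + 1, ((seq_len(nc) - 1 - dc) %% nc) + 1]
}

# A smooth-ish random test image in [0,1] (binned noise, light smoothing).
random_smooth_image <- function(n, seed) {
  set.seed(seed)
  x <- matrix(stats::runif(n * n), n, n)
  k <- matrix(1 / 9, 3, 3)
  xp <- ccflow:::pad_mirror(x, 1)
  out <- matrix(0, n, n)
  for (a in -1:1) for (b in -1:1)
    out <- out + xp[1 + a + seq_len(n), 1 + b + seq_len(n)] / 9
  (out - min(out)) / (max(out) - min(out))
}

# Small scene + speckled SCP frame pair with a known sub-pixel shift: the
# moving frame shares the anatomy but has independent speckle.
shifted_scp_pair <- function(dx, dy, speckle_shape, seed, n = 128) {
  sc <- generate_scene(pixel_count = n, pixel_pitch_um = 10,
                       target_void_fraction = 0.13, mean_void_size_um2 = 790,
                       pachyvessel_fraction = 0, seed = seed)
  base <- ifelse(sc$scp_mask, 0.35, 0.05)
  set.seed(seed + 7919)
  mk <- function(shift_r, shift_c) {
    pad <- ccflow:::pad_mirror(base, 12)
    sp <- matrix(stats::rgamma(length(pad), speckle_shape, speckle_shape),
                 nrow(pad), ncol(pad))
    w <- ccflow:::warp_rigid(pad * sp, shift_r, shift_c, 0, "forward")
    img <- w[12 + seq_len(n), 12 + seq_len(n)]
    img[is.na(img)] <- 0.05
    en_face_image(pmin(img, 1), 10, "octa_scp")
  }
  list(reference = mk(0, 0), moving = mk(dx, dy))
}
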