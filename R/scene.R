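#' Generate a ground-truthed choriocapillaris scene
#'
#' Builds the anatomy underlying one synthetic eye: a capillary meshwork with
#' embedded flow voids, an overlay of large dark choroidal vessels
#' (pachyvessels), and a superficial-capillary-plexus vessel pattern used as
#' the registration reference. The meshwork is seeded by a jittered-grid
#' (blue-noise) lobule tessellation: each lobule centre owns a Voronoi cell,
#' the inter-lobule band of half-width `w` around the cell boundaries is
#' perfused capillary, and the eroded cell interiors are the flow voids. The
#' band half-width is solved by bisection so the realized void area fraction
#' matches `target_void_fraction`; the lobule density is set so the mean void
#' size matches `mean_void_size_um2`.
#'
#' Pachyvessels are smoothed random-walk ribbons entering from the field
#' border with physical widths drawn from `vessel_width_um`; a global width
#' scale is solved by bisection to approach `pachyvessel_fraction`.
#'
#' @param pixel_count Grid side in pixels (square field); at least 64.
#'   Default 300, i.e. a 3 x 3 mm field at 10 um/px.
#' @param pixel_pitch_um Micrometres per pixel (default 10).
#' @param target_void_fraction Intended flow-void area fraction, in (0, 1).
#' @param mean_void_size_um2 Intended mean void size in um^2; must be at
#'   least one pixel's area.
#' @param pachyvessel_fraction Intended pachyvessel area fraction in
#'   \[0, 0.5\]; 0 gives an empty vessel layer.
#' @param vessel_width_um Range of ribbon widths in um (default 150-400).
#' @param seed RNG seed; the scene is a deterministic function of the seed
#'   and parameters.
#' @return An object of class `scene_truth` with logical matrices
#'   `capillary_mask`, `void_mask` (its exact complement),
#'   `pachyvessel_mask`, `scp_mask`, plus `pixel_pitch_um` and `field_mm`.
#' @export
generate_scene <- function(pixel_count = 300, pixel_pitch_um = 10,
                           target_void_fraction = 0.13,
                           mean_void_size_um2 = 790,
                           pachyvessel_fraction = 0.2,
                           vessel_width_um = c(150, 400),
                           seed = 1) {
  if (pixel_count < 64) stop("`pixel_count` must be >= 64")
  if (!(target_void_fraction > 0 && target_void_fraction < 1))
    stop("`target_void_fraction` must lie strictly in (0, 1)")
  if (mean_void_size_um2 < pixel_pitch_um^2)
    stop("`mean_void_size_um2` is smaller than one pixel's area")
  if (pachyvessel_fraction < 0 || pachyvessel_fraction > 0.5)
    stop("`pachyvessel_fraction` must lie in [0, 0.5]")
  with_seed(seed, {
    np <- as.integer(pixel_count)
    vm <- lobule_void_mask(np, pixel_pitch_um, target_void_fraction,
                           mean_void_size_um2)
    pv <- if (pachyvessel_fraction > 0)
      ribbon_mask(np, pixel_pitch_um, pachyvessel_fraction, vessel_width_um)
    else matrix(FALSE, np, np)
    scp <- scp_vessel_mask(np, pixel_pitch_um)
    structure(list(capillary_mask = !vm,
                   void_mask = vm,
                   pachyvessel_mask = pv,
                   scp_mask = scp,
                   pixel_pitch_um = as.numeric(pixel_pitch_um),
                   field_mm = np * pixel_pitch_um / 1000),
              class = "scene_truth")
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf(paste0("<scene_truth> %d x %d px (%.2f mm, %.3g um/px)\n",
                     "  void fraction %.3f, pachyvessel fraction %.3f\n"),
              nrow(x$void_mask), ncol(x$void_mask), x$field_mm,
              x$pixel_pitch_um, mean(x$void_mask), mean(x$pachyvessel_mask)))
  invisible(x)
}

# Jittered-grid Voronoi lobules; voids are cell interiors deeper than `w`
# (in the d2 - d1 boundary-margin metric), solved by bisection on `w`. Small
# cells vanish under the margin threshold, so the realized mean void size
# exceeds the naive seed-density prediction; a couple of fixed-point
# iterations on the seed count correct for it.
lobule_void_mask <- function(np, pitch, target_frac, mean_size_um2) {
  field_um2 <- (np * pitch)^2
  n_seeds <- max(4, round(field_um2 * target_frac / mean_size_um2))
  n_seeds <- min(n_seeds, floor(np^2 / 8))
  for (iter in 1:3) {
    vm <- lobule_void_mask_once(np, n_seeds, target_frac)
    n_comp <- max(label_components(vm, 8))
    ratio <- if (n_comp == 0) 2 else {
      realized_size <- sum(vm) * pitch^2 / n_comp
      if (abs(realized_size / mean_size_um2 - 1) < 0.08) break
      realized_size / mean_size_um2
    }
    n_seeds <- min(max(4, round(n_seeds * min(max(ratio, 0.25), 4))),
                   floor(np^2 / 8))
  }
  vm
}

lobule_void_mask_once <- function(np, n_seeds, target_frac) {
  g <- max(2, round(sqrt(n_seeds)))
  spacing <- np / g
  jit <- 0.45 * spacing
  sx <- outer((seq_len(g) - 0.5) * spacing, rep(1, g)) +
    matrix(stats::runif(g * g, -jit, jit), g, g)
  sy <- outer(rep(1, g), (seq_len(g) - 0.5) * spacing) +
    matrix(stats::runif(g * g, -jit, jit), g, g)

  px <- matrix(seq_len(np), np, np)
  py <- matrix(seq_len(np), np, np, byrow = TRUE)
  ci <- pmin(pmax(ceiling(px / spacing), 1L), g)
  cj <- pmin(pmax(ceiling(py / spacing), 1L), g)
  d1 <- matrix(Inf, np, np)
  d2 <- matrix(Inf, np, np)
  for (a in -2:2) for (b in -2:2) {
    gi <- ci + a; gj <- cj + b
    ok <- gi >= 1 & gi <= g & gj >= 1 & gj <= g
    idx <- (pmin(pmax(gj, 1L), g) - 1L) * g + pmin(pmax(gi, 1L), g)
    dd <- (px - sx[idx])^2 + (py - sy[idx])^2
    dd[!ok] <- Inf
    closer <- dd < d1
    d2 <- pmin(d2, ifelse(closer, d1, dd))
    d1 <- pmin(d1, dd)
  }
  margin <- sqrt(d2) - sqrt(d1)  # 0 on Voronoi boundaries, largest at centres

  lo <- 0; hi <- 2 * spacing
  for (i in 1:48) {
    w <- (lo + hi) / 2
    frac <- mean(margin >= w)
    if (frac > target_frac) lo <- w else hi <- w
  }
  margin >= (lo + hi) / 2
}

# Smoothed random-walk ribbons entering from the border; global width scale
# solved by bisection toward the target area fraction.
ribbon_mask <- function(np, pitch, target_frac, width_um) {
  mean_w_px <- mean(width_um) / pitch
  exp_area_one <- 1.2 * np * mean_w_px            # rough ribbon footprint
  n_rib <- min(5L, max(2L, round(target_frac * np^2 / exp_area_one)))
  paths <- vector("list", n_rib)
  base_r <- numeric(n_rib)
  for (k in seq_len(n_rib)) {
    side <- sample.int(4L, 1L)
    pos <- stats::runif(1, 0.15, 0.85) * np
    start <- switch(side, c(1, pos), c(np, pos), c(pos, 1), c(pos, np))
    heading <- switch(side, 0, pi, pi / 2, -pi / 2) +
      stats::runif(1, -0.5, 0.5)
    n_steps <- 3L * np
    turn <- stats::rnorm(n_steps, 0, 0.05)
    h <- heading + cumsum(turn)
    xs <- start[1] + cumsum(cos(h))
    ys <- start[2] + cumsum(sin(h))
    inside <- xs >= -mean_w_px & xs <= np + mean_w_px &
      ys >= -mean_w_px & ys <= np + mean_w_px
    stop_at <- if (all(inside)) n_steps else max(which(cumsum(!inside) == 0), 1L)
    paths[[k]] <- cbind(xs[seq_len(stop_at)], ys[seq_len(stop_at)])
    base_r[k] <- stats::runif(1, width_um[1], width_um[2]) / 2 / pitch
  }
  stamp <- function(scale) {
    m <- matrix(FALSE, np, np)
    for (k in seq_len(n_rib)) {
      r <- base_r[k] * scale
      ir <- ceiling(r)
      off <- expand.grid(a = -ir:ir, b = -ir:ir)
      off <- off[off$a^2 + off$b^2 <= r^2, , drop = FALSE]
      p <- paths[[k]]
      keep <- seq(1, nrow(p), by = max(1, floor(r / 2)))
      for (i in keep) {
        xi <- round(p[i, 1]) + off$a
        yi <- round(p[i, 2]) + off$b
        ok <- xi >= 1 & xi <= np & yi >= 1 & yi <= np
        m[cbind(xi[ok], yi[ok])] <- TRUE
      }
    }
    m
  }
  lo <- 0.3; hi <- 3
  for (i in 1:18) {
    s <- (lo + hi) / 2
    if (mean(stamp(s)) < target_frac) lo <- s else hi <- s
  }
  stamp((lo + hi) / 2)
}

# Superficial-capillary-plexus reference pattern: a handful of thin,
# high-contrast vessel arcs crossing the field (registration landmarks).
scp_vessel_mask <- function(np, pitch) {
  m <- matrix(FALSE, np, np)
  n_ves <- 10L
  for (k in seq_len(n_ves)) {
    side <- sample.int(4L, 1L)
    pos <- stats::runif(1, 0.05, 0.95) * np
    start <- switch(side, c(1, pos), c(np, pos), c(pos, 1), c(pos, np))
    heading <- switch(side, 0, pi, pi / 2, -pi / 2) +
      stats::runif(1, -0.7, 0.7)
    n_steps <- 2L * np
    h <- heading + cumsum(stats::rnorm(n_steps, 0, 0.03))
    xs <- pmin(pmax(start[1] + cumsum(cos(h)), -5), np + 5)
    ys <- pmin(pmax(start[2] + cumsum(sin(h)), -5), np + 5)
    r <- stats::runif(1, 30, 80) / 2 / pitch   # 30-80 um calibre
    ir <- max(1L, ceiling(r))
    off <- expand.grid(a = -ir:ir, b = -ir:ir)
    off <- off[off$a^2 + off$b^2 <= max(r, 1)^2, , drop = FALSE]
    for (i in seq(1, n_steps, by = 2)) {
      xi <- round(xs[i]) + off$a
      yi <- round(ys[i]) + off$b
      ok <- xi >= 1 & xi <= np & yi >= 1 & yi <= np
      m[cbind(xi[ok], yi[ok])] <- TRUE
    }
  }
  m
}
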