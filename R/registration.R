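#' Estimate the rigid transform aligning one frame to a reference
#'
#' Registration is performed on superficial-capillary-plexus frames, whose
#' high-contrast vessels make reliable landmarks; the estimated transform is
#' then re-applied to the paired choriocapillaris frames. Translation is
#' estimated by phase correlation with sub-pixel refinement (local upsampled
#' discrete Fourier transform of the cross-power spectrum); rotation, when
#' `rotation_range_deg > 0`, by a coarse grid plus golden-section search over
#' the rotation that maximizes the correlation peak. The returned quality is
#' the peak normalized correlation between the reference and the aligned
#' moving frame.
#'
#' @param reference,moving `en_face_image`s of identical shape and pitch.
#' @param rotation_range_deg Half-width of the rotation search in degrees;
#'   0 (translation only) skips the search. Default 2.
#' @param upsample Sub-pixel refinement factor (default 20, i.e. 0.05 px
#'   resolution).
#' @return A `frame_transform` `t` such that `apply_transform(moving, t)`
#'   aligns `moving` onto `reference`; `dx_px`/`dy_px` are the content
#'   displacement of `moving` relative to `reference`.
#' @export
estimate_transform <- function(reference, moving, rotation_range_deg = 2,
                               upsample = 20) {
  stopifnot(inherits(reference, "en_face_image"),
            inherits(moving, "en_face_image"))
  if (!identical(dim(reference$intensities), dim(moving$intensities)))
    stop("reference and moving images must share the same shape")
  if (reference$pixel_pitch_um != moving$pixel_pitch_um)
    stop("reference and moving images must share the same pixel pitch")
  ref <- reference$intensities
  mov <- moving$intensities
  ref[is.na(ref)] <- mean(ref, na.rm = TRUE)
  mov[is.na(mov)] <- mean(mov, na.rm = TRUE)
  if (stats::sd(ref) == 0 || stats::sd(mov) == 0)
    stop("degenerate input: constant image, correlation undefined")

  eval_theta <- function(th, us = 1) {
    m <- if (th == 0) mov else {
      w <- warp_rigid(mov, 0, 0, th, "inverse")  # undo rotation by th
      w[is.na(w)] <- mean(mov)
      w
    }
    pc <- phase_correlate(ref, m, us)
    list(theta = th, peak = pc$peak, shift = pc$shift)
  }

  best <- eval_theta(0)
  if (rotation_range_deg > 0) {
    for (th in setdiff(seq(-rotation_range_deg, rotation_range_deg,
                           length.out = 9), 0)) {
      cand <- eval_theta(th)
      if (cand$peak > best$peak) best <- cand
    }
    # golden-section refinement around the best grid point
    step <- rotation_range_deg / 4
    a <- best$theta - step; b <- best$theta + step
    phi <- (sqrt(5) - 1) / 2
    x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
    f1 <- eval_theta(x1); f2 <- eval_theta(x2)
    for (i in 1:12) {
      if (f1$peak > f2$peak) {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - phi * (b - a); f1 <- eval_theta(x1)
      } else {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + phi * (b - a); f2 <- eval_theta(x2)
      }
    }
    cand <- if (f1$peak > f2$peak) f1 else f2
    if (cand$peak > best$peak) best <- cand
  }
  # sub-pixel refinement of the translation at the selected rotation
  best <- eval_theta(best$theta, upsample)

  th <- best$theta
  # the phase-correlation shift was measured after undoing the rotation, i.e.
  # in the rotated frame; map it back: d = R(theta) s'
  s <- best$shift
  rad <- th * pi / 180
  dx <- cos(rad) * s[1] - sin(rad) * s[2]
  dy <- sin(rad) * s[1] + cos(rad) * s[2]

  t0 <- frame_transform(dx, dy, th, 1)
  aligned <- warp_rigid(mov, dx, dy, th, "inverse")
  ok <- !is.na(aligned)
  q <- suppressWarnings(stats::cor(aligned[ok], ref[ok]))
  if (!is.finite(q)) q <- 0
  frame_transform(dx, dy, th, min(max(q, 0), 1))
}

# Phase correlation of two equal-shape matrices. Returns the content
# displacement of `mov` relative to `ref` (so that shifting mov back by
# -shift aligns it), refined to 1/upsample pixel by a local upsampled DFT of
# the cross-power spectrum.
phase_correlate <- function(ref, mov, upsample = 20) {
  nr <- nrow(ref); nc <- ncol(ref)
  Fr <- stats::fft(ref); Fm <- stats::fft(mov)
  R <- Fr * Conj(Fm)
  mag <- Mod(R)
  R <- R / pmax(mag, 1e-12)
  cc <- Re(stats::fft(R, inverse = TRUE)) / (nr * nc)
  pk <- which.max(cc)
  pr <- (pk - 1) %% nr
  pc <- (pk - 1) %/% nr
  # peak at x* = -shift mod N
  sr <- -ifelse(pr > nr / 2, pr - nr, pr)
  sc <- -ifelse(pc > nc / 2, pc - nc, pc)
  if (upsample > 1) {
    win <- 1.5
    us <- dft_upsample(R, -sr, -sc, win, upsample)
    i <- which.max(us$cc)
    sr <- -(us$r[(i - 1) %% length(us$r) + 1])
    sc <- -(us$c[(i - 1) %/% length(us$r) + 1])
    peak <- us$cc[i] / (nr * nc)
  } else {
    peak <- cc[pk]
  }
  list(shift = c(sr, sc), peak = peak)
}

# Evaluate the inverse DFT of spectrum R on an upsampled local grid centred
# at (r0, c0) with half-width `win` pixels and step 1/usfac.
dft_upsample <- function(R, r0, c0, win, usfac) {
  nr <- nrow(R); nc <- ncol(R)
  kr <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1))
  kc <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1))
  rg <- seq(r0 - win, r0 + win, by = 1 / usfac)
  cg <- seq(c0 - win, c0 + win, by = 1 / usfac)
  Er <- exp(2i * pi * outer(rg, kr) / nr)          # length(rg) x nr
  Ec <- exp(2i * pi * outer(kc, cg) / nc)          # nc x length(cg)
  cc <- Re(Er %*% R %*% Ec)
  list(cc = cc, r = rg, c = cg)
}

#' Resample an image under the inverse of a rigid transform
#'
#' Undoes the motion described by `t`: the image is resampled with bilinear
#' interpolation so that a frame displaced by `t` relative to the reference
#' grid is brought back onto it. Pixels that fall outside the source field
#' are flagged invalid (NA) and are excluded from averaging.
#'
#' @param image An `en_face_image`.
#' @param t A `frame_transform`.
#' @return An `en_face_image` on the same grid, with NAs marking
#'   out-of-field pixels.
#' @export
apply_transform <- function(image, t) {
  stopifnot(inherits(image, "en_face_image"), inherits(t, "frame_transform"))
  if (t$dx_px == 0 && t$dy_px == 0 && t$theta_deg == 0) return(image)
  out <- warp_rigid(image$intensities, t$dx_px, t$dy_px, t$theta_deg, "inverse")
  en_face_image(out, image$pixel_pitch_um, image$modality)
}

#' Average a registered frame stack
#'
#' Warps each frame into the reference grid under the inverse of its
#' transform and takes the pixelwise arithmetic mean over the frames whose
#' quality passes `min_quality`, counting only valid (in-field) pixels at
#' each position. Averaging repeated captures of a static scene suppresses
#' multiplicative speckle roughly as 1/N in variance, which is what makes the
#' choriocapillaris meshwork quantifiable.
#'
#' @param frames List of `en_face_image`s on a common grid.
#' @param transforms List of `frame_transform`s, one per frame.
#' @param min_quality Frames with `quality < min_quality` are excluded
#'   (default 0.5).
#' @return An `en_face_image`; attribute `n_retained` reports how many
#'   frames passed the gate.
#' @export
average_stack <- function(frames, transforms, min_quality = 0.5) {
  if (length(frames) != length(transforms))
    stop("`frames` and `transforms` must have the same length")
  keep <- vapply(transforms, function(t) t$quality >= min_quality, logical(1))
  if (!any(keep))
    stop("no frame passes the quality gate (min_quality = ", min_quality, ")")
  frames <- frames[keep]
  transforms <- transforms[keep]
  d <- dim(frames[[1]]$intensities)
  acc <- matrix(0, d[1], d[2])
  cnt <- matrix(0L, d[1], d[2])
  for (i in seq_along(frames)) {
    w <- apply_transform(frames[[i]], transforms[[i]])$intensities
    ok <- !is.na(w)
    acc[ok] <- acc[ok] + w[ok]
    cnt <- cnt + ok
  }
  out <- matrix(NA_real_, d[1], d[2])
  nz <- cnt > 0
  out[nz] <- acc[nz] / cnt[nz]
  out[nz] <- pmin(pmax(out[nz], 0), 1)
  res <- en_face_image(out, frames[[1]]$pixel_pitch_um, frames[[1]]$modality)
  attr(res, "n_retained") <- sum(keep)
  res
}
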