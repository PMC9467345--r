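#' Parameters of the Phansalkar local adaptive threshold
#'
#' The Phansalkar threshold for a pixel with local window mean `m` and window
#' standard deviation `s` (population SD over the neighborhood) is
#' \deqn{T = m (1 + p e^{-q m} + k (s / r - 1))}
#' on intensities normalized to \[0, 1\]. The `p e^{-q m}` term raises the
#' threshold in dark regions, which is what makes the method suitable for
#' selecting dark objects (flow voids, vessel lumens) in low-contrast images.
#' The defaults (radius 15 px, k = 0.25, r = 0.5, p = 2, q = 10, circular
#' window) are the conventional auto-local-threshold settings.
#'
#' @param radius_px Neighborhood radius in pixels, >= 1 (default 15).
#' @param k Weight of the SD term (default 0.25).
#' @param r Dynamic-range normalizer for the SD, > 0 (default 0.5).
#' @param p,q Dark-region boost coefficients (defaults 2 and 10).
#' @param neighborhood_shape `"disk"` (default) or `"square"`.
#' @return An object of class `phansalkar_params`.
#' @export
phansalkar_params <- function(radius_px = 15, k = 0.25, r = 0.5,
                              p = 2, q = 10,
                              neighborhood_shape = c("disk", "square")) {
  neighborhood_shape <- match.arg(neighborhood_shape)
  if (radius_px < 1) stop("`radius_px` must be >= 1")
  if (r <= 0) stop("`r` must be > 0")
  structure(list(radius_px = as.integer(radius_px), k = k, r = r, p = p,
                 q = q, neighborhood_shape = neighborhood_shape),
            class = "phansalkar_params")
}

#' Phansalkar local adaptive thresholding
#'
#' Binarizes an en face image: for every pixel the mean `m` and population SD
#' `s` of the intensities in the surrounding neighborhood (disk or square of
#' radius `radius_px`, mirror-padded at the borders) are computed, and the
#' pixel is foreground (bright signal) iff its value strictly exceeds
#' \eqn{T = m (1 + p e^{-q m} + k (s/r - 1))}. Local statistics are computed
#' by FFT convolution, which is exact up to floating-point rounding.
#'
#' The same operation serves both pipeline rasters: the averaged
#' choriocapillaris OCTA image (foreground = perfused signal; invert to get
#' flow voids) and the choroidal en face OCT image (foreground = bright
#' stroma; invert to get pachyvessel lumens).
#'
#' @param image An `en_face_image` with no invalid pixels.
#' @param params A `phansalkar_params`.
#' @return A `binary_mask` with `foreground_meaning = "bright_signal"`; the
#'   per-pixel threshold map is attached as attribute `"threshold"`.
#' @export
phansalkar_threshold <- function(image, params = phansalkar_params()) {
  stopifnot(inherits(image, "en_face_image"))
  if (!inherits(params, "phansalkar_params"))
    stop("`params` must be a phansalkar_params object")
  x <- image$intensities
  if (anyNA(x))
    stop("image contains invalid (NA) pixels; fill or crop before thresholding")
  r <- params$radius_px
  if (2 * r >= min(dim(x)))
    stop("neighborhood radius is larger than half the image")

  pad <- pad_mirror(x, r)
  off <- expand.grid(a = -r:r, b = -r:r)
  if (params$neighborhood_shape == "disk")
    off <- off[off$a^2 + off$b^2 <= r^2, , drop = FALSE]
  P <- nrow(pad); Q <- ncol(pad)
  kern <- matrix(0, P, Q)
  kern[cbind(off$a %% P + 1, off$b %% Q + 1)] <- 1
  area <- nrow(off)
  Fk <- stats::fft(kern)
  conv <- function(a) Re(stats::fft(stats::fft(a) * Fk, inverse = TRUE)) / (P * Q)
  s1 <- conv(pad)
  s2 <- conv(pad^2)
  core <- r + seq_len(nrow(x))
  corec <- r + seq_len(ncol(x))
  m <- s1[core, corec] / area
  v <- pmax(s2[core, corec] / area - m^2, 0)
  s <- sqrt(v)
  thr <- m * (1 + params$p * exp(-params$q * m) +
                params$k * (s / params$r - 1))
  out <- binary_mask(x > thr, image$pixel_pitch_um, "bright_signal")
  attr(out, "threshold") <- thr
  out
}

#' Invert a binary mask
#'
#' Logical complement with an explicit re-statement of what the new
#' foreground means: inverting the bright-signal mask of a choriocapillaris
#' image yields the flow voids; inverting the bright-stroma mask of a
#' choroidal OCT image yields the pachyvessel lumens.
#'
#' @param mask A `binary_mask`.
#' @param new_meaning Foreground meaning of the inverted mask.
#' @return A `binary_mask`.
#' @export
invert_mask <- function(mask, new_meaning = c("flow_void", "pachyvessel",
                                              "bright_signal")) {
  stopifnot(inherits(mask, "binary_mask"))
  new_meaning <- match.arg(new_meaning)
  binary_mask(!mask$values, mask$pixel_pitch_um, new_meaning)
}
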