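#' En face image container
#'
#' The universal raster currency of the package: a 2-D grid of intensities in
#' \[0, 1\] with a physical pixel pitch and a modality tag. En face images are
#' frontal-plane projections of a depth slab extracted from an OCT or OCTA
#' volume; the three modalities handled here are the choriocapillaris OCTA
#' slab (`"octa_cc"`), the superficial-capillary-plexus OCTA slab
#' (`"octa_scp"`, used as the registration reference because of its
#' high-contrast vessels), and the choroidal en face OCT slab
#' (`"oct_choroid"`, where large-vessel lumens are dark).
#'
#' @param intensities Numeric matrix with values in \[0, 1\] (NAs mark invalid
#'   pixels, e.g. out-of-field after warping).
#' @param pixel_pitch_um Physical size of one pixel in micrometres; must be
#'   positive.
#' @param modality One of `"octa_cc"`, `"octa_scp"`, `"oct_choroid"`.
#' @return An object of class `en_face_image`.
#' @export
en_face_image <- function(intensities, pixel_pitch_um,
                          modality = c("octa_cc", "octa_scp", "oct_choroid")) {
  modality <- match.arg(modality)
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix")
  rng <- range(intensities, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("intensities must lie in [0, 1]; normalize the image first")
  if (!is.numeric(pixel_pitch_um) || length(pixel_pitch_um) != 1 ||
      !is.finite(pixel_pitch_um) || pixel_pitch_um <= 0)
    stop("`pixel_pitch_um` must be a single positive number")
  structure(list(intensities = intensities,
                 pixel_pitch_um = as.numeric(pixel_pitch_um),
                 modality = modality),
            class = "en_face_image")
}

#' @export
print.en_face_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<en_face_image> %d x %d px, %.3g um/px, modality %s\n",
              d[1], d[2], x$pixel_pitch_um, x$modality))
  cat(sprintf("  field: %.2f x %.2f mm, intensity range [%.3f, %.3f]%s\n",
              d[1] * x$pixel_pitch_um / 1000, d[2] * x$pixel_pitch_um / 1000,
              min(x$intensities, na.rm = TRUE),
              max(x$intensities, na.rm = TRUE),
              if (anyNA(x$intensities)) sprintf(", %d invalid px",
                                                sum(is.na(x$intensities)))
              else ""))
  invisible(x)
}

#' Binary mask container
#'
#' A boolean grid sharing the pixel pitch of its source image. The meaning of
#' the foreground (`TRUE`) pixels is stated explicitly because the same
#' thresholding operation serves opposite semantics in the pipeline: bright
#' perfused signal before inversion, flow voids or pachyvessel lumens after.
#'
#' @param values Logical matrix.
#' @param pixel_pitch_um Micrometres per pixel, positive.
#' @param foreground_meaning One of `"bright_signal"`, `"flow_void"`,
#'   `"pachyvessel"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, pixel_pitch_um,
                        foreground_meaning = c("bright_signal", "flow_void",
                                               "pachyvessel")) {
  foreground_meaning <- match.arg(foreground_meaning)
  if (!is.matrix(values) || !is.logical(values) || anyNA(values))
    stop("`values` must be a logical matrix without NAs")
  if (!is.numeric(pixel_pitch_um) || length(pixel_pitch_um) != 1 ||
      !is.finite(pixel_pitch_um) || pixel_pitch_um <= 0)
    stop("`pixel_pitch_um` must be a single positive number")
  structure(list(values = values,
                 pixel_pitch_um = as.numeric(pixel_pitch_um),
                 foreground_meaning = foreground_meaning),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<binary_mask> %d x %d px, %.3g um/px, foreground = %s (%.1f%%)\n",
              d[1], d[2], x$pixel_pitch_um, x$foreground_meaning,
              100 * mean(x$values)))
  invisible(x)
}

#' Rigid frame transform
#'
#' A per-frame rigid alignment: translation in pixels plus a rotation about
#' the field centre, with a quality score in \[0, 1\]. The quality slot is the
#' software analogue of the device's per-capture signal-strength score and is
#' used to gate frames out of the average.
#'
#' @param dx_px,dy_px Translation along rows / columns, in pixels.
#' @param theta_deg Rotation about the field centre in degrees; must satisfy
#'   `abs(theta_deg) < 90`.
#' @param quality Frame quality in \[0, 1\] (peak normalized correlation after
#'   alignment when estimated).
#' @return An object of class `frame_transform`.
#' @export
frame_transform <- function(dx_px = 0, dy_px = 0, theta_deg = 0, quality = 1) {
  vals <- c(dx_px, dy_px, theta_deg, quality)
  if (!all(is.finite(vals)))
    stop("transform parameters must be finite")
  if (abs(theta_deg) >= 90)
    stop("|theta_deg| must be < 90")
  if (quality < 0 || quality > 1)
    stop("`quality` must lie in [0, 1]")
  structure(list(dx_px = as.numeric(dx_px), dy_px = as.numeric(dy_px),
                 theta_deg = as.numeric(theta_deg),
                 quality = as.numeric(quality)),
            class = "frame_transform")
}

#' @export
print.frame_transform <- function(x, ...) {
  cat(sprintf("<frame_transform> dx=%.3f dy=%.3f px, theta=%.3f deg, q=%.3f\n",
              x$dx_px, x$dy_px, x$theta_deg, x$quality))
  invisible(x)
}

#' Rescale a raw intensity matrix into [0, 1]
#'
#' Divides by the stated white level and clamps; used when ingesting 8/16-bit
#' integer rasters.
#'
#' @param x Numeric matrix.
#' @param white Intensity mapped to 1 (default the observed maximum).
#' @return Numeric matrix in \[0, 1\].
#' @export
normalize_intensities <- function(x, white = max(x, na.rm = TRUE)) {
  if (white <= 0) return(x * 0)
  pmin(pmax(x / white, 0), 1)
}
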