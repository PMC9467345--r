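#' Acquisition parameters for synthetic OCTA frame stacks
#'
#' Describes the repeated-capture process: number of frames, multiplicative
#' speckle law, rigid inter-frame jitter, and the per-frame device quality
#' score analogue. Speckle is gamma-distributed with mean 1 and shape
#' `speckle_shape`; larger shapes mean less noise (speckle contrast is
#' `1/sqrt(speckle_shape)`). The default shape reflects en face slab images
#' after the device's axial compounding within the thin slab, which leaves
#' considerably less than fully developed speckle.
#'
#' @param n_frames Number of repeated captures (default 9).
#' @param speckle_shape Gamma shape of the multiplicative speckle, > 0
#'   (default 12).
#' @param shift_sd_px SD of the per-frame translation in pixels (default 2).
#' @param rotation_sd_deg SD of the per-frame rotation in degrees
#'   (default 0.3).
#' @param signal_strength_range Interval the per-frame quality score is drawn
#'   from, within \[0, 1\] (default c(0.8, 1)).
#' @param cc_level,void_level Mean reflectance of perfused capillary and
#'   flow-void pixels on the choriocapillaris slab (defaults 0.55 / 0.20;
#'   flow voids on OCTA are dark gray rather than black because the noise
#'   floor and multiple scattering leave residual signal in no-flow
#'   regions).
#' @param scp_level,scp_bg_level Mean reflectance of vessel and background
#'   pixels on the superficial-plexus slab (defaults 0.55 / 0.06).
#' @param seed RNG seed.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(n_frames = 9, speckle_shape = 12,
                               shift_sd_px = 2, rotation_sd_deg = 0.3,
                               signal_strength_range = c(0.8, 1),
                               cc_level = 0.55, void_level = 0.20,
                               scp_level = 0.55, scp_bg_level = 0.06,
                               seed = 1) {
  if (n_frames < 1) stop("`n_frames` must be >= 1")
  if (speckle_shape <= 0) stop("`speckle_shape` must be > 0")
  if (shift_sd_px < 0) stop("`shift_sd_px` must be >= 0")
  if (rotation_sd_deg < 0) stop("`rotation_sd_deg` must be >= 0")
  if (length(signal_strength_range) != 2 ||
      signal_strength_range[1] > signal_strength_range[2] ||
      signal_strength_range[1] < 0 || signal_strength_range[2] > 1)
    stop("`signal_strength_range` must be an increasing interval within [0, 1]")
  structure(list(n_frames = as.integer(n_frames),
                 speckle_shape = speckle_shape,
                 shift_sd_px = shift_sd_px,
                 rotation_sd_deg = rotation_sd_deg,
                 signal_strength_range = signal_strength_range,
                 cc_level = cc_level, void_level = void_level,
                 scp_level = scp_level, scp_bg_level = scp_bg_level,
                 seed = seed),
            class = "acquisition_params")
}

#' Render a stack of paired OCTA frames from a scene
#'
#' Emulates repeated 3 x 3 mm captures of one eye: each frame is the base
#' reflectance implied by the scene masks, multiplied by i.i.d. gamma speckle
#' (mean 1, shape `params$speckle_shape`), then rigidly displaced by a
#' per-frame random transform. The superficial-plexus reference frame of each
#' pair shares the *identical* transform as its choriocapillaris frame (the
#' property registration exploits, since alignment is estimated on the
#' high-contrast plexus and re-applied to the choriocapillaris). The true
#' transforms and the per-frame quality scores are returned as ground truth.
#'
#' Frames are rendered on an enlarged canvas and cropped so rigid jitter does
#' not introduce blank borders; intensities are clamped to \[0, 1\].
#'
#' @param truth A `scene_truth`.
#' @param params An `acquisition_params`.
#' @return An object of class `octa_stack`: lists `cc` and `scp` of
#'   `en_face_image` frames, a list `transforms` of the true
#'   `frame_transform`s (with drawn quality scores), and `pixel_pitch_um`.
#' @export
render_octa_stack <- function(truth, params = acquisition_params()) {
  stopifnot(inherits(truth, "scene_truth"), inherits(params, "acquisition_params"))
  with_seed(params$seed, {
    np <- nrow(truth$void_mask)
    margin <- ceiling(4 * params$shift_sd_px +
                        np * sin(4 * params$rotation_sd_deg * pi / 180) / 1.4 + 4)
    margin <- min(margin, np - 1)
    base_cc <- ifelse(truth$capillary_mask, params$cc_level, params$void_level)
    base_scp <- ifelse(truth$scp_mask, params$scp_level, params$scp_bg_level)
    pad_cc <- pad_mirror(base_cc, margin)
    pad_scp <- pad_mirror(base_scp, margin)
    keep <- margin + seq_len(np)

    cc <- vector("list", params$n_frames)
    scp <- vector("list", params$n_frames)
    tr <- vector("list", params$n_frames)
    for (i in seq_len(params$n_frames)) {
      dx <- stats::rnorm(1, 0, params$shift_sd_px)
      dy <- stats::rnorm(1, 0, params$shift_sd_px)
      th <- stats::rnorm(1, 0, params$rotation_sd_deg)
      q <- stats::runif(1, params$signal_strength_range[1],
                        params$signal_strength_range[2])
      sp_cc <- matrix(stats::rgamma(length(pad_cc), shape = params$speckle_shape,
                                    rate = params$speckle_shape),
                      nrow(pad_cc), ncol(pad_cc))
      sp_scp <- matrix(stats::rgamma(length(pad_scp), shape = params$speckle_shape,
                                     rate = params$speckle_shape),
                       nrow(pad_scp), ncol(pad_scp))
      f_cc <- warp_rigid(pad_cc * sp_cc, dx, dy, th, "forward")[keep, keep]
      f_scp <- warp_rigid(pad_scp * sp_scp, dx, dy, th, "forward")[keep, keep]
      f_cc[is.na(f_cc)] <- params$void_level
      f_scp[is.na(f_scp)] <- params$scp_bg_level
      cc[[i]] <- en_face_image(pmin(f_cc, 1), truth$pixel_pitch_um, "octa_cc")
      scp[[i]] <- en_face_image(pmin(f_scp, 1), truth$pixel_pitch_um, "octa_scp")
      tr[[i]] <- frame_transform(dx, dy, th, q)
    }
    structure(list(cc = cc, scp = scp, transforms = tr,
                   pixel_pitch_um = truth$pixel_pitch_um),
              class = "octa_stack")
  })
}

#' @export
print.octa_stack <- function(x, ...) {
  cat(sprintf("<octa_stack> %d frame pairs, %d x %d px, %.3g um/px\n",
              length(x$cc), nrow(x$cc[[1]]$intensities),
              ncol(x$cc[[1]]$intensities), x$pixel_pitch_um))
  invisible(x)
}

#' Render a choroidal en face OCT image from a scene
#'
#' Large choroidal vessel lumens appear dark on en face OCT; the stroma is
#' bright. The rendered image is two-level (`dark_level` inside the
#' pachyvessel mask, `bright_level` elsewhere) plus additive Gaussian noise,
#' clamped to \[0, 1\].
#'
#' @param truth A `scene_truth`.
#' @param noise_sd Additive noise SD (default 0.05); 0 gives an exactly
#'   two-level image.
#' @param bright_level,dark_level Stroma and lumen reflectance (defaults
#'   0.8 / 0.1; large venous lumens are strongly hyporeflective on en face
#'   OCT).
#' @param seed RNG seed.
#' @return An `en_face_image` with modality `"oct_choroid"`.
#' @export
render_choroid_oct <- function(truth, noise_sd = 0.05, bright_level = 0.8,
                               dark_level = 0.1, seed = 1) {
  stopifnot(inherits(truth, "scene_truth"))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  with_seed(seed, {
    img <- ifelse(truth$pachyvessel_mask, dark_level, bright_level)
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                          nrow(img), ncol(img))
    en_face_image(pmin(pmax(img, 0), 1), truth$pixel_pitch_um, "oct_choroid")
  })
}
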