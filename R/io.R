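#' Write / read an OCTA frame stack as multi-page TIFF plus JSON sidecar
#'
#' The choriocapillaris frames and their paired superficial-plexus reference
#' frames are stored as two multi-page 16-bit grayscale TIFFs; the sidecar
#' JSON holds the true per-frame transforms, quality scores, pixel pitch and
#' modalities, so a stack round-trips losslessly up to 16-bit quantization.
#'
#' @param stack An `octa_stack`.
#' @param prefix Path prefix; writes `<prefix>_cc.tif`, `<prefix>_scp.tif`,
#'   `<prefix>.json`.
#' @return `write_stack` returns the sidecar path invisibly; `read_stack`
#'   returns an `octa_stack`.
#' @export
write_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "octa_stack"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(lapply(stack$cc, function(f) f$intensities),
                  paste0(prefix, "_cc.tif"), bits.per.sample = 16)
  tiff::writeTIFF(lapply(stack$scp, function(f) f$intensities),
                  paste0(prefix, "_scp.tif"), bits.per.sample = 16)
  side <- list(
    pixel_pitch_um = stack$pixel_pitch_um,
    n_frames = length(stack$cc),
    transforms = lapply(stack$transforms, function(t)
      list(dx_px = t$dx_px, dy_px = t$dy_px, theta_deg = t$theta_deg,
           quality = t$quality)))
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' @rdname write_stack
#' @export
read_stack <- function(prefix) {
  if (!file.exists(paste0(prefix, ".json")))
    stop("stack sidecar not found: ", paste0(prefix, ".json"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pitch <- side$pixel_pitch_um
  cc <- lapply(tiff::readTIFF(paste0(prefix, "_cc.tif"), all = TRUE),
               en_face_image, pixel_pitch_um = pitch, modality = "octa_cc")
  scp <- lapply(tiff::readTIFF(paste0(prefix, "_scp.tif"), all = TRUE),
                en_face_image, pixel_pitch_um = pitch, modality = "octa_scp")
  tr <- lapply(seq_len(nrow(side$transforms)), function(i)
    frame_transform(side$transforms$dx_px[i], side$transforms$dy_px[i],
                    side$transforms$theta_deg[i], side$transforms$quality[i]))
  structure(list(cc = cc, scp = scp, transforms = tr, pixel_pitch_um = pitch),
            class = "octa_stack")
}

#' Write / read an en face image (16-bit grayscale TIFF or PNG)
#'
#' Format chosen by file extension; a `<path>.json` sidecar stores the pixel
#' pitch and modality.
#'
#' @param image An `en_face_image`.
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @return `write_enface` returns `path` invisibly; `read_enface` returns an
#'   `en_face_image`.
#' @export
write_enface <- function(image, path) {
  stopifnot(inherits(image, "en_face_image"))
  x <- image$intensities
  x[is.na(x)] <- 0
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::writeTIFF(x, path, bits.per.sample = 16)
  else if (grepl("\\.png$", path, ignore.case = TRUE))
    png::writePNG(x, path)
  else stop("unsupported image extension: ", path)
  jsonlite::write_json(list(pixel_pitch_um = image$pixel_pitch_um,
                            modality = image$modality),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_enface
#' @export
read_enface <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  side_path <- paste0(path, ".json")
  meta <- if (file.exists(side_path))
    jsonlite::read_json(side_path, simplifyVector = TRUE)
  else list(pixel_pitch_um = 10, modality = "octa_cc")
  x <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path)
  else if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path)
  else stop("unsupported image extension: ", path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  en_face_image(x, meta$pixel_pitch_um, meta$modality)
}

#' Write / read a binary mask as 8-bit PNG (0/255)
#'
#' @param mask A `binary_mask`.
#' @param path PNG path.
#' @param pixel_pitch_um,foreground_meaning Metadata applied on read.
#' @return `write_mask` returns `path` invisibly; `read_mask` a
#'   `binary_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(mask$values * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, pixel_pitch_um,
                      foreground_meaning = "bright_signal") {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  binary_mask(x > 0.5, pixel_pitch_um, foreground_meaning)
}

# ---- pipeline configuration -------------------------------------------------

config_defaults <- function() {
  list(
    pixel_pitch_um = 10,
    field_mm = 3.0,
    seed = 1,
    phansalkar = list(radius_px = 15, k = 0.25, r = 0.5, p = 2, q = 10,
                      neighborhood_shape = "disk"),
    registration = list(min_quality = 0.5, reference_index = 1,
                        rotation_range_deg = 2),
    quantification = list(connectivity = 8, min_void_px = 0),
    stats = list(ttest_variant = "student",
                 adjust_covariates = c("age", "sex")),
    simulation = list(n_ppe = 32, n_control = 30, n_frames = 3,
                      speckle_shape = 12, shift_sd_px = 2,
                      rotation_sd_deg = 0.3, pixel_count = 300,
                      choroid_noise_sd = 0.05)
  )
}

# integers read from JSON/YAML become doubles so round-trips are identical()
canon_config <- function(x) {
  if (is.list(x)) lapply(x, canon_config)
  else if (is.integer(x)) as.numeric(x)
  else x
}

validate_config <- function(cfg) {
  cfg <- canon_config(cfg)
  pos <- function(path, v) if (!is.numeric(v) || v <= 0)
    stop("config value out of range: ", path, " must be > 0")
  pos("pixel_pitch_um", cfg$pixel_pitch_um)
  pos("field_mm", cfg$field_mm)
  if (cfg$phansalkar$radius_px < 1)
    stop("config value out of range: phansalkar.radius_px must be >= 1")
  pos("phansalkar.r", cfg$phansalkar$r)
  if (!cfg$phansalkar$neighborhood_shape %in% c("disk", "square"))
    stop("config value out of range: phansalkar.neighborhood_shape")
  if (cfg$registration$min_quality < 0 || cfg$registration$min_quality > 1)
    stop("config value out of range: registration.min_quality must be in [0, 1]")
  if (cfg$registration$reference_index < 1)
    stop("config value out of range: registration.reference_index must be >= 1")
  if (!cfg$quantification$connectivity %in% c(4, 8))
    stop("config value out of range: quantification.connectivity must be 4 or 8")
  if (cfg$quantification$min_void_px < 0)
    stop("config value out of range: quantification.min_void_px must be >= 0")
  if (!cfg$stats$ttest_variant %in% c("student", "welch"))
    stop("config value out of range: stats.ttest_variant")
  if (cfg$simulation$n_frames < 1)
    stop("config value out of range: simulation.n_frames must be >= 1")
  pos("simulation.speckle_shape", cfg$simulation$speckle_shape)
  if (cfg$simulation$pixel_count < 64)
    stop("config value out of range: simulation.pixel_count must be >= 64")
  structure(cfg, class = "pipeline_config")
}

#' Load (or build) a pipeline configuration
#'
#' Reads a JSON or YAML config file, overlays it on the defaults, rejects
#' unknown keys naming the offending key, validates every field, and echoes
#' the full effective configuration. `default_config()` returns the pure
#' defaults; `save_config()` writes a config back out (round-trips through
#' `load_config`).
#'
#' @param path Config file (`.json`, `.yaml`/`.yml`); an empty file yields
#'   all defaults.
#' @param quiet Suppress the effective-config echo (default TRUE).
#' @return An object of class `pipeline_config` (a validated nested list).
#' @export
load_config <- function(path, quiet = TRUE) {
  if (!file.exists(path)) stop("config file not readable: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (nchar(trimws(txt)) == 0) list()
    else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    out <- yaml::read_yaml(path)
    if (is.null(out)) list() else out
  } else stop("config file must be .json or .yaml/.yml: ", path)
  cfg <- merge_config(config_defaults(), user, prefix = "")
  cfg <- validate_config(cfg)
  if (!quiet) {
    message("effective configuration:")
    message(yaml::as.yaml(unclass(cfg)))
  }
  cfg
}

#' @rdname load_config
#' @export
default_config <- function() validate_config(config_defaults())

#' @rdname load_config
#' @param cfg A `pipeline_config`.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

merge_config <- function(def, usr, prefix) {
  if (length(usr) == 0) return(def)
  bad <- setdiff(names(usr), names(def))
  if (length(bad) > 0)
    stop("unknown config key: ", paste0(prefix, bad[1]))
  for (k in names(usr)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      if (!is.list(usr[[k]]))
        stop("config key ", prefix, k, " must be a section")
      def[[k]] <- merge_config(def[[k]], usr[[k]], paste0(prefix, k, "."))
    } else {
      def[[k]] <- usr[[k]]
    }
  }
  def
}
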