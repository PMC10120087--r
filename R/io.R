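#' Read a single-plane TIFF image as a numeric matrix
#'
#' Supports 8/16-bit integer and 32-bit float single-plane TIFFs.
#' Integer samples are converted to float without rescaling.
#'
#' @param path Path to a TIFF file.
#' @return Numeric matrix (rows x cols).
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("image file not found: ", path, call. = FALSE)
  # as.is=TRUE returns raw integer values but rejects float TIFFs, which
  # are already on their native scale
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE, all = TRUE),
                  error = function(e) tiff::readTIFF(path, all = TRUE))
  if (length(img) != 1)
    stop("unsupported format: multi-plane TIFF (", length(img), " planes)",
         call. = FALSE)
  img <- img[[1]]
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 1) img <- img[, , 1] else
      stop("unsupported format: multi-channel (RGB) TIFF", call. = FALSE)
  }
  matrix(as.numeric(img), nrow(img), ncol(img))
}

#' Write a numeric matrix as a 32-bit float TIFF
#'
#' Writes a minimal single-strip, little-endian, IEEE-float TIFF so that
#' arbitrary-range scientific images (lifetimes in ns, photon counts)
#' round-trip value-identically. Readable by any libtiff-based reader,
#' including [read_image()].
#'
#' @param img Numeric matrix.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(is.matrix(img), is.numeric(img))
  H <- nrow(img); W <- ncol(img)
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- 4L * H * W
  ifd_off <- 8L + nbytes
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off, con, size = 4, endian = "little")
  writeBin(as.numeric(t(img)), con, size = 4, endian = "little")
  entry <- function(tag, type, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    if (type == 3L) {                     # SHORT: low 2 bytes + padding
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(10L, con, size = 2, endian = "little")   # entry count
  entry(256, 4, W)          # ImageWidth
  entry(257, 4, H)          # ImageLength
  entry(258, 3, 32)         # BitsPerSample
  entry(259, 3, 1)          # Compression: none
  entry(262, 3, 1)          # Photometric: BlackIsZero
  entry(273, 4, 8)          # StripOffsets
  entry(277, 3, 1)          # SamplesPerPixel
  entry(278, 4, H)          # RowsPerStrip
  entry(279, 4, nbytes)     # StripByteCounts
  entry(339, 3, 3)          # SampleFormat: IEEE float
  writeBin(0L, con, size = 4, endian = "little")    # no next IFD
  invisible(path)
}

# Internal: serialize a config object to a plain named list (for YAML
# configuration files and JSON manifests).
config_to_list <- function(x) {
  out <- unclass(x)
  if (!is.null(out$gate)) out$gate <- unclass(out$gate)
  lapply(out, function(v) if (is.list(v)) v else v)
}

# Internal: call a constructor with only the fields present in `vals`,
# rejecting unknown keys with their names.
apply_section <- function(constructor, vals, section) {
  if (is.null(vals)) return(constructor())
  ok <- names(formals(constructor))
  bad <- setdiff(names(vals), ok)
  if (length(bad))
    stop("unknown key(s) in section '", section, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  do.call(constructor, vals)
}

#' Load a full system configuration from a YAML file
#'
#' The file may contain any of the sections \code{system} (with an
#' optional nested \code{gate} block), \code{detector}, \code{ir},
#' \code{cnn} and \code{train}; missing sections take the package
#' defaults and unknown keys are rejected with their names. Units follow
#' the constructors: times in ns, shear in pixels.
#'
#' @param path Path to the YAML configuration.
#' @return Named list with elements \code{system}, \code{detector},
#'   \code{ir}, \code{cnn}, \code{train}.
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("system", "detector", "ir", "cnn", "train")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  sys_vals <- raw$system
  if (!is.null(sys_vals$gate))
    sys_vals$gate <- apply_section(gate_profile, sys_vals$gate, "system/gate")
  if (!is.null(sys_vals$replica_weights))
    sys_vals$replica_weights <- as.numeric(unlist(sys_vals$replica_weights))
  list(system = apply_section(system_config, sys_vals, "system"),
       detector = apply_section(detector_config, raw$detector, "detector"),
       ir = apply_section(ir_config, raw$ir, "ir"),
       cnn = apply_section(cnn_spec, raw$cnn, "cnn"),
       train = apply_section(train_config, raw$train, "train"))
}

#' Save a configuration list to YAML
#'
#' Inverse of [load_config()]: writes the given configuration objects so
#' that loading the file reproduces them exactly.
#'
#' @param cfgs Named list with any of \code{system}, \code{detector},
#'   \code{ir}, \code{cnn}, \code{train} (as returned by [load_config()]).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(cfgs, path) {
  out <- lapply(cfgs, config_to_list)
  # drop non-scalar/NULL entries yaml can't round-trip cleanly
  out <- lapply(out, function(sec) sec[!vapply(sec, is.null, logical(1))])
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}
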