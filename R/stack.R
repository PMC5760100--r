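#' Construct a calibrated time-lapse frame stack
#'
#' A `frame_stack` holds one or two channels of a 2-D time-lapse recording
#' as T x H x W arrays together with the physical calibration: channel 1 is
#' the moving-puncta channel, channel 2 (optional) the static basal-body
#' marker. The default calibration matches the acquisition emulated by the
#' synthetic generator: 210 nm square pixels, 1 frame per second.
#'
#' @param ch1 numeric T x H x W array (frames x rows x columns).
#' @param ch2 optional second channel of identical dimensions.
#' @param pixel_size_nm pixel pitch, nm (> 0).
#' @param frame_interval_s frame interval, s (> 0).
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(ch1, ch2 = NULL, pixel_size_nm = 210,
                        frame_interval_s = 1) {
  stopifnot(length(dim(ch1)) == 3L, pixel_size_nm > 0, frame_interval_s > 0)
  if (!all(is.finite(ch1)) || any(ch1 < 0)) {
    stop("channel 1 intensities must be finite and >= 0")
  }
  if (!is.null(ch2)) {
    stopifnot(identical(dim(ch1), dim(ch2)))
    if (!all(is.finite(ch2)) || any(ch2 < 0)) {
      stop("channel 2 intensities must be finite and >= 0")
    }
  }
  structure(list(ch1 = ch1, ch2 = ch2,
                 pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$ch1)
  cat(sprintf(
    "frame_stack: %d frame(s), %d x %d px, %d channel(s), %g nm/px, %g s/frame\n",
    d[1], d[2], d[3], 1L + !is.null(x$ch2),
    x$pixel_size_nm, x$frame_interval_s))
  invisible(x)
}

n_frames <- function(stack) dim(stack$ch1)[1]

#' Write a frame stack to multi-frame TIFF
#'
#' One 32-bit float TIFF per channel (`<prefix>_ch1.tif`, `<prefix>_ch2.tif`)
#' plus a JSON sidecar `<prefix>_calibration.json` holding `pixel_size_nm`
#' and `frame_interval_s`, since the baseline TIFF writer exposes no
#' free-form calibration tag. [read_stack()] restores the calibration from
#' the sidecar.
#'
#' @param stack a [frame_stack()].
#' @param prefix output path prefix (directory must exist).
#' @return the paths written, invisibly.
#' @export
write_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "frame_stack"))
  # TIFF float samples are written in [0, 1]; intensities are rescaled on
  # write and the scale restored from the sidecar on read.
  scale1 <- max(stack$ch1, 1)
  to_frames <- function(arr, scale) {
    lapply(seq_len(dim(arr)[1]), function(t) arr[t, , ] / scale)
  }
  paths <- character(0)
  p1 <- paste0(prefix, "_ch1.tif")
  tiff::writeTIFF(to_frames(stack$ch1, scale1), p1, bits.per.sample = 32L)
  paths <- c(paths, p1)
  scale2 <- NULL
  if (!is.null(stack$ch2)) {
    scale2 <- max(stack$ch2, 1)
    p2 <- paste0(prefix, "_ch2.tif")
    tiff::writeTIFF(to_frames(stack$ch2, scale2), p2, bits.per.sample = 32L)
    paths <- c(paths, p2)
  }
  meta <- paste0(prefix, "_calibration.json")
  jsonlite::write_json(
    list(pixel_size_nm = stack$pixel_size_nm,
         frame_interval_s = stack$frame_interval_s,
         intensity_scale_ch1 = scale1,
         intensity_scale_ch2 = scale2),
    meta, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta))
}

#' Read a frame stack written by [write_stack()]
#'
#' @param prefix path prefix used when writing.
#' @return a [frame_stack()].
#' @export
read_stack <- function(prefix) {
  p1 <- paste0(prefix, "_ch1.tif")
  if (!file.exists(p1)) stop("no TIFF found at ", p1)
  from_frames <- function(path) {
    fr <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(fr)) fr <- list(fr)
    dims <- unique(lapply(fr, dim))
    if (length(dims) != 1L) stop("inconsistent frame shapes in ", path)
    arr <- array(0, dim = c(length(fr), dims[[1]][1], dims[[1]][2]))
    for (t in seq_along(fr)) arr[t, , ] <- fr[[t]]
    arr
  }
  ch1 <- from_frames(p1)
  p2 <- paste0(prefix, "_ch2.tif")
  ch2 <- if (file.exists(p2)) from_frames(p2) else NULL
  meta_path <- paste0(prefix, "_calibration.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(pixel_size_nm = 210, frame_interval_s = 1)
  }
  if (!is.null(meta$intensity_scale_ch1)) ch1 <- ch1 * meta$intensity_scale_ch1
  if (!is.null(ch2) && !is.null(meta$intensity_scale_ch2)) {
    ch2 <- ch2 * meta$intensity_scale_ch2
  }
  frame_stack(ch1, ch2, pixel_size_nm = meta$pixel_size_nm,
              frame_interval_s = meta$frame_interval_s)
}
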