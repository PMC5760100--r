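#' Rendering configuration for synthetic videos
#'
#' Controls how ground-truth particle positions are turned into a
#' fluorescence-like two-channel video: each particle becomes an isotropic
#' Gaussian blob (width `psf_sigma`, the approximate diffraction limit at
#' the emulated magnification), the basal body a single static blob in
#' channel 2. A `diffuse_fraction` > 0 diverts that fraction of the total
#' particle signal into an unstructured cytoplasmic background inside the
#' cell mask, emulating the diffuse signal seen alongside fewer puncta in
#' mutant cells. Optional Poisson shot noise and additive Gaussian read
#' noise are applied after rendering, as is a per-frame stage drift.
#'
#' @param psf_sigma blob standard deviation, nm (> 0).
#' @param peak_intensity blob peak value, arbitrary units.
#' @param background_level constant background offset.
#' @param cell_background static cytoplasmic autofluorescence inside the
#'   cell mask, as a fraction of `peak_intensity` (default 0.05). Real
#'   recordings always carry such structure; it is also what anchors
#'   translation registration, which is ill-posed on a scene containing
#'   nothing but moving puncta.
#' @param diffuse_fraction fraction of total signal rendered as diffuse
#'   cytoplasmic background, in `[0, 1]`.
#' @param poisson_noise logical; apply Poisson shot noise treating pixel
#'   values as expected photon counts.
#' @param gaussian_sd additive Gaussian read-noise standard deviation
#'   (0 disables).
#' @param drift_per_frame numeric length-2 `(dx, dy)`, pixels of stage drift
#'   accumulated per frame.
#' @param seed integer seed for the noise draws.
#' @return a `render_config` list.
#' @export
render_config <- function(psf_sigma = 250,
                          peak_intensity = 100,
                          background_level = 0,
                          cell_background = 0.05,
                          diffuse_fraction = 0,
                          poisson_noise = FALSE,
                          gaussian_sd = 0,
                          drift_per_frame = c(0, 0),
                          seed = 1L) {
  stopifnot(psf_sigma > 0, peak_intensity > 0, background_level >= 0,
            cell_background >= 0, diffuse_fraction >= 0,
            diffuse_fraction <= 1, gaussian_sd >= 0,
            length(drift_per_frame) == 2L)
  structure(list(
    psf_sigma = psf_sigma,
    peak_intensity = peak_intensity,
    background_level = background_level,
    cell_background = cell_background,
    diffuse_fraction = diffuse_fraction,
    poisson_noise = isTRUE(poisson_noise),
    gaussian_sd = gaussian_sd,
    drift_per_frame = as.numeric(drift_per_frame),
    seed = as.integer(seed)
  ), class = "render_config")
}

# Add one Gaussian blob at continuous pixel position (x0, y0) to `img`
# (matrix, rows = y). Only a +/- 4 sigma window is evaluated.
add_blob <- function(img, x0, y0, sigma_px, peak) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * sigma_px)
  cols <- max(1L, floor(x0) - r + 1L):min(w, ceiling(x0) + r + 1L)
  rws <- max(1L, floor(y0) - r + 1L):min(h, ceiling(y0) + r + 1L)
  if (length(cols) < 1L || length(rws) < 1L || cols[1] > w || rws[1] > h) {
    return(img)
  }
  dx2 <- ((cols - 1) - x0)^2
  dy2 <- ((rws - 1) - y0)^2
  img[rws, cols] <- img[rws, cols] +
    peak * outer(exp(-dy2 / (2 * sigma_px^2)), exp(-dx2 / (2 * sigma_px^2)))
  img
}

#' Render ground-truth trajectories into a two-channel video
#'
#' @param truth a `truth_tracks` data.frame from [simulate_tracks()] (or any
#'   data.frame with `particle_id`, `frame`, `x_nm`, `y_nm` and optionally
#'   `radius_nm`).
#' @param geometry the [make_geometry()] cell the positions live in; sets
#'   the raster size and the basal-body blob of channel 2.
#' @param render a [render_config()].
#' @param n_frames number of frames to render; defaults to the largest frame
#'   index in `truth`.
#' @param pixel_size_nm pixel pitch, nm.
#' @param frame_interval_s frame interval, s.
#' @return a [frame_stack()] with the truth table attached as attribute
#'   `truth` (oracle for tracker evaluation).
#' @export
render_video <- function(truth, geometry, render,
                         n_frames = max(truth$frame),
                         pixel_size_nm = 210, frame_interval_s = 1) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(render, "render_config"))
  h <- nrow(geometry$mask); w <- ncol(geometry$mask)
  sigma_px <- render$psf_sigma / pixel_size_nm
  radius <- if (is.null(truth$radius_nm)) 0 else truth$radius_nm
  radius <- rep(radius, length.out = max(1L, nrow(truth)))
  # effective blob width: optics convolved with a finite particle
  sigma_eff_px <- sqrt(sigma_px^2 + (radius / 2 / pixel_size_nm)^2)
  peak <- render$peak_intensity * (1 - render$diffuse_fraction)

  ch1 <- array(render$background_level, dim = c(n_frames, h, w))
  ch2 <- array(0, dim = c(n_frames, h, w))
  diffuse_per_px <- 0
  if (render$diffuse_fraction > 0) {
    mean_blob_flux <- render$peak_intensity * 2 * pi * mean(sigma_eff_px)^2
    mean_n <- nrow(truth) / n_frames
    diffuse_per_px <- render$diffuse_fraction * mean_n * mean_blob_flux /
      sum(geometry$mask)
  }

  bg_cell <- render$cell_background * render$peak_intensity *
    (geometry$mask + 0)

  on_raster <- rep(FALSE, n_frames)
  for (t in seq_len(n_frames)) {
    drift <- (t - 1) * render$drift_per_frame
    img <- if (render$cell_background > 0) {
      translate_frame(bg_cell, round(drift[1]), round(drift[2]))
    } else {
      matrix(0, h, w)
    }
    sel <- which(truth$frame == t)
    for (i in sel) {
      x0 <- truth$x_nm[i] / pixel_size_nm + drift[1]
      y0 <- truth$y_nm[i] / pixel_size_nm + drift[2]
      if (x0 > -1 && x0 < w && y0 > -1 && y0 < h) on_raster[t] <- TRUE
      img <- add_blob(img, x0, y0, sigma_eff_px[i], peak)
    }
    if (diffuse_per_px > 0) img <- img + diffuse_per_px * geometry$mask
    ch1[t, , ] <- ch1[t, , ] + img
    bb <- matrix(0, h, w)
    bbx <- geometry$bb_position[["x"]] + drift[1]
    bby <- geometry$bb_position[["y"]] + drift[2]
    if (bbx > -1 && bbx < w && bby > -1 && bby < h) on_raster[t] <- TRUE
    ch2[t, , ] <- add_blob(bb, bbx, bby, sigma_px, render$peak_intensity)
  }
  if (!all(on_raster)) {
    stop(sprintf("drift pushed all content off the raster in frame %d",
                 which(!on_raster)[1]))
  }

  if (render$poisson_noise || render$gaussian_sd > 0) {
    set.seed(render$seed)
    if (render$poisson_noise) {
      ch1[] <- stats::rpois(length(ch1), lambda = ch1)
      ch2[] <- stats::rpois(length(ch2), lambda = ch2)
    }
    if (render$gaussian_sd > 0) {
      ch1[] <- ch1 + stats::rnorm(length(ch1), 0, render$gaussian_sd)
      ch2[] <- ch2 + stats::rnorm(length(ch2), 0, render$gaussian_sd)
    }
    ch1[ch1 < 0] <- 0
    ch2[ch2 < 0] <- 0
  }

  out <- frame_stack(ch1, ch2, pixel_size_nm = pixel_size_nm,
                     frame_interval_s = frame_interval_s)
  attr(out, "truth") <- truth
  out
}
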