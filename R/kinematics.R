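#' Basal-body contact criterion configuration
#'
#' A frame counts as a contact when the particle barycenter lies within
#' `radius_px` pixels (inclusive) of the basal-body barycenter: 3 pixels at
#' 210 nm per pixel, i.e. 630 nm.
#'
#' @param radius_px contact radius in pixels (> 0).
#' @param pixel_size_nm pixel pitch, nm.
#' @return a `contact_config` list with the derived `radius_nm`.
#' @export
contact_config <- function(radius_px = 3, pixel_size_nm = 210) {
  stopifnot(radius_px > 0, pixel_size_nm > 0)
  structure(list(radius_px = radius_px, pixel_size_nm = pixel_size_nm,
                 radius_nm = radius_px * pixel_size_nm),
            class = "contact_config")
}

track_xy_nm <- function(track) {
  stopifnot(all(c("x_nm", "y_nm") %in% names(track)))
  cbind(track$x_nm, track$y_nm)[order(track$frame), , drop = FALSE]
}

#' Particle displacement
#'
#' Euclidean distance between the first and the last barycenter of a track,
#' in nm.
#'
#' @param track one track: data.frame with `frame`, `x_nm`, `y_nm`.
#' @return displacement in nm (0 for a single-frame track).
#' @export
displacement <- function(track) {
  p <- track_xy_nm(track)
  if (nrow(p) < 2L) return(0)
  sqrt(sum((p[nrow(p), ] - p[1, ])^2))
}

#' Total trajectory length
#'
#' Sum of Euclidean step lengths between consecutive frames, reported in um.
#'
#' @inheritParams displacement
#' @return trajectory length in um (0 for a single-frame track).
#' @export
trajectory_length <- function(track) {
  p <- track_xy_nm(track)
  if (nrow(p) < 2L) return(0)
  steps <- sqrt(rowSums(diff(p)^2))
  sum(steps) / 1000
}

#' Maximum particle speed
#'
#' Largest distance traveled between two consecutive frames, divided by the
#' frame interval; nm/s.
#'
#' @inheritParams displacement
#' @param frame_interval_s frame interval in seconds.
#' @return maximum speed in nm/s, or `NA` (flagged) for tracks with fewer
#'   than 2 frames.
#' @export
max_speed <- function(track, frame_interval_s = 1) {
  p <- track_xy_nm(track)
  if (nrow(p) < 2L) return(NA_real_)
  max(sqrt(rowSums(diff(p)^2))) / frame_interval_s
}

#' Rotation-corrected directionality ratio
#'
#' Rotates the barycenters into the cell frame with
#' [rotate_to_cell_axis()] and returns the ratio of the lateral span to the
#' apico-basal span, `(max x' - min x') / (max y' - min y')`. Values below 1
#' indicate predominantly apico-basal movement.
#'
#' @inheritParams displacement
#' @param theta the cell's axis angle, radians.
#' @return dimensionless ratio, or `NA` (flagged) when the track has fewer
#'   than 2 frames or zero apico-basal span.
#' @export
directionality <- function(track, theta) {
  p <- track_xy_nm(track)
  if (nrow(p) < 2L) return(NA_real_)
  r <- rotate_to_cell_axis(p, theta)
  span_x <- diff(range(r[, 1]))
  span_y <- diff(range(r[, 2]))
  if (span_y == 0) return(NA_real_)
  span_x / span_y
}

#' Mean cross-sectional area of a tracked particle
#'
#' Mean over the track's frames of `pixel_count` times the pixel area
#' (0.0441 um^2 at 210 nm pixels, i.e. 10 pixels = 0.441 um^2).
#'
#' @inheritParams displacement
#' @param pixel_size_nm pixel pitch, nm.
#' @return area in um^2, or `NA` when the track carries no `pixel_count`.
#' @export
mean_area <- function(track, pixel_size_nm = 210) {
  if (is.null(track$pixel_count) || any(is.na(track$pixel_count))) {
    return(NA_real_)
  }
  mean(track$pixel_count) * (pixel_size_nm / 1000)^2
}

#' Basal-body contacts of a track
#'
#' A frame is a contact frame iff the barycenter lies within the contact
#' radius (inclusive) of the basal-body barycenter.
#'
#' @inheritParams displacement
#' @param geometry a [make_geometry()] geometry providing `bb_position`.
#' @param config a [contact_config()].
#' @return list with `contacted` (logical) and `n_contact_frames` (count).
#' @export
bb_contacts <- function(track, geometry, config = contact_config()) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(config, "contact_config"))
  p <- track_xy_nm(track)
  bb_nm <- geometry$bb_position * config$pixel_size_nm
  d <- sqrt((p[, 1] - bb_nm[["x"]])^2 + (p[, 2] - bb_nm[["y"]])^2)
  n <- sum(d <= config$radius_nm)
  list(contacted = n >= 1L, n_contact_frames = as.integer(n))
}

#' Per-track kinematic metrics
#'
#' Computes the five per-particle statistics (displacement, trajectory,
#' maximum speed, directionality, area) plus basal-body contact information
#' for every track in a long-format track table.
#'
#' @param tracks data.frame from [link_tracks()]/[filter_tracks()] (or a
#'   truth table with `particle_id` renamed to `track_id`).
#' @param geometry the cell's [make_geometry()] geometry (axis angle and
#'   basal-body position).
#' @param frame_interval_s frame interval, s.
#' @param pixel_size_nm pixel pitch, nm.
#' @param contact a [contact_config()].
#' @return data.frame with one row per track: `track_id`, `n_frames`,
#'   `displacement_nm`, `trajectory_um`, `max_speed_nm_s`, `directionality`,
#'   `area_um2`, `contacted_bb`, `n_contact_frames`.
#' @export
track_metrics <- function(tracks, geometry, frame_interval_s = 1,
                          pixel_size_nm = 210,
                          contact = contact_config(pixel_size_nm = pixel_size_nm)) {
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    ct <- bb_contacts(tr, geometry, contact)
    data.frame(
      track_id = id,
      n_frames = nrow(tr),
      displacement_nm = displacement(tr),
      trajectory_um = trajectory_length(tr),
      max_speed_nm_s = max_speed(tr, frame_interval_s),
      directionality = directionality(tr, geometry$axis_angle_theta),
      area_um2 = mean_area(tr, pixel_size_nm),
      contacted_bb = ct$contacted,
      n_contact_frames = ct$n_contact_frames
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(track_id = integer(0), n_frames = integer(0),
                      displacement_nm = numeric(0), trajectory_um = numeric(0),
                      max_speed_nm_s = numeric(0), directionality = numeric(0),
                      area_um2 = numeric(0), contacted_bb = logical(0),
                      n_contact_frames = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Per-photoreceptor summary
#'
#' Unweighted means of each kinematic metric over a cell's eligible tracks
#' (tracks must already be filtered to >= 10 frames) and the proportion of
#' tracks contacting the basal body: one row per photoreceptor, the unit
#' plotted as one dot in the study's scatter plots. Tracks with undefined
#' metrics (single frame, zero apico-basal span, no pixel counts) are
#' excluded from the corresponding mean and counted in the
#' `n_undefined` attribute.
#'
#' @param metrics per-track metrics from [track_metrics()].
#' @param cell_id photoreceptor identifier.
#' @param condition condition label (genotype x paralog x photoreceptor
#'   type).
#' @param animal_id animal identifier.
#' @return one-row data.frame: `animal_id`, `cell_id`, `condition`,
#'   `n_tracks`, mean `displacement_nm`, `trajectory_um`, `max_speed_nm_s`,
#'   `directionality`, `area_um2`, `contact_proportion`, `n_contacting`.
#' @export
summarize_pr <- function(metrics, cell_id = "cell_1", condition = "wt",
                         animal_id = "animal_1") {
  n <- nrow(metrics)
  mean_or_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) NA_real_ else mean(x)
  }
  n_undef <- sum(is.na(metrics$max_speed_nm_s)) +
    sum(is.na(metrics$directionality))
  out <- data.frame(
    animal_id = animal_id,
    cell_id = cell_id,
    condition = condition,
    n_tracks = n,
    displacement_nm = mean_or_na(metrics$displacement_nm),
    trajectory_um = mean_or_na(metrics$trajectory_um),
    max_speed_nm_s = mean_or_na(metrics$max_speed_nm_s),
    directionality = mean_or_na(metrics$directionality),
    area_um2 = mean_or_na(metrics$area_um2),
    contact_proportion = if (n > 0) sum(metrics$contacted_bb) / n else NA_real_,
    n_contacting = sum(metrics$contacted_bb)
  )
  attr(out, "n_undefined") <- n_undef
  if (n == 0L) attr(out, "flag") <- "no eligible tracks"
  out
}
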