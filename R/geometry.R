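#' Rotate image coordinates into the cell's apico-basal frame
#'
#' Applies the Euler-angle rotation used to express particle coordinates in a
#' photoreceptor's own reference frame before computing directionality:
#' `x' = x*cos(theta) + y*sin(theta)` and `y' = y*cos(theta) - x*sin(theta)`,
#' where `theta` is the angle between the cell's apico-basal axis and the
#' image vertical (y) axis. After rotation, `x'` is the lateral coordinate
#' and `y'` the apico-basal (axial) coordinate.
#'
#' @param points numeric matrix or data.frame with two columns (x, y), or a
#'   length-2 numeric vector for a single point.
#' @param theta rotation angle in radians.
#' @return a numeric matrix with columns `x` and `y` holding the rotated
#'   coordinates (same number of rows as the input).
#' @examples
#' rotate_to_cell_axis(c(1, 0), pi / 2)  # -> (0, -1)
#' @export
rotate_to_cell_axis <- function(points, theta) {
  p <- as_xy_matrix(points)
  stopifnot(is.finite(theta))
  ct <- cos(theta)
  st <- sin(theta)
  out <- cbind(x = p[, 1] * ct + p[, 2] * st,
               y = p[, 2] * ct - p[, 1] * st)
  out
}

#' Inverse of [rotate_to_cell_axis()]: cell-frame coordinates back to image
#' coordinates.
#' @inheritParams rotate_to_cell_axis
#' @return matrix with columns `x`, `y` in image coordinates.
#' @keywords internal
cell_to_image <- function(points, theta) {
  rotate_to_cell_axis(points, -theta)
}

as_xy_matrix <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 2L)
    points <- matrix(points, ncol = 2L)
  }
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(p) <- "double"
  stopifnot(all(is.finite(p)))
  p
}

#' Construct a synthetic photoreceptor geometry
#'
#' Builds one cell's geometry annotation: a rectangular footprint of
#' `cell_length` (apico-basal) by `cell_width` (lateral) pixels, rotated by
#' `theta` relative to the image vertical axis, with the basal body (BB)
#' placed near the apical end and compartment boundaries along the rotated
#' apico-basal axis splitting the cell into an apical (outer-segment/BB)
#' region, the inner segment, and the basal (synaptic) region.
#'
#' Image coordinates are 0-based with `x` = column and `y` = row; `y`
#' increases basally, so the apical end of an unrotated cell is at low `y`.
#' Axial (cell-frame) coordinates `y'` are measured from the cell centre,
#' negative towards the apical end.
#'
#' @param axis_angle_theta angle (radians, in (-pi, pi]) between the
#'   apico-basal axis and the image vertical axis.
#' @param cell_length apico-basal extent in pixels (>= 4).
#' @param cell_width lateral extent in pixels (>= 4).
#' @param cell_id identifier stored in the geometry.
#' @param seed integer seed (reserved for randomized footprint variants; the
#'   default footprint is deterministic).
#' @return an object of class `cell_geometry`: a list with `cell_id`,
#'   `axis_angle_theta`, `bb_position` (x, y in pixels), `mask` (logical
#'   H x W matrix, rows = y), `compartment_bounds` (two strictly increasing
#'   axial positions, pixels, cell-frame), `center` (x, y pixels),
#'   `cell_length`, `cell_width`.
#' @export
make_geometry <- function(axis_angle_theta, cell_length, cell_width,
                          cell_id = "cell_1", seed = 1L) {
  if (!is.finite(axis_angle_theta) || axis_angle_theta <= -pi ||
      axis_angle_theta > pi) {
    stop("axis_angle_theta must be finite and in (-pi, pi]")
  }
  if (!is.finite(cell_length) || cell_length < 4 ||
      !is.finite(cell_width) || cell_width < 4) {
    stop("degenerate cell dimensions: cell_length and cell_width must be >= 4 px")
  }
  margin <- 4
  ex <- (cell_width * abs(cos(axis_angle_theta)) +
           cell_length * abs(sin(axis_angle_theta))) / 2
  ey <- (cell_width * abs(sin(axis_angle_theta)) +
           cell_length * abs(cos(axis_angle_theta))) / 2
  w_img <- ceiling(2 * ex) + 2 * margin
  h_img <- ceiling(2 * ey) + 2 * margin
  center <- c(x = (w_img - 1) / 2, y = (h_img - 1) / 2)

  # pixel centres, 0-based
  xs <- rep(seq_len(w_img) - 1, each = h_img)
  ys <- rep(seq_len(h_img) - 1, times = w_img)
  rel <- cbind(xs - center[["x"]], ys - center[["y"]])
  cf <- rotate_to_cell_axis(rel, axis_angle_theta)
  inside <- abs(cf[, 1]) <= cell_width / 2 & abs(cf[, 2]) <= cell_length / 2
  mask <- matrix(inside, nrow = h_img, ncol = w_img)
  if (!any(mask)) stop("geometry mask is empty")

  bb_inset <- max(1, 0.08 * cell_length)
  bb_axial <- -cell_length / 2 + bb_inset
  bb <- cell_to_image(c(0, bb_axial), axis_angle_theta)
  bb_position <- stats::setNames(
    as.numeric(c(bb[1, 1] + center[["x"]], bb[1, 2] + center[["y"]])),
    c("x", "y"))

  b1 <- -cell_length / 2 + max(0.25 * cell_length, bb_inset + 0.5)
  b2 <- -cell_length / 2 + 0.70 * cell_length
  stopifnot(b1 < b2)

  geom <- structure(list(
    cell_id = cell_id,
    axis_angle_theta = axis_angle_theta,
    bb_position = bb_position,
    mask = mask,
    compartment_bounds = c(b1, b2),
    center = center,
    cell_length = cell_length,
    cell_width = cell_width,
    seed = as.integer(seed)
  ), class = "cell_geometry")
  validate_geometry(geom)
  geom
}

#' Check the invariants of a `cell_geometry` object
#' @param geom a `cell_geometry`.
#' @return the geometry, invisibly; errors if an invariant is violated.
#' @export
validate_geometry <- function(geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  th <- geom$axis_angle_theta
  if (!(th > -pi && th <= pi)) stop("axis_angle_theta out of (-pi, pi]")
  b <- geom$compartment_bounds
  if (!(length(b) == 2L && b[1] < b[2])) {
    stop("compartment_bounds must be two strictly increasing values")
  }
  if (!point_in_mask(geom$bb_position, geom$mask)) {
    stop("bb_position does not lie inside the cell mask")
  }
  bb_axial <- rotate_to_cell_axis(
    geom$bb_position - geom$center, th)[1, 2]
  if (bb_axial >= b[1]) {
    stop("bb_position must lie in the apical-most compartment (y' < bounds[1])")
  }
  invisible(geom)
}

#' Test whether points fall on TRUE pixels of a mask
#' @param points (x, y) pixel coordinates (0-based), matrix or vector.
#' @param mask logical matrix, rows = y, columns = x.
#' @return logical vector.
#' @export
point_in_mask <- function(points, mask) {
  p <- as_xy_matrix(points)
  col <- round(p[, 1]) + 1L
  row <- round(p[, 2]) + 1L
  ok <- row >= 1L & row <= nrow(mask) & col >= 1L & col <= ncol(mask)
  res <- logical(nrow(p))
  res[ok] <- mask[cbind(row[ok], col[ok])]
  res
}
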