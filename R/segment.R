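#' Segmentation configuration
#'
#' Parameters of the per-frame punctum segmentation: Gaussian blur, min-max
#' normalization to `[0, 1]`, fixed threshold, 4-connected component
#' labelling and a minimum component size. Defaults follow the configuration
#' used for Rab8-punctum tracking: blur sigma 0.1 px (effectively no
#' smoothing, retained verbatim), threshold 0.30 (the working range is
#' 0.29-0.31), minimum size 2 pixels at 210 nm per pixel.
#'
#' @param blur_sigma Gaussian blur sigma in pixels (>= 0; 0 disables).
#' @param threshold threshold on the normalized blurred intensity, in (0, 1).
#' @param min_size minimum component size in pixels (>= 1).
#' @param pixel_size_nm pixel pitch, nm.
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(blur_sigma = 0.1, threshold = 0.30,
                                min_size = 2L, pixel_size_nm = 210) {
  stopifnot(blur_sigma >= 0, threshold > 0, threshold < 1, min_size >= 1,
            pixel_size_nm > 0)
  structure(list(blur_sigma = blur_sigma, threshold = threshold,
                 min_size = as.integer(min_size),
                 pixel_size_nm = pixel_size_nm),
            class = "segmentation_config")
}

# Label 4-connected foreground components via union-find over the foreground
# pixel list (hand-rolled: the detection contract requires 4-connectivity).
label_components4 <- function(fg_rows, fg_cols, h) {
  n <- length(fg_rows)
  if (n == 0L) return(integer(0))
  key <- fg_rows + (fg_cols - 1L) * h
  idx_of <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = idx_of)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  for (i in seq_len(n)) {
    # right neighbour (col + 1) and down neighbour (row + 1)
    for (nk in c(key[i] + h, if (fg_rows[i] < h) key[i] + 1L)) {
      j <- idx_of[[as.character(nk)]]
      if (!is.null(j)) union(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Segment one frame into detections
#'
#' Blurs the frame, min-max normalizes it to `[0, 1]`, thresholds, labels
#' 4-connected components, drops components smaller than `min_size`, and
#' returns one detection per surviving component with its unweighted
#' barycenter in pixels (0-based; x = column, y = row) and in nm.
#'
#' @param frame numeric matrix (rows = y), finite and non-negative.
#' @param config a [segmentation_config()].
#' @return data.frame with columns `x_px`, `y_px`, `x_nm`, `y_nm`,
#'   `pixel_count` and a list-column `pixels` (2-column matrices of 0-based
#'   `(x, y)` pixel coordinates). A constant frame yields zero detections.
#' @export
segment_frame <- function(frame, config = segmentation_config()) {
  stopifnot(is.matrix(frame), all(is.finite(frame)), all(frame >= 0),
            inherits(config, "segmentation_config"))
  img <- frame
  if (config$blur_sigma > 0) {
    img <- gaussian_blur(img, config$blur_sigma)
  }
  rng <- range(img)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      x_nm = numeric(0), y_nm = numeric(0),
                      pixel_count = integer(0))
  empty$pixels <- list()
  if (rng[2] <= rng[1]) return(empty)  # constant frame: normalization undefined
  norm <- (img - rng[1]) / (rng[2] - rng[1])
  fg <- which(norm > config$threshold)
  if (length(fg) == 0L) return(empty)
  h <- nrow(img)
  fg_rows <- ((fg - 1L) %% h) + 1L
  fg_cols <- ((fg - 1L) %/% h) + 1L
  labels <- label_components4(fg_rows, fg_cols, h)
  comp <- split(seq_along(fg), labels)
  keep <- vapply(comp, length, integer(1)) >= config$min_size
  comp <- comp[keep]
  if (length(comp) == 0L) return(empty)
  x0 <- fg_cols - 1L  # 0-based x
  y0 <- fg_rows - 1L  # 0-based y
  res <- data.frame(
    x_px = vapply(comp, function(i) mean(x0[i]), numeric(1)),
    y_px = vapply(comp, function(i) mean(y0[i]), numeric(1)),
    pixel_count = vapply(comp, length, integer(1))
  )
  res$x_nm <- res$x_px * config$pixel_size_nm
  res$y_nm <- res$y_px * config$pixel_size_nm
  res$pixels <- lapply(comp, function(i) cbind(x = x0[i], y = y0[i]))
  # deterministic order: by barycenter (y, then x)
  o <- order(res$y_px, res$x_px)
  res <- res[o, c("x_px", "y_px", "x_nm", "y_nm", "pixel_count", "pixels")]
  rownames(res) <- NULL
  res
}

gaussian_blur <- function(img, sigma) {
  EBImage::gblur(img, sigma = sigma)
}

#' Segment every frame of a stack
#'
#' @param stack a [frame_stack()]; channel 1 is segmented.
#' @param config a [segmentation_config()]; its `pixel_size_nm` defaults to
#'   the stack calibration.
#' @return data.frame of detections with a leading `frame` column (1-based).
#' @export
segment_stack <- function(stack, config = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(config)) {
    config <- segmentation_config(pixel_size_nm = stack$pixel_size_nm)
  }
  dets <- lapply(seq_len(n_frames(stack)), function(t) {
    d <- segment_frame(stack$ch1[t, , ], config)
    if (nrow(d)) d$frame <- t
    d
  })
  dets <- dets[vapply(dets, nrow, integer(1)) > 0]
  if (length(dets) == 0L) {
    out <- data.frame(frame = integer(0), x_px = numeric(0), y_px = numeric(0),
                      x_nm = numeric(0), y_nm = numeric(0),
                      pixel_count = integer(0))
    out$pixels <- list()
    return(out)
  }
  out <- do.call(rbind, dets)
  out <- out[, c("frame", "x_px", "y_px", "x_nm", "y_nm", "pixel_count", "pixels")]
  rownames(out) <- NULL
  out
}
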