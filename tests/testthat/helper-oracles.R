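# Independent brute-force oracles used across the suite.

# All one-to-one partial matchings between rows of `a` and `b`:
# minimum total cost by exhaustive enumeration (matching cost
# w * d^2 within the gate, unmatched costs for the rest).
enumerate_pair_cost <- function(a, b, costs) {
  n <- nrow(a)
  m <- nrow(b)
  app <- costs$appearance_cost
  dis <- costs$disappearance_cost
  if (n == 0L || m == 0L) {
    return(list(objective = n * dis + m * app,
                links = matrix(integer(0), ncol = 2)))
  }
  d2 <- outer(a$x_px, b$x_px, "-")^2 + outer(a$y_px, b$y_px, "-")^2
  pair_cost <- costs$transition_weight * d2
  pair_cost[d2 > costs$gating_radius^2] <- Inf
  best <- n * dis + m * app
  best_links <- matrix(integer(0), ncol = 2)
  for (k in seq_len(min(n, m))) {
    rows <- utils::combn(n, k, simplify = FALSE)
    cols <- utils::combn(m, k, simplify = FALSE)
    perms <- permutations_of(k)
    for (r in rows) for (cc in cols) for (p in seq_len(nrow(perms))) {
      links <- cbind(r, cc[perms[p, ]])
      tot <- sum(pair_cost[links]) + dis * (n - k) + app * (m - k)
      if (tot < best) {
        best <- tot
        best_links <- links
      }
    }
  }
  list(objective = best, links = best_links)
}

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- permutations_of(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Total linking objective of a multi-frame instance by per-pair enumeration
# (the pairwise model factorizes over consecutive frame pairs).
enumerate_linking <- function(detections, costs, n_frames) {
  total <- 0
  links <- list()
  for (t in seq_len(n_frames - 1L)) {
    a <- detections[detections$frame == t, , drop = FALSE]
    b <- detections[detections$frame == t + 1L, , drop = FALSE]
    res <- enumerate_pair_cost(a, b, costs)
    total <- total + res$objective
    links[[t]] <- res$links
  }
  list(objective = total, links = links)
}

# random small linking instance on a fixed seed
random_instance <- function(seed, max_det = 4L, n_frames = 5L, extent = 20) {
  set.seed(seed)
  nf <- sample(2:n_frames, 1)
  rows <- list()
  for (t in seq_len(nf)) {
    k <- sample(0:max_det, 1)
    if (k > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        frame = t, x_px = round(stats::runif(k, 0, extent), 2),
        y_px = round(stats::runif(k, 0, extent), 2))
    }
  }
  det <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), x_px = numeric(0), y_px = numeric(0))
  list(detections = det, n_frames = nf)
}

# Exact two-sided Mann-Whitney p by full permutation enumeration over
# group-label assignments (independent of the package implementation:
# iterates bitmasks rather than combinations).
mwu_permutation_p <- function(a, b) {
  n1 <- length(a)
  n <- n1 + length(b)
  vals <- c(a, b)
  r <- rank(vals)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  obs <- abs(u_of(seq_len(n1)) - mu)
  hits <- 0L
  total <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) != n1) next
    total <- total + 1L
    if (abs(u_of(idx) - mu) >= obs - 1e-9) hits <- hits + 1L
  }
  hits / total
}

# track data.frame from explicit pixel coordinates
px_track <- function(x_px, y_px, pixel_size_nm = 210, pixel_count = NULL,
                     track_id = 1L) {
  d <- data.frame(track_id = track_id, frame = seq_along(x_px),
                  x_px = x_px, y_px = y_px,
                  x_nm = x_px * pixel_size_nm, y_nm = y_px * pixel_size_nm)
  if (!is.null(pixel_count)) d$pixel_count <- pixel_count
  d
}

# well-separated multi-particle truth by simulating independent cells and
# offsetting them laterally on a shared raster
separated_truth <- function(n_particles = 3L, n_frames = 100L, seed = 1L,
                            sigma = 80, spacing_px = 40) {
  geoms <- list()
  truths <- list()
  width_px <- spacing_px * n_particles
  base <- make_geometry(0, 120, width_px)
  for (i in seq_len(n_particles)) {
    mc <- motion_config(n_particles = 1L, sigma_axial = sigma,
                        sigma_lateral = sigma / 2, bb_excursion_prob = 0,
                        mean_lifetime = Inf, birth_rate = 0,
                        seed = seed + i)
    small <- make_geometry(0, 120, 8)
    tr <- simulate_tracks(mc, small, n_frames)
    offset_px <- (i - 1) * spacing_px + spacing_px / 2 -
      small$center[["x"]]
    tr$x_nm <- tr$x_nm + offset_px * 210
    tr$y_nm <- tr$y_nm + (base$center[["y"]] - small$center[["y"]]) * 210
    tr$particle_id <- i
    truths[[i]] <- tr
  }
  truth <- do.call(rbind, truths)
  class(truth) <- c("truth_tracks", "data.frame")
  list(truth = truth, geometry = base)
}
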