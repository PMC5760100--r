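#' Tracking-by-assignment cost configuration
#'
#' Frame-to-frame linking costs: matching detection `i` in frame `t` to
#' detection `j` in frame `t+1` costs `transition_weight * d(i,j)^2` with
#' `d` the pixel distance between barycenters; leaving `i` unmatched costs
#' `disappearance_cost` and leaving `j` unmatched costs `appearance_cost`.
#' Matches beyond `gating_radius` pixels are forbidden. Defaults are the
#' optimized tracking parameters of the reproduced study: merger cap 1,
#' division weight 10 (stored but inert, objects are not divisible),
#' transition weight 3, appearance cost 9, disappearance cost 47.
#'
#' @param transition_weight weight on the squared pixel distance.
#' @param appearance_cost cost of an unmatched detection in the later frame.
#' @param disappearance_cost cost of an unmatched detection in the earlier
#'   frame.
#' @param gating_radius maximum link distance in pixels.
#' @param max_objects_per_merger stored for completeness; must be 1 (no
#'   merging).
#' @param division_weight stored but inert; divisions are never produced.
#' @return an `assignment_costs` list.
#' @export
assignment_costs <- function(transition_weight = 3,
                             appearance_cost = 9,
                             disappearance_cost = 47,
                             gating_radius = 8,
                             max_objects_per_merger = 1L,
                             division_weight = 10) {
  stopifnot(transition_weight >= 0, appearance_cost >= 0,
            disappearance_cost >= 0, gating_radius > 0,
            max_objects_per_merger == 1L, division_weight >= 0)
  structure(list(transition_weight = transition_weight,
                 appearance_cost = appearance_cost,
                 disappearance_cost = disappearance_cost,
                 gating_radius = gating_radius,
                 max_objects_per_merger = 1L,
                 division_weight = division_weight),
            class = "assignment_costs")
}

#' Solve the square linear assignment problem (minimum cost)
#'
#' Shortest-augmenting-path (Hungarian) solver; costs must be finite.
#'
#' @param cost square numeric matrix.
#' @return integer vector `p` with `p[i]` the column assigned to row `i`.
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(is.matrix(cost), ncol(cost) == n, all(is.finite(cost)))
  if (n == 0L) return(integer(0))
  # potentials: u over rows (index i + 1; slot 1 unused), v over columns
  # (index j + 1; slot 1 = virtual column 0)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)    # p[j + 1] = row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- logical(n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[2:(n + 1)])
      cur <- cost[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
      upd <- cur < minv[free_j]
      if (any(upd)) {
        jj <- free_j[upd]
        minv[jj] <- cur[upd]
        way[jj + 1L] <- j0
      }
      k <- which.min(minv[free_j])
      delta <- minv[free_j][k]
      j1 <- free_j[k]
      uj <- which(used)  # indices j + 1
      rows_used <- p[uj]
      u[rows_used + 1L] <- u[rows_used + 1L] + delta
      v[uj] <- v[uj] - delta
      minv[free_j] <- minv[free_j] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  res <- integer(n)
  res[p[2:(n + 1)]] <- seq_len(n)
  res
}

# Optimal links between two frames of detections.
# a, b: data.frames with x_px, y_px. Returns list(links = 2-col matrix of
# (i, j) indices, objective = pairwise assignment objective).
link_pair <- function(a, b, costs) {
  n <- nrow(a)
  m <- nrow(b)
  app <- costs$appearance_cost
  dis <- costs$disappearance_cost
  if (n == 0L && m == 0L) {
    return(list(links = matrix(integer(0), ncol = 2), objective = 0))
  }
  if (n == 0L) {
    return(list(links = matrix(integer(0), ncol = 2), objective = m * app))
  }
  if (m == 0L) {
    return(list(links = matrix(integer(0), ncol = 2), objective = n * dis))
  }
  d2 <- outer(a$x_px, b$x_px, "-")^2 + outer(a$y_px, b$y_px, "-")^2
  trans <- costs$transition_weight * d2
  forbidden <- d2 > costs$gating_radius^2
  big <- app + dis + 1  # never preferable to leaving both unmatched
  trans[forbidden] <- big
  size <- n + m
  cost <- matrix(0, size, size)
  cost[seq_len(n), seq_len(m)] <- trans
  cost[seq_len(n), m + seq_len(n)] <- big
  cost[seq_len(n), m + seq_len(n)][cbind(seq_len(n), seq_len(n))] <- dis
  cost[n + seq_len(m), seq_len(m)] <- big
  cost[n + seq_len(m), seq_len(m)][cbind(seq_len(m), seq_len(m))] <- app
  assign <- solve_assignment(cost)
  li <- which(assign[seq_len(n)] <= m & !forbidden[cbind(seq_len(n),
                pmin(assign[seq_len(n)], m))])
  links <- cbind(i = li, j = assign[li])
  objective <- sum(trans[links]) + dis * (n - nrow(links)) +
    app * (m - nrow(links))
  list(links = links, objective = objective)
}

#' Link per-frame detections into tracks
#'
#' For every consecutive frame pair, solves the minimum-cost bipartite
#' assignment defined by [assignment_costs()] (optimal matching with
#' unmatch costs; no merging, no division, no gap closing: a particle lost
#' for one frame restarts as a new track). Matched chains become tracks.
#'
#' @param detections data.frame from [segment_stack()] (`frame`, `x_px`,
#'   `y_px`, plus any extra columns, carried through).
#' @param costs an [assignment_costs()].
#' @param n_frames total number of frames; defaults to the largest frame
#'   index present.
#' @return data.frame of the same columns plus a leading `track_id`, ordered
#'   by track and frame, with attribute `objective` = total assignment
#'   objective summed over frame pairs.
#' @export
link_tracks <- function(detections, costs = assignment_costs(),
                        n_frames = if (nrow(detections)) max(detections$frame) else 0L) {
  stopifnot(inherits(costs, "assignment_costs"))
  det <- detections
  if (nrow(det) == 0L) {
    out <- cbind(data.frame(track_id = integer(0)), det)
    attr(out, "objective") <- 0
    return(out)
  }
  by_frame <- split(seq_len(nrow(det)), factor(det$frame, levels = seq_len(n_frames)))
  track_of <- integer(nrow(det))
  next_track <- 1L
  for (i in by_frame[[1]]) {
    track_of[i] <- next_track
    next_track <- next_track + 1L
  }
  objective <- 0
  for (t in seq_len(n_frames - 1L)) {
    ia <- by_frame[[t]]
    ib <- by_frame[[t + 1L]]
    res <- link_pair(det[ia, , drop = FALSE], det[ib, , drop = FALSE], costs)
    objective <- objective + res$objective
    matched_b <- rep(FALSE, length(ib))
    if (nrow(res$links)) {
      track_of[ib[res$links[, "j"]]] <- track_of[ia[res$links[, "i"]]]
      matched_b[res$links[, "j"]] <- TRUE
    }
    for (i in ib[!matched_b]) {
      track_of[i] <- next_track
      next_track <- next_track + 1L
    }
  }
  out <- cbind(data.frame(track_id = track_of), det)
  o <- order(out$track_id, out$frame)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "objective") <- objective
  out
}

#' Keep tracks long enough for kinematic analysis
#'
#' Only particles present in at least `min_frames` frames are analyzed
#' (default 10).
#'
#' @param tracks data.frame from [link_tracks()] (long format with
#'   `track_id` and `frame`).
#' @param min_frames minimum number of frames per track.
#' @return the filtered data.frame, original order preserved.
#' @export
filter_tracks <- function(tracks, min_frames = 10L) {
  if (nrow(tracks) == 0L) return(tracks)
  len <- table(tracks$track_id)
  keep <- names(len)[len >= min_frames]
  out <- tracks[as.character(tracks$track_id) %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
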