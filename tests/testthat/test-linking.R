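dets <- function(frame, x, y) data.frame(frame = frame, x_px = x, y_px = y)

test_that("well-separated stationary particles yield one track each", {
  d <- rbind(dets(1, c(0, 20), c(0, 0)),
             dets(2, c(0, 20), c(0, 0)),
             dets(3, c(0, 20), c(0, 0)))
  tr <- link_tracks(d, n_frames = 3)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_equal(as.integer(table(tr$track_id)), c(3L, 3L))
  expect_equal(attr(tr, "objective"), 0)
})

test_that("a vanishing detection ends its track at the disappearance cost", {
  d <- dets(1, 5, 5)
  tr <- link_tracks(d, n_frames = 2)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(attr(tr, "objective"), 47)
})

test_that("an appearing detection starts a new track at the appearance cost", {
  d <- rbind(dets(1, 5, 5), dets(2, c(5, 15), c(5, 5)))
  tr <- link_tracks(d, n_frames = 2)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_equal(attr(tr, "objective"), 9)
})

test_that("links beyond the gating radius are forbidden", {
  # 10 px jump: transition would cost 3 * 100 = 300 and is outside the
  # default 8 px gate; appearance + disappearance (56) wins either way
  d <- rbind(dets(1, 0, 0), dets(2, 10, 0))
  tr <- link_tracks(d, n_frames = 2)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_equal(attr(tr, "objective"), 47 + 9)
  # 4 px jump: 3 * 16 = 48 < 56, the link is made
  d2 <- rbind(dets(1, 0, 0), dets(2, 4, 0))
  tr2 <- link_tracks(d2, n_frames = 2)
  expect_equal(length(unique(tr2$track_id)), 1)
  expect_equal(attr(tr2, "objective"), 48)
})

test_that("the square-assignment solver matches brute force on random costs", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(1:5, 1)
    cost <- matrix(runif(n * n, 0, 10), n, n)
    p <- solve_assignment(cost)
    got <- sum(cost[cbind(seq_len(n), p)])
    perms <- permutations_of(n)
    best <- min(apply(perms, 1, function(q) sum(cost[cbind(seq_len(n), q)])))
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("linker objective and decomposition match exhaustive enumeration", {
  costs <- assignment_costs()
  for (seed in 1:60) {
    inst <- random_instance(seed)
    tr <- link_tracks(inst$detections, costs, n_frames = inst$n_frames)
    oracle <- enumerate_linking(inst$detections, costs, inst$n_frames)
    expect_equal(attr(tr, "objective"), oracle$objective, tolerance = 1e-9)
  }
})

test_that("every detection belongs to exactly one track", {
  inst <- random_instance(123, max_det = 4L, n_frames = 5L)
  tr <- link_tracks(inst$detections, n_frames = inst$n_frames)
  expect_equal(nrow(tr), nrow(inst$detections))
  # one detection per frame per track, frames consecutive
  for (id in unique(tr$track_id)) {
    fr <- tr$frame[tr$track_id == id]
    expect_equal(fr, seq(min(fr), max(fr)))
  }
})

test_that("track filtering keeps only long-enough tracks", {
  d <- rbind(
    do.call(rbind, lapply(1:9, function(t) dets(t, 0, 0))),
    do.call(rbind, lapply(1:10, function(t) dets(t, 30, 0))),
    do.call(rbind, lapply(1:20, function(t) dets(t, 60, 0))))
  tr <- link_tracks(d, n_frames = 20)
  expect_equal(length(unique(tr$track_id)), 3)
  kept <- filter_tracks(tr, 10)
  lens <- sort(as.integer(table(kept$track_id)))
  expect_equal(lens, c(10L, 20L))
  expect_equal(nrow(filter_tracks(tr[0, ], 10)), 0)
  expect_equal(filter_tracks(tr, 1), tr, ignore_attr = TRUE)
})
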