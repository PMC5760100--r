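test_that("displacement is the endpoint distance in nm", {
  expect_equal(displacement(px_track(0, 0)), 0)
  tr <- px_track(c(0, 1, 3), c(0, 5, 4))
  expect_equal(displacement(tr), sqrt(3^2 + 4^2) * 210)  # 3-4-5 triangle
  expect_equal(displacement(tr), 1050)
  # random track equals the direct endpoint formula
  set.seed(1)
  tr2 <- px_track(rnorm(20), rnorm(20))
  expect_equal(displacement(tr2),
               sqrt(sum((tr2[20, c("x_nm", "y_nm")] -
                           tr2[1, c("x_nm", "y_nm")])^2)))
})

test_that("trajectory length sums consecutive steps in um", {
  expect_equal(trajectory_length(px_track(2, 2)), 0)
  # closed 2 px square: trajectory 8 px = 1.68 um, displacement 0
  sq <- px_track(c(0, 2, 2, 0, 0), c(0, 0, 2, 2, 0))
  expect_equal(trajectory_length(sq), 1.68)
  expect_equal(displacement(sq), 0)
  set.seed(2)
  tr <- px_track(rnorm(30), rnorm(30))
  brute <- sum(vapply(2:30, function(i) {
    sqrt(sum((tr[i, c("x_nm", "y_nm")] - tr[i - 1, c("x_nm", "y_nm")])^2))
  }, numeric(1))) / 1000
  expect_equal(trajectory_length(tr), brute)
})

test_that("max speed is the largest consecutive step over the interval", {
  expect_equal(max_speed(px_track(c(0, 1, 2), c(0, 0, 0))), 210)
  steps <- cumsum(c(0, 1, 5, 2))
  expect_equal(max_speed(px_track(steps, steps * 0)), 1050)
  expect_true(is.na(max_speed(px_track(1, 1))))
  # frame interval rescales
  expect_equal(max_speed(px_track(c(0, 1), c(0, 0)), frame_interval_s = 2), 105)
  set.seed(3)
  tr <- px_track(rnorm(25), rnorm(25))
  brute <- max(vapply(2:25, function(i) {
    sqrt(sum((tr[i, c("x_nm", "y_nm")] - tr[i - 1, c("x_nm", "y_nm")])^2))
  }, numeric(1)))
  expect_equal(max_speed(tr), brute)
})

test_that("directionality is the lateral over apico-basal span ratio", {
  expect_equal(directionality(px_track(c(3, 3, 3), c(0, 4, 2)), 0), 0)
  expect_equal(directionality(px_track(c(0, 2), c(0, 2)), 0), 1)
  expect_true(is.na(directionality(px_track(c(0, 5), c(2, 2)), 0)))
})

test_that("directionality is translation invariant and rotation equivariant", {
  set.seed(4)
  for (rep in 1:20) {
    n <- 15
    tr <- px_track(rnorm(n, sd = 2), rnorm(n, sd = 5))
    theta <- runif(1, -pi, pi)
    d0 <- directionality(tr, 0)
    # translate
    tr_shift <- tr
    tr_shift$x_nm <- tr_shift$x_nm + 5000
    tr_shift$y_nm <- tr_shift$y_nm - 3000
    expect_equal(directionality(tr_shift, 0), d0, tolerance = 1e-12)
    # rotate the track into a cell tilted by theta: measuring with that
    # theta recovers the axis-aligned value
    rot <- rotate_to_cell_axis(cbind(tr$x_nm, tr$y_nm), -theta)
    tr_rot <- tr
    tr_rot$x_nm <- rot[, 1]
    tr_rot$y_nm <- rot[, 2]
    expect_equal(directionality(tr_rot, theta), d0, tolerance = 1e-9)
  }
})

test_that("mean area follows the printed pixel-area conversion", {
  tr10 <- px_track(rep(0, 3), rep(0, 3), pixel_count = rep(10L, 3))
  expect_equal(round(mean_area(tr10), 2), 0.44)   # printed rounding
  expect_equal(mean_area(tr10), 0.441)            # exact
  tr1 <- px_track(0, 0, pixel_count = 1L)
  expect_equal(mean_area(tr1), 0.0441)
  tr24 <- px_track(c(0, 0), c(0, 0), pixel_count = c(2L, 4L))
  expect_equal(tr24$pixel_count, c(2L, 4L))
  expect_equal(mean_area(tr24), 3 * 0.0441)
  expect_true(is.na(mean_area(px_track(0, 0))))
})

test_that("BB contact uses an inclusive 3-pixel radius", {
  g <- make_geometry(0, 40, 10)
  bb <- g$bb_position
  exactly3 <- px_track(bb[["x"]] + 3, bb[["y"]])
  expect_true(bb_contacts(exactly3, g)$contacted)
  at4 <- px_track(bb[["x"]] + 4, bb[["y"]])
  expect_false(bb_contacts(at4, g)$contacted)
  # random track agrees with a per-frame distance oracle
  set.seed(5)
  tr <- px_track(bb[["x"]] + rnorm(50, sd = 3), bb[["y"]] + rnorm(50, sd = 3))
  res <- bb_contacts(tr, g)
  d <- sqrt((tr$x_px - bb[["x"]])^2 + (tr$y_px - bb[["y"]])^2)
  expect_equal(res$n_contact_frames, sum(d <= 3))
  expect_equal(res$contacted, any(d <= 3))
})

test_that("kinematic inequalities hold on simulated tracks", {
  g <- make_geometry(0.5, 60, 12)
  tr <- simulate_tracks(motion_config(n_particles = 10L, seed = 6L), g, 100)
  tr$track_id <- tr$particle_id
  m <- track_metrics(filter_tracks(tr, 10), g)
  expect_true(all(m$displacement_nm <= m$trajectory_um * 1000 + 1e-9))
  expect_true(all(m$max_speed_nm_s * (m$n_frames - 1) >=
                    m$displacement_nm - 1e-9))
  expect_true(all(m$directionality >= 0, na.rm = TRUE))
})

test_that("per-cell summaries average eligible tracks and count contacts", {
  m <- data.frame(track_id = 1:2, n_frames = c(12L, 20L),
                  displacement_nm = c(800, 1000), trajectory_um = c(2, 4),
                  max_speed_nm_s = c(500, 700), directionality = c(0.5, 0.7),
                  area_um2 = c(0.3, 0.5), contacted_bb = c(TRUE, FALSE),
                  n_contact_frames = c(3L, 0L))
  s <- summarize_pr(m, cell_id = "c1", condition = "wt")
  expect_equal(s$displacement_nm, 900)
  expect_equal(s$contact_proportion, 0.5)
  expect_equal(s$n_contacting, 1)
  s1 <- summarize_pr(m[1, ])
  expect_equal(s1$displacement_nm, 800)
  expect_true(s1$contact_proportion %in% c(0, 1))
  s0 <- summarize_pr(m[0, ])
  expect_equal(s0$n_tracks, 0)
  expect_true(is.na(s0$displacement_nm))
})

test_that("grand means across cells equal the brute-force two-level average", {
  set.seed(8)
  summaries <- do.call(rbind, lapply(1:13, function(i) {
    m <- data.frame(track_id = 1:4, n_frames = 12L,
                    displacement_nm = runif(4, 500, 1500),
                    trajectory_um = runif(4, 1, 30),
                    max_speed_nm_s = runif(4, 300, 1500),
                    directionality = runif(4), area_um2 = runif(4),
                    contacted_bb = FALSE, n_contact_frames = 0L)
    attr(m, "raw") <- m
    s <- summarize_pr(m, cell_id = paste0("c", i))
    s$brute <- mean(m$displacement_nm)
    s
  }))
  expect_equal(mean(summaries$displacement_nm), mean(summaries$brute))
})
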