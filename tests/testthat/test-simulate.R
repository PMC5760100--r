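geom <- make_geometry(0.3, 60, 12)

test_that("zero-variance walks are stationary with zero displacement", {
  mc <- motion_config(n_particles = 3L, sigma_axial = 0, sigma_lateral = 0,
                      bb_excursion_prob = 0, mean_lifetime = Inf,
                      birth_rate = 0, seed = 5L)
  tr <- simulate_tracks(mc, geom, 20)
  for (id in unique(tr$particle_id)) {
    p <- tr[tr$particle_id == id, ]
    expect_equal(displacement(p), 0)
    expect_equal(trajectory_length(p), 0)
  }
})

test_that("simulation is bit-reproducible given config and seed", {
  mc <- motion_config(seed = 11L)
  t1 <- simulate_tracks(mc, geom, 50)
  t2 <- simulate_tracks(mc, geom, 50)
  expect_identical(t1, t2)
  t3 <- simulate_tracks(motion_config(seed = 12L), geom, 50)
  expect_false(identical(t1, t3))
})

test_that("confined trajectories stay inside the cell mask", {
  mc <- motion_config(n_particles = 6L, sigma_axial = 600,
                      sigma_lateral = 400, seed = 3L)
  for (theta in c(0, -0.9, 1.7)) {
    g <- make_geometry(theta, 50, 10)
    tr <- simulate_tracks(mc, g, 200)
    inside <- point_in_mask(cbind(tr$x_nm / 210, tr$y_nm / 210), g$mask)
    expect_true(all(inside))
  }
})

test_that("without excursions, distant confined particles never touch the BB", {
  # particles start in the inner segment, > 630 nm from the apical BB, and
  # reflection keeps them there
  mc <- motion_config(n_particles = 5L, sigma_axial = 200, sigma_lateral = 100,
                      bb_excursion_prob = 0, mean_lifetime = Inf,
                      birth_rate = 0, seed = 8L)
  tr <- simulate_tracks(mc, geom, 300)
  cc <- contact_config()
  for (id in unique(tr$particle_id)) {
    res <- bb_contacts(tr[tr$particle_id == id, ], geom, cc)
    expect_false(res$contacted)
  }
})

test_that("excursions produce BB contacts", {
  mc <- motion_config(n_particles = 3L, sigma_axial = 100, sigma_lateral = 50,
                      bb_excursion_prob = 0.05, excursion_speed = 2000,
                      mean_lifetime = Inf, birth_rate = 0, seed = 2L)
  tr <- simulate_tracks(mc, geom, 300)
  contacted <- vapply(unique(tr$particle_id), function(id) {
    bb_contacts(tr[tr$particle_id == id, ], geom, contact_config())$contacted
  }, logical(1))
  expect_true(any(contacted))
})

test_that("isotropic unconfined steps have the Rayleigh mean length", {
  sigma <- 300
  mc <- motion_config(n_particles = 20L, sigma_axial = sigma,
                      sigma_lateral = sigma, bb_excursion_prob = 0,
                      mean_lifetime = Inf, birth_rate = 0,
                      confinement = "none", seed = 21L)
  tr <- simulate_tracks(mc, geom, 501)
  steps <- unlist(lapply(split(tr, tr$particle_id), function(p) {
    p <- p[order(p$frame), ]
    sqrt(diff(p$x_nm)^2 + diff(p$y_nm)^2)
  }))
  expect_gte(length(steps), 10000)
  expected <- sigma * sqrt(pi / 2)
  se <- sigma * sqrt((4 - pi) / 2) / sqrt(length(steps))
  expect_lt(abs(mean(steps) - expected), 3 * se)
})

test_that("geometric lifetimes and births change the particle census", {
  mc <- motion_config(n_particles = 10L, mean_lifetime = 20,
                      birth_rate = 0.5, seed = 9L)
  tr <- simulate_tracks(mc, geom, 200)
  lifetimes <- table(tr$particle_id)
  expect_gt(length(lifetimes), 10)       # births happened
  expect_lt(mean(lifetimes), 200)        # deaths happened
  # no gaps within a particle's life
  for (id in unique(tr$particle_id)) {
    fr <- sort(tr$frame[tr$particle_id == id])
    expect_equal(fr, seq(min(fr), max(fr)))
  }
})
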