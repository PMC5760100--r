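test_that("a stationary particle renders at its true position every frame", {
  g <- make_geometry(0, 30, 10)
  truth <- data.frame(particle_id = 1L, frame = 1:5,
                      x_nm = 6 * 210, y_nm = 14 * 210, radius_nm = 150)
  st <- render_video(truth, g, render_config(), n_frames = 5)
  for (t in 1:5) {
    peak <- arrayInd(which.max(st$ch1[t, , ]), dim(st$ch1[t, , ]))
    expect_equal(peak[1, 2] - 1, 6)   # x = column
    expect_equal(peak[1, 1] - 1, 14)  # y = row
  }
})

test_that("integer drift translates frames exactly (zero noise)", {
  g <- make_geometry(0, 30, 10)
  truth <- data.frame(particle_id = 1L, frame = 1:4,
                      x_nm = 7 * 210, y_nm = 10 * 210, radius_nm = 150)
  st <- render_video(truth, g, render_config(drift_per_frame = c(1, 0)),
                     n_frames = 4)
  h <- dim(st$ch1)[2]; w <- dim(st$ch1)[3]
  for (t in 2:4) {
    shifted <- matrix(0, h, w)
    d <- t - 1
    shifted[, (1 + d):w] <- st$ch1[1, , 1:(w - d)]
    expect_equal(st$ch1[t, , ], shifted, tolerance = 1e-12)
  }
})

test_that("drift pushing all content off the raster errors", {
  g <- make_geometry(0, 30, 10)
  truth <- data.frame(particle_id = 1L, frame = 1:50,
                      x_nm = 7 * 210, y_nm = 10 * 210, radius_nm = 150)
  expect_error(
    render_video(truth, g, render_config(drift_per_frame = c(200, 0)),
                 n_frames = 50),
    "off the raster")
})

test_that("the BB channel is static and centred on the basal body", {
  g <- make_geometry(0.4, 40, 10)
  truth <- data.frame(particle_id = 1L, frame = 1:3,
                      x_nm = g$center[["x"]] * 210,
                      y_nm = g$center[["y"]] * 210, radius_nm = 150)
  st <- render_video(truth, g, render_config(), n_frames = 3)
  expect_equal(st$ch2[1, , ], st$ch2[3, , ])
  peak <- arrayInd(which.max(st$ch2[1, , ]), dim(st$ch2[1, , ]))
  expect_equal(peak[1, 2] - 1, round(g$bb_position[["x"]]))
  expect_equal(peak[1, 1] - 1, round(g$bb_position[["y"]]))
})

test_that("noise layers are seeded and reproducible", {
  g <- make_geometry(0, 30, 10)
  truth <- data.frame(particle_id = 1L, frame = 1:3,
                      x_nm = 6 * 210, y_nm = 14 * 210, radius_nm = 150)
  rc <- render_config(poisson_noise = TRUE, gaussian_sd = 3, seed = 13L)
  s1 <- render_video(truth, g, rc, n_frames = 3)
  s2 <- render_video(truth, g, rc, n_frames = 3)
  expect_identical(s1$ch1, s2$ch1)
  expect_true(all(s1$ch1 >= 0))
  s3 <- render_video(truth, g, render_config(poisson_noise = TRUE,
                                             gaussian_sd = 3, seed = 14L),
                     n_frames = 3)
  expect_false(identical(s1$ch1, s3$ch1))
})

test_that("diffuse mutant mode moves signal into the cytoplasm", {
  g <- make_geometry(0, 30, 10)
  truth <- data.frame(particle_id = 1L, frame = 1:2,
                      x_nm = 6 * 210, y_nm = 14 * 210, radius_nm = 150)
  clean <- render_video(truth, g, render_config(cell_background = 0),
                        n_frames = 2)
  diffuse <- render_video(truth, g,
                          render_config(cell_background = 0,
                                        diffuse_fraction = 0.5),
                          n_frames = 2)
  # peak is dimmer, off-particle cytoplasm is brighter
  expect_lt(max(diffuse$ch1[1, , ]), max(clean$ch1[1, , ]))
  far <- g$mask & (clean$ch1[1, , ] < 1e-6)
  expect_gt(mean(diffuse$ch1[1, , ][far]), mean(clean$ch1[1, , ][far]))
})
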