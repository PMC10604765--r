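test_that("evaluate_flow returns the prescribed analytic fields", {
  uni <- flow_model("uniform", peak_speed = 1.0, waveform = steady)
  v <- evaluate_flow(uni, c(1, 5, 9), c(2, 4, 8), t = 0.01, period = 0.1)
  expect_equal(v[, "vx"], rep(1.0, 3))
  expect_equal(v[, "vy"], rep(0, 3))

  # any model at a waveform zero gives a zero vector
  sten <- flow_model("stenotic_jet", peak_speed = 1.5)
  expect_equal(unname(evaluate_flow(sten, 5, 5, t = 0.075, period = 0.1)),
               matrix(0, 1, 2))  # t/T = 0.75, diastole

  # peak axial speed normalization: max over y equals peak * w(s)
  y <- seq(0, 9.8, by = 0.01)
  v_peak <- evaluate_flow(sten, 0, y, t = 0.02, period = 0.1)[, 1]
  expect_equal(max(v_peak), 1.5 * systolic_waveform(0.2), tolerance = 1e-3)
})

test_that("stenotic jet reverses in the posterior recirculation band", {
  sten <- flow_model("stenotic_jet", peak_speed = 1.5)
  band <- recirculation_band(sten)
  expect_true(band[1] > sten$jet_center_y)
  y_mid <- mean(band)
  # at peak systole the recirculation has developed and flow is reversed
  v <- evaluate_flow(sten, 5, y_mid, t = 0.02, period = 0.1)
  expect_lt(v[1, 1], 0)
  # a sign change exists across the shear layer
  y <- seq(sten$jet_center_y, band[2], by = 0.05)
  vx <- evaluate_flow(sten, 5, y, t = 0.02, period = 0.1)[, 1]
  expect_true(any(vx > 0) && any(vx < 0))
})

test_that("evaluate_flow rejects out-of-domain coordinates", {
  uni <- flow_model("uniform")
  expect_error(evaluate_flow(uni, 50, 5, 0, 0.1), class = "bsi_validation_error")
  expect_error(evaluate_flow(uni, 5, -3, 0, 0.1), class = "bsi_validation_error")
})

test_that("advection moves scatterers by v*dt and conserves their count", {
  cfg <- small_imaging()
  uni <- flow_model("uniform", peak_speed = 1.0, waveform = steady)
  cl <- scatterer_cloud(cfg, seed = 3)
  moved <- advect(cl, uni, t = 0, dt = 1 / 6000, period = 0.1)
  inside <- cl$x < fov_extent(cfg)[["x"]] + cl$margin - 0.2
  expect_equal(moved$x[inside] - cl$x[inside],
               rep(1.0 / 6000 * 1000, sum(inside)))  # 0.1667 mm
  expect_equal(length(moved$x), length(cl$x))
  expect_true(all(moved$x <= fov_extent(cfg)[["x"]] + cl$margin + 1e-9))

  none <- flow_model("uniform", peak_speed = 0)
  still <- advect(cl, none, t = 0, dt = 1 / 6000, period = 0.1)
  expect_identical(still$x, cl$x)
  expect_identical(still$y, cl$y)

  expect_error(advect(cl, uni, 0, -1, 0.1), class = "bsi_validation_error")
})

test_that("rendering is deterministic, peaked at scatterers, shift-equivariant", {
  cfg <- small_imaging(noise_sigma = 0)
  # single scatterer at a pixel centre: brightness maximum at that pixel
  one <- structure(list(x = 40 * cfg$pixel_pitch, y = 30 * cfg$pixel_pitch,
                        amp = 1, margin = 1, extent = fov_extent(cfg),
                        density = 1), class = "scatterer_cloud")
  img <- render_frame(one, cfg)
  expect_equal(which(img == max(img), arr.ind = TRUE)[1, ],
               c(row = 31, col = 41))

  cfgn <- small_imaging(noise_sigma = 0.2)
  cl <- scatterer_cloud(cfgn, seed = 5)
  expect_identical(render_frame(cl, cfgn, seed = 9),
                   render_frame(cl, cfgn, seed = 9))

  # rigid integer-pixel cloud shift shifts the image (interior pixels)
  k <- 4L
  a <- render_frame(cl, cfg)
  cl2 <- cl
  cl2$x <- cl$x + k * cfg$pixel_pitch
  b <- render_frame(cl2, cfg)
  interior <- 15:80
  expect_equal(b[interior, interior + k], a[interior, interior],
               tolerance = 1e-6 * max(a))
})

test_that("default scatterer density yields fully developed speckle texture", {
  cfg <- small_imaging(noise_sigma = 0)
  img <- render_frame(scatterer_cloud(cfg, seed = 2), cfg)
  tiles <- expand.grid(i = seq(1, 89, by = 8), j = seq(1, 89, by = 8))
  v <- mapply(function(i, j) stats::var(c(img[i:(i + 7), j:(j + 7)])),
              tiles$i, tiles$j)
  expect_gte(mean(v > 1e-6), 0.99)
})

test_that("generate_cine assembles frames, truth and metadata consistently", {
  cfg <- small_imaging()
  cfg$n_cycles <- 2L
  m <- flow_model("stenotic_jet", peak_speed = 1.2)
  cine <- generate_cine(m, cfg, seed = 4)
  expect_equal(n_frames(cine), 16L)
  expect_equal(dim(cine$truth), c(16L, 96L, 96L, 2L))
  expect_equal(cine$meta$period, cfg$frames_per_cycle / cfg$prf)

  # truth stack equals direct evaluate_flow on the pixel grid (exact)
  co <- cine_coords(cine)
  m2 <- m
  m2$domain <- c(0, max(co$x), 0, max(co$y))
  k <- 3L
  v <- evaluate_flow(m2, 0, co$y, cine$meta$frame_times[k], cine$meta$period)
  expect_identical(cine$truth[k, , 17, 1], v[, 1])
  expect_identical(cine$truth[k, , 17, 2], v[, 2])

  # zero-flow model: all-zero truth, identical consecutive noiseless frames
  cfg0 <- small_imaging(noise_sigma = 0)
  z <- generate_cine(flow_model("uniform", peak_speed = 0), cfg0, seed = 4)
  expect_true(all(z$truth == 0))
  expect_identical(z$tissue[1, , ], z$tissue[2, , ])
})
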