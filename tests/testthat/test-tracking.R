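test_that("integer-lag search matches the brute-force oracle exactly", {
  cfg <- small_imaging(noise_sigma = 0.1)
  set.seed(42)
  for (rep in 1:3) {
    cl <- scatterer_cloud(cfg)
    a <- render_frame(cl, cfg)
    cl$x <- cl$x + runif(length(cl$x), -0.2, 0.2)
    cl$y <- cl$y + runif(length(cl$y), -0.2, 0.2)
    b <- render_frame(cl, cfg)
    tcfg <- tracker_config(kernel_size = 9L, search_radius = 3L,
                           subpixel = "none")
    for (center in list(c(25, 25), c(48, 40), c(70, 66))) {
      got <- match_block(a, b, center, tcfg)
      ora <- oracle_best_lag(a, b, center[1], center[2], h = 4L, radius = 3L)
      expect_equal(c(got$dy, got$dx), c(ora$di, ora$dj))
      expect_equal(got$quality, ora$score, tolerance = 1e-10)
    }
  }
})

test_that("self-match and rigid shifts are recovered", {
  p <- shifted_pair(shift_px = c(0, 0))
  self_int <- match_block(p$a, p$a, c(48, 48),
                          tracker_config(subpixel = "none"))
  expect_equal(c(self_int$dx, self_int$dy), c(0, 0))
  expect_equal(self_int$quality, 1)
  # refinement on real speckle autocorrelation stays within 0.1 px of zero
  self <- match_block(p$a, p$a, c(48, 48))
  expect_lt(max(abs(c(self$dx, self$dy))), 0.1)

  p3 <- shifted_pair(shift_px = c(0, 3))
  m3 <- match_block(p3$a, p3$b, c(48, 48))
  expect_equal(c(m3$dx, m3$dy), c(3, 0), tolerance = 0.02)

  # half-pixel shift: sub-pixel refinement recovers it within 0.25 px
  ph <- shifted_pair(shift_px = c(0, 0.5))
  mh <- match_block(ph$a, ph$b, c(48, 48))
  expect_lt(abs(mh$dx - 0.5), 0.25)

  # antisymmetry: matching b -> a reverses the displacement
  back <- match_block(p3$b, p3$a, c(48, 48))
  expect_lt(abs(back$dx + m3$dx), 0.25)
})

test_that("border kernels are flagged invalid, bad shapes error", {
  p <- shifted_pair()
  expect_false(match_block(p$a, p$b, c(5, 5))$valid)
  expect_error(track_pair(p$a, p$b[1:50, ]), class = "bsi_validation_error")
})

test_that("track_pair fields behave on identical, shifted and noise pairs", {
  p <- shifted_pair(shift_px = c(0, 3), seed = 12)
  imaging <- p$cfg

  ident <- track_pair(p$a, p$a, tracker_config(subpixel = "none"), imaging)
  expect_true(all(ident$dx == 0 & ident$dy == 0))
  expect_true(all(ident$confidence > 0.999))
  ident_sub <- track_pair(p$a, p$a, tracker_config(), imaging)
  expect_true(all(abs(ident_sub$dx) < 0.1 & abs(ident_sub$dy) < 0.1))

  sh <- track_pair(p$a, p$b, tracker_config(), imaging)
  frac <- mean(abs(sh$dx - 3) < 0.25 & abs(sh$dy) < 0.25)
  expect_gte(frac, 0.95)

  set.seed(33)
  n1 <- matrix(rnorm(96 * 96), 96, 96)
  n2 <- matrix(rnorm(96 * 96), 96, 96)
  noise <- track_pair(n1, n2, tracker_config(), imaging)
  expect_lt(mean(noise$confidence), 0.5)
})

test_that("confidence is bounded in [0,1] for arbitrary images", {
  imaging <- small_imaging()
  set.seed(99)
  for (rep in 1:6) {
    a <- matrix(rnorm(96 * 96, sd = sample(c(0.01, 1, 50), 1)), 96, 96)
    b <- switch(1 + rep %% 3,
                a,
                matrix(rnorm(96 * 96), 96, 96),
                a + matrix(rnorm(96 * 96, sd = 2), 96, 96))
    tp <- track_pair(a, b, tracker_config(), imaging)
    expect_true(all(tp$confidence >= 0 & tp$confidence <= 1))
  }
})

test_that("displacements convert to velocities via pitch and PRF", {
  imaging <- imaging_config()  # 0.0825 mm, 6 kHz
  expect_equal(displacement_to_velocity(2.0, imaging), 0.99)
  expect_equal(displacement_to_velocity(0, imaging), 0)
  # a displacement at the default search radius exceeds v_max: the search
  # geometry, not the window, caps reported speeds
  expect_gte(displacement_to_velocity(6, imaging), 2.0)
})

test_that("reported speeds never exceed the velocity-limit search cap", {
  p <- shifted_pair(shift_px = c(2, 5), seed = 21)
  tp <- track_pair(p$a, p$b, tracker_config(v_max = 2.0), p$cfg)
  d_cap <- 2.0 / (p$cfg$prf * p$cfg$pixel_pitch * 1e-3)
  d <- sqrt(tp$dx^2 + tp$dy^2)
  expect_true(all(d <= d_cap + 0.5 * sqrt(2) + 1e-9))
  v <- displacement_to_velocity(tp, p$cfg)
  slack <- 0.5 * p$cfg$pixel_pitch * 1e-3 * p$cfg$prf
  expect_true(all(sqrt(v$vx^2 + v$vy^2) <=
                    tp$radius * p$cfg$pixel_pitch * 1e-3 * p$cfg$prf + slack))
})

test_that("search radius must cover the velocity limit", {
  expect_error(
    track_pair(matrix(0, 96, 96), matrix(0, 96, 96),
               tracker_config(search_radius = 2L, v_max = 2.0),
               imaging_config()),
    class = "bsi_validation_error"
  )
})

test_that("uniform-flow phantoms are recovered within 0.05 m/s", {
  cfg <- small_imaging(noise_sigma = 0)
  m <- flow_model("uniform", peak_speed = 1.2, waveform = steady)
  cine <- generate_cine(m, cfg, seed = 8)
  tr <- track_cine(cine)
  mid <- 4L
  err <- abs(tr$velocity[mid, 30:66, 30:66, 1] - 1.2)
  expect_lt(median(err), 0.05)
})

test_that("saturation_report flags only frames beyond the limit", {
  st <- stenotic_fixture()
  rep_ok <- saturation_report(st$truth$velocity, st$truth$velocity,
                              v_max = 2.0)
  expect_false(any(rep_ok$saturated))  # truth peak 1.5 < 2
  rep_hot <- saturation_report(2.5 * st$truth$velocity,
                               2.5 * st$truth$velocity, v_max = 2.0)
  expect_true(any(rep_hot$saturated))
  expect_equal(rep_hot$true_max, 2.5 * rep_ok$true_max)
})
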