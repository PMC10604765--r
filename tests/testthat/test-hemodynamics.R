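test_that("shear profiles recover analytic gradients", {
  Y <- seq(0, 5, by = 0.05)
  # V = 100 * y with y in m: gradient 100 /s -> tau = 0.35 Pa
  sp <- shear_profile(100 * Y * 1e-3, Y, mu = 0.0035)
  expect_equal(sp$tau, rep(0.35, length(Y)))

  expect_equal(shear_profile(rep(2, 60), seq_len(60), mu = 0.0035)$tau,
               rep(0, 60))

  # V = sin(k y): max |tau| = mu * k within 2% at >= 50 samples/period
  k <- 2 * pi / 2.0  # period 2 mm
  Yf <- seq(0, 4, by = 2.0 / 60)
  spf <- shear_profile(sin(k * Yf), Yf, mu = 0.0035)
  expect_equal(max(abs(spf$tau), na.rm = TRUE), 0.0035 * k * 1e3,
               tolerance = 0.02)
})

test_that("masked samples leave gaps that are not bridged", {
  Y <- seq(0, 3, by = 0.1)
  v <- 0.5 * Y
  mask <- rep(TRUE, length(Y))
  mask[12:14] <- FALSE
  sp <- shear_profile(v, Y, mask = mask)
  expect_true(all(is.na(sp$tau[12:14])))
  expect_false(any(sp$valid[12:14]))
  expect_true(all(is.finite(sp$tau[mask])))
  expect_error(shear_profile(v, Y, mask = c(rep(TRUE, 2), rep(FALSE, 29))),
               class = "bsi_quality_error")
})

test_that("TAWSS matches analytic integrals", {
  T_ <- 0.8
  tt <- seq(0, T_, length.out = 1001)
  const <- wss_series(tt, rep(-1.7, 1001), T_)
  expect_equal(tawss(const), 1.7)

  A <- 2.3
  sine <- wss_series(tt, A * sin(2 * pi * tt / T_), T_)
  expect_equal(tawss(sine), 2 * A / pi, tolerance = 0.005)

  # homogeneity
  twice <- wss_series(tt, 2 * A * sin(2 * pi * tt / T_), T_)
  expect_equal(tawss(twice), 2 * tawss(sine))
})

test_that("OSI analytic values: unidirectional 0, balanced reversal 0.5", {
  T_ <- 1.0
  tt <- seq(0, T_, length.out = 1000)
  pos <- wss_series(tt, 1 + 0.5 * sin(2 * pi * tt), T_)
  expect_equal(osi(pos), 0)  # machine precision: |integral| == integral| |

  bal <- wss_series(tt, sin(2 * pi * tt), T_)
  expect_equal(osi(bal), 0.5, tolerance = 1e-3)

  # |net integral| = half the rectified integral -> OSI 0.25
  half <- wss_series(tt, ifelse(tt < 0.5, 3, -1), T_)
  expect_equal(osi(half), 0.25, tolerance = 5e-3)

  zero <- wss_series(tt, rep(0, 1000), T_)
  expect_error(osi(zero), class = "bsi_quality_error")
})

test_that("OSI stays in [0, 0.5] and is sign-flip invariant (property)", {
  set.seed(20)
  T_ <- 0.7
  tt <- seq(0, T_, length.out = 200)
  worst <- 0
  for (i in 1:300) {
    w <- stats::rnorm(1, 0, 2)
    for (h in 1:3) {
      w <- w + stats::rnorm(1, 0, 1) *
        sin(2 * pi * h * tt / T_ + stats::runif(1, 0, 2 * pi))
    }
    if (all(abs(w) < 1e-12)) next
    s <- wss_series(tt, w, T_)
    o <- osi(s)
    expect_gte(o, 0)
    expect_lte(o, 0.5)
    flip <- wss_series(tt, -w, T_)
    expect_equal(osi(flip), o)
    expect_equal(tawss(flip), tawss(s))
    worst <- max(worst, o)
  }
  expect_lte(worst, 0.5)
})

test_that("quadrature error decreases at the trapezoid rate", {
  # odd sample counts keep the |sin| kink at T/2 on the grid, so the
  # trapezoid error of TAWSS contracts cleanly at O(h^2); OSI of the same
  # series is exact by symmetry and is checked at 0.5 directly
  T_ <- 1.0
  A <- 1.0
  errs <- vapply(c(17, 65, 257), function(n) {
    tt <- seq(0, T_, length.out = n)
    s <- wss_series(tt, A * sin(2 * pi * tt), T_)
    expect_equal(osi(s), 0.5)
    abs(tawss(s) - 2 * A / pi)
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_gt(errs[2] / errs[3], 8)  # ~16 expected for second order
  expect_lt(errs[3], 1e-4)
})

test_that("wall series on steady Poiseuille flow is constant and symmetric", {
  cfg <- imaging_config(frames_per_cycle = 6)
  m <- flow_model("parabolic", peak_speed = 1.0, waveform = steady)
  cine <- generate_cine(m, cfg, seed = 14)
  tc <- truth_cine(cine)
  yc <- m$jet_center_y
  line <- line_profile(6.6, yc - 3.3, 6.6, yc + 3.3)
  wa <- wall_series(tc, line, "anterior")
  wp <- wall_series(tc, line, "posterior")
  expect_lt(max(abs(wa$wss - mean(wa$wss))), 1e-6)
  expect_equal(mean(wa$wss), mean(wp$wss), tolerance = 1e-6)
  expect_gt(mean(wa$wss), 0)  # forward flow: positive WSS at both walls
})

test_that("stenotic posterior wall reverses during systole, anterior does not", {
  st <- stenotic_fixture()
  line <- line_profile(6.56, 1.2, 6.56, 8.6)
  wp <- wall_series(st$truth, line, "posterior")
  wa <- wall_series(st$truth, line, "anterior")
  expect_true(any(wp$wss > 1e-3) && any(wp$wss < -1e-3))
  expect_true(all(wa$wss > -1e-6))

  # an all-masked cine cannot provide wall samples
  dead <- st$truth
  dead$confidence <- array(0, dim(dead$confidence))
  expect_error(wall_series(dead, line, "posterior"),
               class = "bsi_quality_error")
})

test_that("indicators bundle TAWSS and OSI consistently", {
  T_ <- 0.6
  tt <- seq(0, T_, length.out = 800)
  steady_pos <- wss_series(tt, rep(1.3, 800), T_)
  ind <- wss_indicators(steady_pos)
  expect_equal(ind$tawss, 1.3)
  expect_equal(ind$osi, 0)

  A <- 0.9
  sine <- wss_indicators(wss_series(tt, A * sin(2 * pi * tt / T_), T_))
  expect_equal(sine$tawss, 2 * A / pi, tolerance = 0.005)
  expect_equal(sine$osi, 0.5, tolerance = 1e-3)
})

test_that("peak-velocity trace follows the waveform and the line", {
  uni <- flow_model("uniform", peak_speed = 1.0, waveform = steady)
  cfg <- small_imaging()
  cine <- truth_cine(generate_cine(uni, cfg, seed = 6))
  line <- line_profile(4, 1.5, 4, 6.0)
  tr <- peak_velocity_trace(cine, line)
  expect_equal(tr$v_peak, rep(1.0, 8))

  st <- stenotic_fixture()
  trs <- peak_velocity_trace(st$truth, line_profile(6.56, 1.2, 6.56, 8.6))
  expect_equal(trs$phase[which.max(trs$v_peak)], 0.2)
})

test_that("simplified Bernoulli gradient is 4 v^2 mmHg", {
  expect_equal(bernoulli_gradient(3.5), 49)
  expect_equal(bernoulli_gradient(0), 0)
  expect_equal(bernoulli_gradient(1.4), 7.84)
  expect_error(bernoulli_gradient(-1), class = "bsi_validation_error")
})
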