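make_cine <- function(velocity_fun = NULL, conf = 1, n = 40L, frames = 4L,
                      pitch = 0.0825) {
  tissue <- array(runif(frames * n * n), c(frames, n, n))
  vel <- array(0, c(frames, n, n, 2))
  if (!is.null(velocity_fun)) {
    y <- (seq_len(n) - 1) * pitch
    x <- (seq_len(n) - 1) * pitch
    for (k in seq_len(frames)) {
      vel[k, , , 1] <- outer(y, x, function(a, b) {
        rep_len(velocity_fun(a, b), length(a))
      })
    }
  }
  cine_loop(tissue = tissue, velocity = vel,
            confidence = array(conf, c(frames, n, n)),
            pixel_pitch = pitch, prf = 6000, period = frames / 6000,
            frame_times = (seq_len(frames) - 1) / 6000)
}

test_that("grid mapping validates channels and spans the physical extent", {
  cine <- make_cine(n = 100L)
  co <- cine_coords(cine)
  expect_equal(max(co$x), 99 * 0.0825)  # 8.1675 mm
  expect_equal(co$x[1], 0)

  bad <- unclass(cine)
  expect_error(
    map_to_grid(list(tissue = bad$tissue,
                     confidence = bad$confidence + 0.5),
                c(list(pixel_pitch = 0.0825, prf = 6000,
                       period = bad$meta$period,
                       frame_times = bad$meta$frame_times))),
    regexp = "confidence", class = "bsi_validation_error"
  )
  expect_error(
    cine_loop(bad$tissue, pixel_pitch = 0.0825, prf = 6000,
              period = 1, frame_times = rev(bad$meta$frame_times)),
    class = "bsi_validation_error"
  )

  # physical coordinate -> pixel index -> physical coordinate round trip
  px <- round(co$x / 0.0825)
  expect_equal(px * 0.0825, co$x)
})

test_that("profile extraction is exact on linear fields and bounded in confidence", {
  uni <- make_cine(function(y, x) 1.0)
  line <- line_profile(0.5, 0.3, 0.5, 2.9)
  pr <- extract_profile(uni, line, 2)
  expect_equal(pr$v_long, rep(1.0, nrow(pr)))

  lin <- make_cine(function(y, x) 2 * y + 0.5 * x)
  ln2 <- line_profile(0.7, 0.2, 1.9, 3.0, n_samples = 23L)
  pr2 <- extract_profile(lin, ln2, 1)
  s <- seq(0, 1, length.out = 23L)
  expect_equal(pr2$v_long, 2 * (0.2 + s * 2.8) + 0.5 * (0.7 + s * 1.2),
               tolerance = 1e-12)
  expect_equal(diff(pr2$Y_mm), rep(ln2$length / 22, 22))

  set.seed(1)
  rc <- make_cine(function(y, x) 0)
  rc$confidence <- array(runif(length(rc$confidence)), dim(rc$confidence))
  pr3 <- extract_profile(rc, ln2, 1)
  expect_true(all(pr3$confidence >= 0 & pr3$confidence <= 1))

  expect_error(extract_profile(uni, line_profile(0.5, 0.3, 9.0, 2.9), 1),
               class = "bsi_validation_error")
})

test_that("profiles across a stenotic jet change sign at the shear layer", {
  st <- stenotic_fixture()
  line <- line_profile(6.56, 1.2, 6.56, 9.5)
  k <- which.min(abs(cycle_phase(st$cine$meta$frame_times,
                                 st$cine$meta$period) - 0.25))
  pr <- extract_profile(st$truth, line, k)
  expect_true(any(pr$v_long > 0.2) && any(pr$v_long < -0.05))
  sign_changes <- sum(diff(sign(pr$v_long[pr$v_long != 0])) != 0)
  expect_gte(sign_changes, 1)
})

test_that("cycle phase wraps times into [0,1)", {
  expect_equal(cycle_phase(0.2 * 0.8, 0.8), 0.2)
  expect_equal(cycle_phase(1.8 * 0.8, 0.8), 0.8)
  cfg <- small_imaging()
  cine <- generate_cine(flow_model("uniform", peak_speed = 0), cfg, seed = 1)
  ph <- cycle_phase(cine$meta$frame_times, cine$meta$period)
  expect_equal(ph, (0:7) / 8)
  expect_error(cycle_phase(1, 0), class = "bsi_validation_error")
})

test_that("profile export writes the documented CSV columns", {
  cine <- make_cine(function(y, x) y)
  path <- withr::local_tempfile(fileext = ".csv")
  export_profiles(cine, line_profile(0.4, 0.4, 0.4, 2.8), path, frames = 1:2)
  got <- read.csv(path)
  expect_named(got, c("frame", "phase", "Y_mm", "V_long_mps", "V_short_mps",
                      "confidence"))
  expect_equal(sort(unique(got$frame)), 1:2)
})
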