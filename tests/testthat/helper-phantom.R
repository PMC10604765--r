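options(bsiflow.log_level = "quiet")

# Small shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# compact imaging geometry for fast tests (full-size runs live in the
# acceptance suite)
small_imaging <- function(...) {
  imaging_config(n_x = 96, n_y = 96, frames_per_cycle = 8, n_cycles = 1, ...)
}

steady <- function(s) rep(1, length(s))

# a rendered speckle frame pair displaced by an exact integer pixel shift
# (same cloud, moved rigidly)
shifted_pair <- function(shift_px = c(0, 3), seed = 7, noise = 0,
                         cfg = small_imaging(noise_sigma = noise)) {
  cl <- scatterer_cloud(cfg, seed = seed)
  a <- render_frame(cl, cfg, seed = seed + 1)
  cl2 <- cl
  cl2$y <- cl$y + shift_px[1] * cfg$pixel_pitch
  cl2$x <- cl$x + shift_px[2] * cfg$pixel_pitch
  b <- render_frame(cl2, cfg, seed = seed + 1)
  list(a = a, b = b, cfg = cfg)
}

# tracked + truth pair for the default stenotic phantom, small size
stenotic_fixture <- function() {
  fixture("stenotic_small", function() {
    cfg <- imaging_config(frames_per_cycle = 20)
    m <- flow_model("stenotic_jet", peak_speed = 1.5)
    cine <- generate_cine(m, cfg, seed = 11)
    list(model = m, cfg = cfg, cine = cine, truth = truth_cine(cine))
  })
}
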