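#' Imaging configuration for the synthetic speckle phantom
#'
#' Describes the acquisition geometry of a BSI-style cine: pixel pitch,
#' pulse repetition frequency (PRF), image size, the Gaussian point-spread
#' function of the imaging system, and additive brightness noise. Defaults
#' follow a pediatric transesophageal acquisition: 0.0825 mm/pixel and a
#' PRF of 6 kHz.
#'
#' The cardiac period of a generated phantom is
#' `frames_per_cycle / prf`: consecutive tracked frames are one pulse
#' interval apart, so a phantom cycle is deliberately compressed in wall
#' time. All derived quantities are phase-based (t/T) and unaffected.
#'
#' @param pixel_pitch Pixel size in mm/pixel.
#' @param prf Pulse repetition frequency in Hz (frame rate of the tracked
#'   cine).
#' @param n_x,n_y Image width and height in pixels (x = long axis along
#'   columns, y = short axis along rows; row 0 is the anterior side).
#' @param psf_sigma_x,psf_sigma_y Gaussian PSF standard deviations in
#'   pixels.
#' @param noise_sigma Additive Gaussian noise standard deviation, in image
#'   brightness units (speckle mean brightness is of order 5 at the default
#'   scatterer density).
#' @param noise_ramp Optional linear depth ramp of the noise level: the
#'   noise s.d. grows by this factor from the top (anterior) to the bottom
#'   (posterior) row, emulating depth-dependent signal loss. Off (0) by
#'   default.
#' @param frames_per_cycle Frames per cardiac cycle (>= 4).
#' @param n_cycles Number of cardiac cycles in the loop.
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(pixel_pitch = 0.0825, prf = 6000,
                           n_x = 160, n_y = 136,
                           psf_sigma_x = 1.2, psf_sigma_y = 1.2,
                           noise_sigma = 0.05, noise_ramp = 0,
                           frames_per_cycle = 40L, n_cycles = 1L) {
  check_number(pixel_pitch, "pixel_pitch", 0, strict = TRUE)
  check_number(prf, "prf", 0, strict = TRUE)
  check_number(psf_sigma_x, "psf_sigma_x", 0, strict = TRUE)
  check_number(psf_sigma_y, "psf_sigma_y", 0, strict = TRUE)
  check_number(noise_sigma, "noise_sigma", 0)
  check_number(noise_ramp, "noise_ramp", 0)
  check_number(n_x, "n_x", 8)
  check_number(n_y, "n_y", 8)
  check_number(frames_per_cycle, "frames_per_cycle", 4)
  check_number(n_cycles, "n_cycles", 1)
  structure(list(
    pixel_pitch = pixel_pitch, prf = prf,
    n_x = as.integer(n_x), n_y = as.integer(n_y),
    psf_sigma_x = psf_sigma_x, psf_sigma_y = psf_sigma_y,
    noise_sigma = noise_sigma, noise_ramp = noise_ramp,
    frames_per_cycle = as.integer(frames_per_cycle),
    n_cycles = as.integer(n_cycles)
  ), class = "imaging_config")
}

#' Field of view of an imaging configuration, in mm
#' @param cfg An [imaging_config()].
#' @return Named vector `c(x = , y = )`: physical coordinate of the last
#'   pixel centre along each axis (0-based indexing times pixel pitch).
#' @export
fov_extent <- function(cfg) {
  c(x = (cfg$n_x - 1) * cfg$pixel_pitch, y = (cfg$n_y - 1) * cfg$pixel_pitch)
}

#' Systolic waveform envelope
#'
#' Periodic envelope w(t/T) in [0, 1]: a raised-cosine systolic pulse that
#' rises from 0 at t/T = 0, peaks at t/T = 0.2 (peak systole) and returns
#' to 0 at t/T = 0.5; the diastolic half of the cycle carries no outflow.
#'
#' @param s Cycle phase t/T (any real; used modulo 1).
#' @return Envelope values in [0, 1].
#' @export
systolic_waveform <- function(s) {
  s <- s %% 1
  w <- numeric(length(s))
  up <- s <= 0.2
  dn <- s > 0.2 & s <= 0.5
  w[up] <- 0.5 * (1 - cos(pi * s[up] / 0.2))
  w[dn] <- 0.5 * (1 + cos(pi * (s[dn] - 0.2) / 0.3))
  w
}

# smooth top-hat profile with tanh shear layers, in [0, 1]
smooth_tophat <- function(y, center, width, delta) {
  0.5 * (tanh((y - (center - width / 2)) / delta) -
           tanh((y - (center + width / 2)) / delta))
}

smoothstep <- function(u) {
  u <- clamp(u, 0, 1)
  u * u * (3 - 2 * u)
}

#' Analytic pulsatile flow model
#'
#' Time-varying 2D in-plane velocity field used as phantom ground truth.
#' All fields are separable into a spatial profile across the short axis
#' (y) and the periodic systolic envelope [systolic_waveform()]; x is the
#' long axis (flow direction). Four profile kinds are available:
#'
#' * `uniform` — plug flow, same vector everywhere.
#' * `parabolic` — Poiseuille channel flow between walls at
#'   `jet_center_y +/- jet_width/2`.
#' * `tophat_jet` — nearly uniform core with thin tanh shear layers and
#'   minor counter-flow lobes near both walls; the healthy post-valvular
#'   profile.
#' * `stenotic_jet` — narrow jet whose centre drifts anteriorly (toward
#'   low y) by `deflection` mm over systole, with a recirculation zone of
#'   reversed flow on the posterior aspect that develops after early
#'   systole, plus a slight anterior tilt of the jet vector.
#'
#' The axial profile is normalized so that the peak axial speed over the
#' cycle equals `peak_speed`. A weak forward pedestal (a broad Gaussian
#' co-flow around the jet) keeps near-wall velocities nonzero, as in real
#' outflow tracts.
#'
#' @param kind One of `"uniform"`, `"parabolic"`, `"tophat_jet"`,
#'   `"stenotic_jet"`.
#' @param peak_speed Peak axial speed over the cycle, m/s.
#' @param jet_center_y Initial jet centre on the short axis, mm.
#' @param jet_width Jet (or channel) width, mm.
#' @param shear_width Shear-layer thickness (tanh scale), mm.
#' @param deflection Short-axis drift of the jet centre over systole, mm;
#'   negative values deflect anteriorly (toward low y).
#' @param recirculation_strength Reversed-flow strength as a fraction of
#'   `peak_speed`.
#' @param vy_tilt Short-axis tilt of the jet velocity as a fraction of the
#'   axial component (negative = anteriorly directed jet).
#' @param waveform Periodic envelope function of phase `s = t/T` returning
#'   values in [0, 1].
#' @param domain Field-of-view bounds `c(xmin, xmax, ymin, ymax)` in mm
#'   used for domain checks in [evaluate_flow()] and for profile
#'   normalization. Defaults to the default imaging geometry.
#' @return An object of class `flow_model`.
#' @export
flow_model <- function(kind = c("uniform", "parabolic", "tophat_jet",
                                "stenotic_jet"),
                       peak_speed = 1.0,
                       jet_center_y = NULL, jet_width = NULL,
                       shear_width = NULL, deflection = NULL,
                       recirculation_strength = NULL, vy_tilt = NULL,
                       waveform = systolic_waveform,
                       domain = c(0, 13.1175, 0, 9.8175)) {
  kind <- match.arg(kind)
  check_number(peak_speed, "peak_speed", 0)
  stopifnot(is.function(waveform), length(domain) == 4L)
  defaults <- switch(kind,
    uniform = list(jet_center_y = NA, jet_width = NA, shear_width = 1,
                   deflection = 0, recirculation_strength = 0, vy_tilt = 0),
    parabolic = list(jet_center_y = mean(domain[3:4]), jet_width = 7.5,
                     shear_width = 1, deflection = 0,
                     recirculation_strength = 0, vy_tilt = 0),
    tophat_jet = list(jet_center_y = mean(domain[3:4]), jet_width = 5.0,
                      shear_width = 1.2, deflection = -0.4,
                      recirculation_strength = 0.05, vy_tilt = 0),
    stenotic_jet = list(jet_center_y = 4.2, jet_width = 3.0,
                        shear_width = 1.4, deflection = -1.2,
                        recirculation_strength = 0.8, vy_tilt = -0.15)
  )
  m <- list(
    kind = kind, peak_speed = peak_speed,
    jet_center_y = jet_center_y %||% defaults$jet_center_y,
    jet_width = jet_width %||% defaults$jet_width,
    shear_width = shear_width %||% defaults$shear_width,
    deflection = deflection %||% defaults$deflection,
    recirculation_strength =
      recirculation_strength %||% defaults$recirculation_strength,
    vy_tilt = vy_tilt %||% defaults$vy_tilt,
    waveform = waveform, domain = domain,
    pedestal_frac = switch(kind, stenotic_jet = 0.25, tophat_jet = 0.08, 0),
    pedestal_sigma = 4.0,
    recirc_onset = 0.15, recirc_rise = 0.1
  )
  # recirculation lobe geometry (mm)
  if (kind == "stenotic_jet") {
    m$recirc_center <- m$jet_center_y + m$jet_width / 2 + 1.6
    m$recirc_width <- 2.4
    m$recirc_delta <- 1.5
  } else if (kind == "tophat_jet") {
    m$recirc_offset <- m$jet_width / 2 + 1.1
    m$recirc_width <- 1.5
    m$recirc_delta <- 0.9
  }
  # normalize so the peak axial speed at peak systole (t/T = 0.2, with
  # the recirculation state developed as at that phase) equals peak_speed
  yy <- seq(domain[3], domain[4], length.out = 2001L)
  m$scale <- max(forward_profile(m, yy, m$jet_center_y))
  m$peak_norm <- 1
  mm <- structure(m, class = "flow_model")
  m$peak_norm <- max(flow_eval(mm, 0, yy, 0.2, 1)[, 1]) / (peak_speed *
                                                             mm$waveform(0.2))
  if (!is.finite(m$peak_norm) || m$peak_norm <= 0) m$peak_norm <- 1
  structure(m, class = "flow_model")
}

# forward (unreversed) axial profile at jet centre yc, unnormalized
forward_profile <- function(m, y, yc) {
  switch(m$kind,
    uniform = rep(1, length(y)),
    parabolic = pmax(0, 1 - ((y - yc) / (m$jet_width / 2))^2),
    smooth_tophat(y, yc, m$jet_width, m$shear_width) +
      m$pedestal_frac * exp(-((y - yc) / m$pedestal_sigma)^2)
  )
}

# development ramp of the recirculation zone: absent in early systole
# (the near-wall flow is then a weak forward co-flow), fully formed by
# late systole
recirc_ramp <- function(m, s) {
  clamp((s %% 1 - m$recirc_onset) / m$recirc_rise, 0, 1)
}

# jet-centre drift over systole
jet_center_at <- function(m, s) {
  m$jet_center_y + m$deflection * smoothstep(((s %% 1) - 0.1) / 0.35)
}

# core evaluation without domain checks (used by advection, where
# scatterers live in a margin outside the field of view)
flow_eval <- function(m, x, y, t, period) {
  s <- (t / period) %% 1
  w <- m$waveform(s)
  if (m$kind %in% c("uniform", "parabolic")) {
    u <- forward_profile(m, y, m$jet_center_y) / m$scale
    return(cbind(vx = m$peak_speed * w * u, vy = rep(0, length(u))))
  }
  yc <- jet_center_at(m, s)
  fwd <- forward_profile(m, y, yc) / m$scale
  rev <- if (m$kind == "stenotic_jet") {
    smooth_tophat(y, m$recirc_center, m$recirc_width, m$recirc_delta)
  } else {
    smooth_tophat(y, yc - m$recirc_offset, m$recirc_width, m$recirc_delta) +
      smooth_tophat(y, yc + m$recirc_offset, m$recirc_width, m$recirc_delta)
  }
  u <- (fwd - m$recirculation_strength * recirc_ramp(m, s) * rev) /
    m$peak_norm
  vx <- m$peak_speed * w * u
  jet <- smooth_tophat(y, yc, m$jet_width, m$shear_width) /
    (m$scale * m$peak_norm)
  vy <- m$vy_tilt * m$peak_speed * w * jet
  cbind(vx = vx, vy = vy)
}

#' Evaluate a flow model at physical coordinates
#'
#' Returns the ground-truth in-plane velocity of a [flow_model()] at the
#' given positions and time. Positions must lie inside the model's domain
#' (field of view).
#'
#' @param model A [flow_model()].
#' @param x,y Physical coordinates in mm (vectors, recycled to a common
#'   length).
#' @param t Time in seconds.
#' @param period Cardiac period T in seconds.
#' @return A two-column matrix `(vx, vy)` in m/s, one row per position.
#' @export
evaluate_flow <- function(model, x, y, t, period) {
  stopifnot(inherits(model, "flow_model"))
  check_number(period, "period", 0, strict = TRUE)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  d <- model$domain
  if (any(x < d[1] - 1e-9 | x > d[2] + 1e-9 |
            y < d[3] - 1e-9 | y > d[4] + 1e-9)) {
    bsi_validation_error("coordinates outside the model's field of view")
  }
  v <- flow_eval(model, x, y, t, period)
  if (!all(is.finite(v))) bsi_validation_error("non-finite velocity")
  v
}

#' Recirculation band of a stenotic jet model
#'
#' Short-axis interval (mm) occupied by the posterior reversed-flow zone;
#' the axial velocity is negative there once the recirculation has
#' developed (from just after early systole onward).
#'
#' @param model A stenotic-jet [flow_model()].
#' @return Numeric `c(lo, hi)` in mm.
#' @export
recirculation_band <- function(model) {
  stopifnot(inherits(model, "flow_model"))
  if (model$kind != "stenotic_jet") {
    bsi_validation_error("recirculation_band applies to stenotic_jet models")
  }
  c(model$recirc_center - model$recirc_width / 2,
    model$recirc_center + model$recirc_width / 2)
}

#' Random point-scatterer cloud for speckle rendering
#'
#' Seeds scatterers uniformly over the field of view plus a margin, with
#' Rayleigh-distributed reflectivities (unit mean), producing fully
#' developed speckle at the default density of 4 scatterers per PSF
#' resolution-cell area.
#'
#' @param cfg An [imaging_config()].
#' @param density Scatterers per mm^2; default 4 per PSF area
#'   (2 * pi * sigma_x * sigma_y pixels^2).
#' @param margin Margin around the field of view in mm; must exceed the
#'   maximum per-frame displacement. Default 1 mm.
#' @param seed Optional integer seed (uses the current RNG stream when
#'   `NULL`).
#' @return An object of class `scatterer_cloud`.
#' @export
scatterer_cloud <- function(cfg, density = NULL, margin = 1.0, seed = NULL) {
  stopifnot(inherits(cfg, "imaging_config"))
  psf_area_mm2 <- 2 * pi * cfg$psf_sigma_x * cfg$psf_sigma_y *
    cfg$pixel_pitch^2
  density <- density %||% (4 / psf_area_mm2)
  check_number(density, "density", 0, strict = TRUE)
  ext <- fov_extent(cfg)
  gen <- function() {
    area <- (ext["x"] + 2 * margin) * (ext["y"] + 2 * margin)
    n <- max(16L, as.integer(round(density * area)))
    list(
      x = runif(n, -margin, ext[["x"]] + margin),
      y = runif(n, -margin, ext[["y"]] + margin),
      amp = rayleigh_amp(n)
    )
  }
  p <- if (is.null(seed)) gen() else with_seed(seed, gen())
  structure(list(x = p$x, y = p$y, amp = p$amp, margin = margin,
                 extent = ext, density = density),
            class = "scatterer_cloud")
}

# Rayleigh amplitudes with unit mean
rayleigh_amp <- function(n) sqrt(2 / pi) * sqrt(-2 * log(runif(n)))

#' Advect a scatterer cloud through one frame interval
#'
#' Moves every scatterer by the local flow velocity over `dt` using a
#' midpoint (RK2) step. Scatterers leaving the margin are wrapped to the
#' opposite edge (re-seeded at the inflow side for forward flow) and get
#' fresh reflectivities drawn from the current RNG stream; the scatterer
#' count is conserved.
#'
#' @param cloud A [scatterer_cloud()].
#' @param model A [flow_model()].
#' @param t Time at the start of the step, s.
#' @param dt Step length, s (one pulse interval, 1/prf).
#' @param period Cardiac period, s.
#' @return The advected `scatterer_cloud`.
#' @export
advect <- function(cloud, model, t, dt, period) {
  stopifnot(inherits(cloud, "scatterer_cloud"), inherits(model, "flow_model"))
  if (!is.numeric(dt) || dt <= 0) bsi_validation_error("'dt' must be > 0")
  # velocities in m/s, positions in mm
  v1 <- flow_eval(model, cloud$x, cloud$y, t, period)
  xm <- cloud$x + v1[, 1] * 1000 * dt / 2
  ym <- cloud$y + v1[, 2] * 1000 * dt / 2
  v2 <- flow_eval(model, xm, ym, t + dt / 2, period)
  x <- cloud$x + v2[, 1] * 1000 * dt
  y <- cloud$y + v2[, 2] * 1000 * dt
  m <- cloud$margin
  spanx <- cloud$extent[["x"]] + 2 * m
  spany <- cloud$extent[["y"]] + 2 * m
  out <- x > cloud$extent[["x"]] + m | x < -m |
    y > cloud$extent[["y"]] + m | y < -m
  if (any(out)) {
    x[out] <- ((x[out] + m) %% spanx) - m
    y[out] <- ((y[out] + m) %% spany) - m
    cloud$amp[out] <- rayleigh_amp(sum(out))
  }
  cloud$x <- x
  cloud$y <- y
  cloud
}

#' Render one speckle frame from a scatterer cloud
#'
#' The brightness image is the sum of Gaussian point-spread functions
#' centred at the scatterer positions (mm mapped to pixels via the pixel
#' pitch), scaled by reflectivity, plus seeded additive Gaussian noise.
#' Rendering is deterministic for a fixed seed.
#'
#' @param cloud A [scatterer_cloud()].
#' @param cfg An [imaging_config()].
#' @param seed Integer seed for the noise; `NULL` uses the current RNG
#'   stream.
#' @return An `n_y x n_x` brightness matrix.
#' @export
render_frame <- function(cloud, cfg, seed = NULL) {
  stopifnot(inherits(cloud, "scatterer_cloud"), inherits(cfg, "imaging_config"))
  if (length(cloud$x) == 0L) bsi_validation_error("empty scatterer cloud")
  img <- cpp_render(cloud$x / cfg$pixel_pitch, cloud$y / cfg$pixel_pitch,
                    cloud$amp, cfg$n_y, cfg$n_x,
                    cfg$psf_sigma_x, cfg$psf_sigma_y)
  if (cfg$noise_sigma > 0) {
    addnoise <- function() {
      nz <- matrix(rnorm(cfg$n_y * cfg$n_x), cfg$n_y, cfg$n_x)
      if (cfg$noise_ramp > 0) {
        ramp <- 1 + cfg$noise_ramp * (seq_len(cfg$n_y) - 1) / (cfg$n_y - 1)
        nz <- nz * ramp
      }
      img + cfg$noise_sigma * nz
    }
    img <- if (is.null(seed)) addnoise() else with_seed(seed, addnoise())
  }
  img
}

#' Generate a synthetic speckle cine loop with ground truth
#'
#' Runs the full phantom: seeds a scatterer cloud, renders
#' `frames_per_cycle * n_cycles` speckle frames while advecting the cloud
#' through the flow at the pulse repetition interval, and samples the
#' analytic flow on the pixel grid at every frame time as the ground-truth
#' velocity stack. The cardiac period is `frames_per_cycle / prf`.
#'
#' @param model A [flow_model()]; its domain is reset to the imaging field
#'   of view.
#' @param cfg An [imaging_config()].
#' @param seed Integer seed; the whole loop is deterministic given it.
#' @return A [cine_loop()] with the tissue channel and a `truth` velocity
#'   stack (`T_f x n_y x n_x x 2`, m/s); velocity and confidence channels
#'   are empty until tracked.
#' @export
generate_cine <- function(model, cfg, seed = 1L) {
  stopifnot(inherits(model, "flow_model"), inherits(cfg, "imaging_config"))
  ext <- fov_extent(cfg)
  model$domain <- c(0, ext[["x"]], 0, ext[["y"]])
  period <- cfg$frames_per_cycle / cfg$prf
  dt <- 1 / cfg$prf
  n_frames <- cfg$frames_per_cycle * cfg$n_cycles
  times <- (seq_len(n_frames) - 1) * dt
  y_mm <- (seq_len(cfg$n_y) - 1) * cfg$pixel_pitch
  tissue <- array(0, c(n_frames, cfg$n_y, cfg$n_x))
  truth <- array(0, c(n_frames, cfg$n_y, cfg$n_x, 2))
  with_seed(seed, {
    cloud <- scatterer_cloud(cfg)
    for (k in seq_len(n_frames)) {
      tissue[k, , ] <- render_frame(cloud, cfg)
      v <- flow_eval(model, rep(0, cfg$n_y), y_mm, times[k], period)
      truth[k, , , 1] <- matrix(v[, 1], cfg$n_y, cfg$n_x)
      truth[k, , , 2] <- matrix(v[, 2], cfg$n_y, cfg$n_x)
      if (k < n_frames) cloud <- advect(cloud, model, times[k], dt, period)
    }
  })
  bsi_log("info", "simulated ", n_frames, " frames (",
          cfg$n_y, "x", cfg$n_x, "), period ", signif(period, 4), " s")
  cine_loop(tissue = tissue, pixel_pitch = cfg$pixel_pitch, prf = cfg$prf,
            period = period, frame_times = times, truth = truth)
}
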