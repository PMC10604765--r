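#' Multichannel BSI cine loop
#'
#' The central data container: a time-ordered stack of co-registered
#' channels on one pixel grid — tissue brightness, in-plane velocity
#' (long-axis vx, short-axis vy, m/s), and a block-matching confidence
#' level in [0, 1] — plus acquisition metadata. Physical coordinates are
#' 0-based pixel indices times the pixel pitch, with the origin at the
#' image's top-left (anterior) corner: `x = col * pitch`,
#' `y = row * pitch` (mm).
#'
#' Phantom-generated loops additionally carry a `truth` stack with the
#' analytic velocity field sampled on the same grid.
#'
#' @param tissue `T_f x n_y x n_x` brightness array.
#' @param velocity Optional `T_f x n_y x n_x x 2` velocity array (m/s),
#'   components `(vx, vy)`.
#' @param confidence Optional `T_f x n_y x n_x` confidence array in [0, 1].
#' @param pixel_pitch Pixel size, mm/pixel.
#' @param prf Pulse repetition frequency, Hz.
#' @param period Cardiac period T, s.
#' @param frame_times Strictly increasing frame times, s (length `T_f`).
#' @param truth Optional ground-truth velocity array, same shape as
#'   `velocity`.
#' @return A validated object of class `cine_loop`.
#' @export
cine_loop <- function(tissue, velocity = NULL, confidence = NULL,
                      pixel_pitch, prf, period, frame_times, truth = NULL) {
  cine <- structure(list(
    tissue = tissue, velocity = velocity, confidence = confidence,
    meta = list(pixel_pitch = pixel_pitch, prf = prf, period = period,
                frame_times = as.numeric(frame_times)),
    truth = truth
  ), class = "cine_loop")
  validate_cine(cine)
}

#' Validate a cine loop's channels and metadata
#'
#' Checks shape agreement across channels, the [0, 1] confidence range,
#' finite positive metadata and strictly increasing frame times. Called by
#' [cine_loop()] and [read_cine()]; errors name the offending channel.
#'
#' @param cine A `cine_loop`.
#' @return The validated `cine_loop`, invisibly usable in pipelines.
#' @export
validate_cine <- function(cine) {
  if (!inherits(cine, "cine_loop")) {
    bsi_validation_error("not a cine_loop object")
  }
  d <- dim(cine$tissue)
  if (is.null(d) || length(d) != 3L) {
    bsi_validation_error("channel 'tissue' must be a T_f x n_y x n_x array")
  }
  if (!all(is.finite(cine$tissue))) {
    bsi_validation_error("channel 'tissue' contains non-finite values")
  }
  for (nm in c("velocity", "truth")) {
    v <- cine[[nm]]
    if (!is.null(v)) {
      dv <- dim(v)
      if (length(dv) != 4L || !all(dv == c(d, 2L))) {
        bsi_validation_error(paste0(
          "channel '", nm, "' must be a T_f x n_y x n_x x 2 array matching tissue"
        ))
      }
      if (!all(is.finite(v))) {
        bsi_validation_error(paste0("channel '", nm, "' contains non-finite values"))
      }
    }
  }
  if (!is.null(cine$confidence)) {
    dc <- dim(cine$confidence)
    if (length(dc) != 3L || !all(dc == d)) {
      bsi_validation_error("channel 'confidence' must match the tissue shape")
    }
    if (any(!is.finite(cine$confidence)) ||
          any(cine$confidence < 0) || any(cine$confidence > 1)) {
      bsi_validation_error("channel 'confidence' must lie in [0, 1]")
    }
  }
  m <- cine$meta
  check_number(m$pixel_pitch %||% NA, "pixel_pitch", 0, strict = TRUE)
  check_number(m$prf %||% NA, "prf", 0, strict = TRUE)
  check_number(m$period %||% NA, "period", 0, strict = TRUE)
  ft <- m$frame_times
  if (length(ft) != d[1] || any(!is.finite(ft)) || any(diff(ft) <= 0)) {
    bsi_validation_error(
      "frame_times must be strictly increasing and match the frame count"
    )
  }
  cine
}

#' Assemble raw channel arrays into a validated cine loop
#'
#' Maps raw multichannel data onto the physical 2D grid defined by the
#' metadata (`x = col * pitch`, `y = row * pitch`, 0-based) and validates
#' all invariants. Thin named wrapper over [cine_loop()] matching the
#' acquisition-side mapping step.
#'
#' @param raw Named list with `tissue` and optionally `velocity`,
#'   `confidence`, `truth` arrays.
#' @param meta Named list with `pixel_pitch`, `prf`, `period`,
#'   `frame_times`.
#' @return A `cine_loop`.
#' @export
map_to_grid <- function(raw, meta) {
  cine_loop(tissue = raw$tissue, velocity = raw$velocity,
            confidence = raw$confidence,
            pixel_pitch = meta$pixel_pitch, prf = meta$prf,
            period = meta$period, frame_times = meta$frame_times,
            truth = raw$truth)
}

#' Physical grid coordinates of a cine loop
#' @param cine A `cine_loop`.
#' @return List with vectors `x` (length n_x) and `y` (length n_y), mm.
#' @export
cine_coords <- function(cine) {
  d <- dim(cine$tissue)
  p <- cine$meta$pixel_pitch
  list(x = (seq_len(d[3]) - 1) * p, y = (seq_len(d[2]) - 1) * p)
}

#' Number of frames in a cine loop
#' @param cine A `cine_loop`.
#' @return Integer frame count.
#' @export
n_frames <- function(cine) dim(cine$tissue)[1]

#' Swap the ground-truth stack into the velocity channel
#'
#' Returns a copy of a phantom cine whose velocity channel is the analytic
#' ground truth and whose confidence is 1 everywhere — the reference
#' against which tracked quantities are compared.
#'
#' @param cine A phantom `cine_loop` carrying a `truth` stack.
#' @return A `cine_loop`.
#' @export
truth_cine <- function(cine) {
  validate_cine(cine)
  if (is.null(cine$truth)) {
    bsi_validation_error("cine carries no ground-truth stack")
  }
  cine$velocity <- cine$truth
  cine$confidence <- array(1, dim(cine$tissue))
  cine
}

#' Sampling line across the field of view
#'
#' A straight line between two physical points, sampled uniformly; used
#' for velocity profiles, shear profiles and peak-velocity traces. The
#' arclength coordinate Y runs from the anterior endpoint (smaller y) to
#' the posterior endpoint; endpoints are reordered if needed.
#'
#' @param x0,y0,x1,y1 Endpoints in mm.
#' @param n_samples Number of samples; default
#'   `ceil(length / pixel_pitch) + 1` resolved when the line is applied to
#'   a cine (stored as `NULL` until then).
#' @return An object of class `line_profile`.
#' @export
line_profile <- function(x0, y0, x1, y1, n_samples = NULL) {
  for (v in list(x0, y0, x1, y1)) check_number(v, "endpoint", -Inf)
  if (y1 < y0) {
    tmp <- c(x0, y0); x0 <- x1; y0 <- y1; x1 <- tmp[1]; y1 <- tmp[2]
  }
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (len <= 0) bsi_validation_error("line endpoints coincide")
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1, length = len,
                 n_samples = n_samples),
            class = "line_profile")
}

line_samples <- function(line, pitch) {
  n <- line$n_samples %||% (ceiling(line$length / pitch) + 1)
  u <- seq(0, 1, length.out = n)
  list(x = line$x0 + u * (line$x1 - line$x0),
       y = line$y0 + u * (line$y1 - line$y0),
       Y = u * line$length, n = n)
}

# bilinear sampling of one image at fractional 0-based pixel coordinates;
# exact for fields linear (or bilinear) in x and y
bilinear_sample <- function(img, px, py) {
  ny <- nrow(img); nx <- ncol(img)
  j0 <- clamp(floor(px), 0, nx - 2); i0 <- clamp(floor(py), 0, ny - 2)
  fx <- px - j0; fy <- py - i0
  i0 <- i0 + 1; j0 <- j0 + 1  # to 1-based
  (1 - fx) * (1 - fy) * img[cbind(i0, j0)] +
    fx * (1 - fy) * img[cbind(i0, j0 + 1)] +
    (1 - fx) * fy * img[cbind(i0 + 1, j0)] +
    fx * fy * img[cbind(i0 + 1, j0 + 1)]
}

#' Sample cine channels along a line
#'
#' Bilinearly interpolates the velocity and confidence channels of one
#' frame at evenly spaced points along a [line_profile()]. Bilinear
#' interpolation is exact for fields linear in (x, y), and keeps the
#' confidence channel inside [0, 1] (convex combination).
#'
#' @param cine A tracked (or truth-filled) `cine_loop`.
#' @param line A [line_profile()].
#' @param frame Frame index (1-based).
#' @return A data.frame with columns `Y_mm`, `v_long`, `v_short`,
#'   `confidence`.
#' @export
extract_profile <- function(cine, line, frame) {
  validate_cine(cine)
  if (is.null(cine$velocity)) {
    bsi_validation_error("cine has no velocity channel; track it first")
  }
  d <- dim(cine$tissue)
  p <- cine$meta$pixel_pitch
  s <- line_samples(line, p)
  px <- s$x / p
  py <- s$y / p
  if (any(px < 0 | px > d[3] - 1 | py < 0 | py > d[2] - 1)) {
    bsi_validation_error("profile line leaves the field of view")
  }
  if (frame < 1 || frame > d[1]) bsi_validation_error("frame index out of range")
  conf <- if (is.null(cine$confidence)) rep(1, s$n) else {
    bilinear_sample(cine$confidence[frame, , ], px, py)
  }
  data.frame(
    Y_mm = s$Y,
    v_long = bilinear_sample(cine$velocity[frame, , , 1], px, py),
    v_short = bilinear_sample(cine$velocity[frame, , , 2], px, py),
    confidence = conf
  )
}

#' Cardiac cycle phase of frame times
#'
#' @param times Frame times, s.
#' @param period Cardiac period T, s (> 0).
#' @return Phases `(t mod T) / T` in [0, 1).
#' @export
cycle_phase <- function(times, period) {
  check_number(period, "period", 0, strict = TRUE)
  (times %% period) / period
}

#' Export line profiles of a cine to CSV
#'
#' Writes one row per (frame, sample): columns `frame`, `phase`, `Y_mm`,
#' `V_long_mps`, `V_short_mps`, `confidence`.
#'
#' @param cine A tracked `cine_loop`.
#' @param line A [line_profile()].
#' @param path Output CSV path.
#' @param frames Frame indices to export (default all).
#' @return The path, invisibly.
#' @export
export_profiles <- function(cine, line, path, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(cine))
  ph <- cycle_phase(cine$meta$frame_times, cine$meta$period)
  rows <- lapply(frames, function(k) {
    pr <- extract_profile(cine, line, k)
    data.frame(frame = k, phase = ph[k], Y_mm = pr$Y_mm,
               V_long_mps = pr$v_long, V_short_mps = pr$v_short,
               confidence = pr$confidence)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cine_loop <- function(x, ...) {
  d <- dim(x$tissue)
  cat("<cine_loop> ", d[1], " frames, ", d[2], "x", d[3], " px, pitch ",
      x$meta$pixel_pitch, " mm, PRF ", x$meta$prf, " Hz, period ",
      signif(x$meta$period, 4), " s\n", sep = "")
  cat("  channels:", paste(c("tissue",
                             if (!is.null(x$velocity)) "velocity",
                             if (!is.null(x$confidence)) "confidence",
                             if (!is.null(x$truth)) "truth"),
                           collapse = ", "), "\n")
  invisible(x)
}
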