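#' Shear-stress profile along a sampling line
#'
#' Computes the long-axis shear stress `tau = mu * dV/dy` (Pa) from a
#' velocity profile sampled at uniform spacing: central differences in the
#' interior, one-sided differences at the ends of each contiguous run of
#' valid samples. Samples failing the confidence mask are excluded and the
#' gap is not bridged — the stress is undefined (NA) there, and
#' differences are never taken across a gap.
#'
#' @param v_long Long-axis velocity samples, m/s.
#' @param Y Arclength coordinate of the samples, mm (uniformly spaced).
#' @param mu Dynamic viscosity, Pa s; default 0.0035 (blood, Newtonian).
#' @param mask Logical vector of confidence-passing samples (default all).
#' @return data.frame with `Y_mm`, `tau` (Pa, NA where undefined) and
#'   `valid`.
#' @export
shear_profile <- function(v_long, Y, mu = 0.0035, mask = NULL) {
  n <- length(v_long)
  stopifnot(length(Y) == n)
  mask <- mask %||% rep(TRUE, n)
  mask <- mask & is.finite(v_long)
  if (sum(mask) < 3L) {
    bsi_quality_error("fewer than 3 valid samples in the shear profile")
  }
  dy <- diff(Y)
  if (any(abs(dy - dy[1]) > 1e-9 * abs(dy[1]))) {
    bsi_validation_error("shear_profile requires uniform Y spacing")
  }
  h <- dy[1] * 1e-3  # mm -> m
  tau <- rep(NA_real_, n)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < 2L) next
    i0 <- starts[k]; i1 <- ends[k]
    idx <- i0:i1
    g <- numeric(length(idx))
    if (length(idx) > 2L) {
      mid <- 2:(length(idx) - 1L)
      g[mid] <- (v_long[idx[mid] + 1L] - v_long[idx[mid] - 1L]) / (2 * h)
    }
    g[1] <- (v_long[i0 + 1L] - v_long[i0]) / h
    g[length(idx)] <- (v_long[i1] - v_long[i1 - 1L]) / h
    tau[idx] <- mu * g
  }
  data.frame(Y_mm = Y, tau = tau, valid = mask & !is.na(tau))
}

#' Wall shear stress time series over one cardiac cycle
#'
#' Signed WSS at a fixed wall location as a function of time. The series
#' must span exactly one period; when the samples stop one frame short of
#' the period (the usual cine case, frames at k/T_f), the cycle is closed
#' by periodic continuation — the first sample is appended at
#' `t0 + period`. Non-finite samples are dropped.
#'
#' @param times Sample times, s.
#' @param wss Signed wall shear stress, Pa.
#' @param period Cardiac period T, s.
#' @return An object of class `wss_series`.
#' @export
wss_series <- function(times, wss, period) {
  check_number(period, "period", 0, strict = TRUE)
  keep <- is.finite(times) & is.finite(wss)
  times <- times[keep]; wss <- wss[keep]
  o <- order(times)
  times <- times[o]; wss <- wss[o]
  if (length(times) < 4L) {
    bsi_validation_error("wss_series needs at least 4 valid samples")
  }
  span <- times[length(times)] - times[1]
  if (span > period * (1 + 1e-9)) {
    bsi_validation_error("wss_series must cover exactly one period")
  }
  if (span < period) {  # close the cycle by periodicity
    times <- c(times, times[1] + period)
    wss <- c(wss, wss[1])
  }
  structure(list(times = times, wss = wss, period = period),
            class = "wss_series")
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' `TAWSS = (1/T) * integral_0^T |WSS| dt`, evaluated by the composite
#' trapezoidal rule on the actual (possibly non-uniform) sample times.
#'
#' @param series A [wss_series()].
#' @return TAWSS in Pa (non-negative).
#' @export
tawss <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  trapz(series$times, abs(series$wss)) / series$period
}

#' Oscillatory shear index (OSI)
#'
#' `OSI = 0.5 * (1 - |integral WSS dt| / integral |WSS| dt)`, in
#' [0, 0.5]: 0 when the WSS never changes effective sign over the cycle,
#' 0.5 when the positive and negative lobes integrate to equal magnitude.
#' Both integrals use the trapezoidal rule on the sample times, so the
#' bound holds exactly (the rule is a positive linear functional). An
#' identically-zero series has no defined OSI and raises a quality error.
#'
#' @param series A [wss_series()].
#' @return OSI, dimensionless in [0, 0.5].
#' @export
osi <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  denom <- trapz(series$times, abs(series$wss))
  if (denom <= .Machine$double.eps * length(series$wss)) {
    bsi_quality_error("OSI undefined: integral of |WSS| is zero")
  }
  0.5 * (1 - abs(trapz(series$times, series$wss)) / denom)
}

#' Bundle TAWSS and OSI for one wall series
#'
#' @param series A [wss_series()].
#' @return Object of class `wss_indicators`: list with `tawss` (Pa) and
#'   `osi`.
#' @export
wss_indicators <- function(series) {
  structure(list(tawss = tawss(series), osi = osi(series)),
            class = "wss_indicators")
}

#' @export
print.wss_indicators <- function(x, ...) {
  cat("TAWSS ", signif(x$tawss, 4), " Pa, OSI ", signif(x$osi, 3), "\n",
      sep = "")
  invisible(x)
}

#' Wall shear stress series at a profile endpoint
#'
#' For every frame of the first full cycle, extracts the velocity profile
#' along the line, masks samples below the confidence threshold, computes
#' the shear profile and takes its value at the valid sample nearest the
#' chosen wall end. The sign convention makes forward (systolic, +x) flow
#' give positive WSS at both walls: the raw `mu * dV/dy` is kept at the
#' anterior (low-y) wall and negated at the posterior wall, so a sign
#' change in the series always means a reversal of near-wall flow
#' direction.
#'
#' @param cine A tracked (or truth-filled) `cine_loop` spanning at least
#'   one cardiac cycle.
#' @param line A [line_profile()]; its endpoints define the walls.
#' @param wall_end `"anterior"` (first endpoint, low y) or `"posterior"`.
#' @param mu Dynamic viscosity, Pa s.
#' @param confidence_threshold Samples below it are excluded (default
#'   0.5).
#' @param n_lines Number of parallel profile lines the wall WSS is
#'   averaged over (odd; default 7). The lines are offset perpendicular
#'   to the profile by `line_spacing` so the wall value represents a
#'   short wall segment rather than a single speckle column; per-column
#'   estimates share speckle realizations across frames, so this spatial
#'   average suppresses noise that the cycle integral cannot.
#' @param line_spacing Offset between neighbouring lines, mm; default
#'   1.4 (about one tracking kernel, so the averaged columns are
#'   statistically independent). Lines leaving the field of view are
#'   dropped.
#' @return A [wss_series()] over one period.
#' @export
wall_series <- function(cine, line, wall_end = c("anterior", "posterior"),
                        mu = 0.0035, confidence_threshold = 0.5,
                        n_lines = 7L, line_spacing = 1.4) {
  wall_end <- match.arg(wall_end)
  validate_cine(cine)
  times <- cine$meta$frame_times
  period <- cine$meta$period
  if (times[length(times)] - times[1] < period * (1 - 1 / length(times)) - 1e-12) {
    bsi_validation_error("cine does not span a full cardiac cycle")
  }
  lines <- parallel_lines(cine, line, n_lines, line_spacing)
  in_cycle <- which(times <= times[1] + period + 1e-12)
  wss <- rep(NA_real_, length(in_cycle))
  for (ii in seq_along(in_cycle)) {
    k <- in_cycle[ii]
    vals <- vapply(lines, function(ln) {
      pr <- extract_profile(cine, ln, k)
      m <- pr$confidence >= confidence_threshold
      if (sum(m) < 3L) return(NA_real_)
      sp <- shear_profile(pr$v_long, pr$Y_mm, mu = mu, mask = m)
      ok <- which(sp$valid)
      if (length(ok) == 0L) return(NA_real_)
      idx <- if (wall_end == "anterior") ok[1] else ok[length(ok)]
      if (wall_end == "anterior") sp$tau[idx] else -sp$tau[idx]
    }, 0)
    if (any(is.finite(vals))) wss[ii] <- mean(vals, na.rm = TRUE)
  }
  if (mean(is.na(wss)) > 0.2) {
    bsi_quality_error(paste0(
      "no valid near-", wall_end, " sample in more than 20% of frames"
    ))
  }
  wss_series(times[in_cycle], wss, period)
}

# parallel copies of a profile line, offset perpendicular to it; copies
# leaving the field of view are dropped (the base line is always kept)
parallel_lines <- function(cine, line, n_lines, spacing) {
  n_lines <- max(1L, as.integer(n_lines))
  d <- dim(cine$tissue)
  p <- cine$meta$pixel_pitch
  xmax <- (d[3] - 1) * p
  ymax <- (d[2] - 1) * p
  ux <- -(line$y1 - line$y0) / line$length
  uy <- (line$x1 - line$x0) / line$length
  offs <- spacing * (seq_len(n_lines) - (n_lines + 1) / 2)
  out <- list()
  for (o in offs) {
    x0 <- line$x0 + o * ux; y0 <- line$y0 + o * uy
    x1 <- line$x1 + o * ux; y1 <- line$y1 + o * uy
    if (min(x0, x1) < 0 || max(x0, x1) > xmax ||
          min(y0, y1) < 0 || max(y0, y1) > ymax) {
      next
    }
    out[[length(out) + 1L]] <- line_profile(x0, y0, x1, y1, line$n_samples)
  }
  if (length(out) == 0L) list(line) else out
}

#' Peak-velocity and mean-confidence traces along a line
#'
#' Per-frame maximum of |V_long| and mean confidence along a sampling
#' line — the quantities compared against CW Doppler envelopes.
#'
#' @param cine A tracked `cine_loop`.
#' @param line A [line_profile()].
#' @return data.frame with `frame`, `time`, `phase`, `v_peak` (m/s),
#'   `mean_confidence`.
#' @export
peak_velocity_trace <- function(cine, line) {
  validate_cine(cine)
  nT <- n_frames(cine)
  v_peak <- numeric(nT)
  mean_conf <- numeric(nT)
  for (k in seq_len(nT)) {
    pr <- extract_profile(cine, line, k)
    v_peak[k] <- max(abs(pr$v_long))
    mean_conf[k] <- mean(pr$confidence)
  }
  data.frame(frame = seq_len(nT), time = cine$meta$frame_times,
             phase = cycle_phase(cine$meta$frame_times, cine$meta$period),
             v_peak = v_peak, mean_confidence = mean_conf)
}

#' Simplified-Bernoulli pressure gradient
#'
#' The standard clinical simplification `dP = 4 * v^2` converting a peak
#' velocity (m/s) into a transvalvar pressure gradient (mmHg); the
#' constant 4 bundles blood density and unit conversions.
#'
#' @param v_peak Peak velocity, m/s (non-negative).
#' @return Pressure gradient, mmHg.
#' @export
bernoulli_gradient <- function(v_peak) {
  if (any(!is.finite(v_peak)) || any(v_peak < 0)) {
    bsi_validation_error("'v_peak' must be non-negative")
  }
  4 * v_peak^2
}
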