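#' Velocity-field snapshot over the tissue image
#'
#' Grayscale tissue frame with the in-plane velocity field drawn as
#' arrows on a decimated grid, colored by speed. Physical axes in mm;
#' y increases downward (toward the posterior wall), matching the image
#' convention.
#'
#' @param cine A tracked `cine_loop`.
#' @param frame Frame index.
#' @param stride Arrow decimation in pixels.
#' @param arrow_scale Arrow length in mm per m/s.
#' @export
plot_flow_snapshot <- function(cine, frame, stride = 8L, arrow_scale = 1.5) {
  validate_cine(cine)
  co <- cine_coords(cine)
  img <- cine$tissue[frame, , ]
  graphics::image(co$x, co$y, t(img[rev(seq_len(nrow(img))), ]),
                  col = grDevices::gray.colors(64, 0, 1), useRaster = TRUE,
                  xlab = "x (mm, long axis)", ylab = "y (mm, short axis)",
                  main = sprintf("frame %d, t/T = %.2f", frame,
                                 cycle_phase(cine$meta$frame_times[frame],
                                             cine$meta$period)))
  if (!is.null(cine$velocity)) {
    ri <- seq(1, nrow(img), by = stride)
    cj <- seq(1, ncol(img), by = stride)
    vx <- cine$velocity[frame, ri, cj, 1]
    vy <- cine$velocity[frame, ri, cj, 2]
    sp <- sqrt(vx^2 + vy^2)
    x0 <- matrix(co$x[cj], length(ri), length(cj), byrow = TRUE)
    y0 <- matrix(co$y[ri], length(ri), length(cj))
    cols <- grDevices::hcl.colors(32, "viridis")[
      pmax(1L, ceiling(31 * sp / max(sp, 1e-9)))]
    keep <- sp > 0.02 * max(sp)
    # plotted y axis runs 0 (top) to max; flip to match image orientation
    ymax <- max(co$y)
    suppressWarnings(graphics::arrows(
      x0[keep], ymax - y0[keep],
      (x0 + arrow_scale * vx)[keep], ymax - (y0 + arrow_scale * vy)[keep],
      length = 0.03, col = cols[keep]))
  }
  invisible(NULL)
}

#' Velocity and shear profiles at selected phases
#'
#' Long-axis velocity (top) and shear stress (bottom) along a sampling
#' line at the frames nearest the requested phases.
#'
#' @param cine A tracked `cine_loop`.
#' @param line A [line_profile()].
#' @param phases Cycle phases t/T to display.
#' @param mu Dynamic viscosity, Pa s.
#' @export
plot_velocity_profiles <- function(cine, line, phases = c(0, 0.2, 0.4, 0.8),
                                   mu = 0.0035) {
  ph <- cycle_phase(cine$meta$frame_times, cine$meta$period)
  frames <- vapply(phases, function(p) which.min(abs(ph - p)), 0L)
  profs <- lapply(frames, function(k) extract_profile(cine, line, k))
  taus <- lapply(profs, function(pr) {
    shear_profile(pr$v_long, pr$Y_mm, mu = mu)$tau
  })
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  cols <- grDevices::hcl.colors(length(phases), "Dark 3")
  yl <- range(unlist(lapply(profs, `[[`, "v_long")))
  plot(NA, xlim = range(profs[[1]]$Y_mm), ylim = yl,
       xlab = "Y (mm)", ylab = "V long (m/s)")
  graphics::abline(h = 0, col = "gray70")
  for (i in seq_along(profs)) {
    graphics::lines(profs[[i]]$Y_mm, profs[[i]]$v_long, col = cols[i])
  }
  graphics::legend("topright", legend = sprintf("t/T=%.1f", phases),
                   col = cols, lty = 1, cex = 0.8, bty = "n")
  yl <- range(unlist(taus), na.rm = TRUE)
  plot(NA, xlim = range(profs[[1]]$Y_mm), ylim = yl,
       xlab = "Y (mm)", ylab = expression(mu * partialdiff * V /
                                            partialdiff * y ~ "(Pa)"))
  graphics::abline(h = 0, col = "gray70")
  for (i in seq_along(taus)) {
    graphics::lines(profs[[i]]$Y_mm, taus[[i]], col = cols[i])
  }
  invisible(NULL)
}

#' Peak-velocity and confidence traces
#'
#' @param trace Output of [peak_velocity_trace()].
#' @export
plot_traces <- function(trace) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  plot(trace$phase, trace$v_peak, type = "b", pch = 16, cex = 0.6,
       xlab = "t/T", ylab = "max |V| (m/s)")
  plot(trace$phase, trace$mean_confidence, type = "b", pch = 16, cex = 0.6,
       ylim = c(0, 1), xlab = "t/T", ylab = "mean confidence")
  invisible(NULL)
}

report_figures <- function(cine, line, out_dir) {
  figdir <- file.path(out_dir, "figures")
  dir.create(figdir, recursive = TRUE, showWarnings = FALSE)
  ph <- cycle_phase(cine$meta$frame_times, cine$meta$period)
  for (p in c(0, 0.2, 0.4, 0.8)) {
    k <- which.min(abs(ph - p))
    grDevices::png(file.path(figdir, sprintf("snapshot_tT%03d.png", p * 100)),
                   width = 900, height = 700, res = 120)
    plot_flow_snapshot(cine, k)
    grDevices::dev.off()
  }
  grDevices::png(file.path(figdir, "profiles.png"),
                 width = 800, height = 900, res = 120)
  plot_velocity_profiles(cine, line)
  grDevices::dev.off()
  grDevices::png(file.path(figdir, "traces.png"),
                 width = 800, height = 900, res = 120)
  plot_traces(peak_velocity_trace(cine, line))
  grDevices::dev.off()
  invisible(figdir)
}
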