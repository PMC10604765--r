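#' Block-matching tracker configuration
#'
#' Parameters of the speckle block-matching velocimeter. A square kernel
#' from frame k is matched against a search window in frame k+1; the
#' displacement maximising normalized cross-correlation (NCC; or
#' minimising the sum of absolute differences, SAD) over integer lags is
#' refined per axis by a 3-point parabolic fit. The best NCC value doubles
#' as the match confidence after clamping to [0, 1].
#'
#' Candidate integer lags are restricted to a Euclidean magnitude of
#' `v_max / (prf * pixel_pitch)` pixels — the tracker's search distance is
#' proportional to its velocity limit, so speeds beyond `v_max` saturate
#' rather than track. The search window (`search_radius`) is one pixel
#' wider than the cap so refinement at the cap boundary still has
#' neighbouring scores: at the default 2 m/s limit, 6 kHz PRF and
#' 0.0825 mm pitch the cap is about 4.04 px and the default radius 6 px.
#'
#' @param kernel_size Odd kernel side length, px.
#' @param grid_stride Spacing between kernel centres, px.
#' @param search_radius Integer search-window radius, px; `NULL` derives
#'   `ceil(v_max / (prf * pitch)) + 1` when the tracker is applied.
#' @param metric `"ncc"` (default) or `"sad"` (faster; confidence still
#'   uses NCC at the chosen lag).
#' @param subpixel Peak-fit for sub-pixel refinement: `"gaussian"`
#'   (default; 3-point log-parabolic fit, exact for the Gaussian
#'   correlation peak of Gaussian speckle and nearly free of peak
#'   locking), `"parabolic"`, or `"none"`.
#' @param v_max Tracking velocity limit, m/s.
#' @param validate_vectors Apply the normalized-median outlier test
#'   (3 x 3 neighbourhood) to the kernel-grid displacement field and
#'   replace outliers with the neighbourhood median — the standard
#'   post-validation step of block-matching velocimetry. Used by
#'   [track_cine()] only.
#' @param smooth_sigma Gaussian smoothing of the validated displacement
#'   field, in kernel-grid units (0 disables). Used by [track_cine()]
#'   only.
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(kernel_size = 15L, grid_stride = 2L,
                           search_radius = NULL,
                           metric = c("ncc", "sad"),
                           subpixel = c("gaussian", "parabolic", "none"),
                           v_max = 2.0,
                           validate_vectors = TRUE, smooth_sigma = 1.0) {
  metric <- match.arg(metric)
  subpixel <- match.arg(subpixel)
  check_number(kernel_size, "kernel_size", 3)
  if (kernel_size %% 2 == 0) {
    bsi_validation_error("'kernel_size' must be odd")
  }
  check_number(grid_stride, "grid_stride", 1)
  check_number(v_max, "v_max", 0, strict = TRUE)
  if (!is.null(search_radius)) check_number(search_radius, "search_radius", 1)
  check_number(smooth_sigma, "smooth_sigma", 0)
  structure(list(
    kernel_size = as.integer(kernel_size),
    grid_stride = as.integer(grid_stride),
    search_radius = if (is.null(search_radius)) NULL else
      as.integer(search_radius),
    metric = metric, subpixel = subpixel, v_max = v_max,
    validate_vectors = isTRUE(validate_vectors),
    smooth_sigma = smooth_sigma
  ), class = "tracker_config")
}

# displacement cap (px) implied by the velocity limit, and the resolved
# search radius; radius must cover the cap
resolve_search <- function(cfg, imaging) {
  d_cap <- cfg$v_max / (imaging$prf * imaging$pixel_pitch * 1e-3)
  radius <- cfg$search_radius %||% (ceiling(d_cap) + 1L)
  if (radius < ceiling(d_cap)) {
    bsi_validation_error(
      "search_radius smaller than the displacement implied by v_max"
    )
  }
  list(d_cap = d_cap, radius = as.integer(radius))
}

#' Match one kernel between two frames
#'
#' Single-kernel block matching: exhaustive integer-lag search (NCC
#' maximised or SAD minimised) over the search window, parabolic sub-pixel
#' refinement, and the best integer-lag NCC as match quality. A kernel
#' whose search window does not fit inside both frames is flagged invalid
#' rather than raising an error.
#'
#' @param frame_a,frame_b Equal-sized image matrices; the kernel is taken
#'   from `frame_a`.
#' @param center Kernel centre `c(row, col)`, 1-based.
#' @param cfg A [tracker_config()]; `search_radius` must be set (the
#'   default 6 px corresponds to a 2 m/s limit at 6 kHz and 0.0825 mm).
#' @param d_cap Optional candidate-lag cap in px (default unbounded; the
#'   cine-level tracker derives it from `v_max`).
#' @return List with `dx`, `dy` (px, x = columns, y = rows), `quality`
#'   (NCC at the best integer lag) and `valid`.
#' @export
match_block <- function(frame_a, frame_b, center, cfg = tracker_config(),
                        d_cap = Inf) {
  stopifnot(is.matrix(frame_a), is.matrix(frame_b),
            all(dim(frame_a) == dim(frame_b)))
  radius <- cfg$search_radius %||% 6L
  h <- (cfg$kernel_size - 1L) %/% 2L
  m <- h + radius
  ci <- center[1]; cj <- center[2]
  if (ci - m < 1 || ci + m > nrow(frame_a) ||
        cj - m < 1 || cj + m > ncol(frame_a)) {
    return(list(dx = NA_real_, dy = NA_real_, quality = 0, valid = FALSE))
  }
  r <- cpp_match_grid(frame_a, frame_b, as.integer(ci - 1L),
                      as.integer(cj - 1L), h, radius,
                      as.integer(cfg$metric == "sad"),
                      if (is.finite(d_cap)) d_cap else 1e9,
                      as.integer(cfg$subpixel == "gaussian"))
  sub <- cfg$subpixel != "none"
  list(dx = if (sub) r[1, 4] else r[1, 2],
       dy = if (sub) r[1, 3] else r[1, 1],
       quality = r[1, 5], valid = TRUE)
}

#' Track one frame pair on a kernel grid
#'
#' Applies [match_block()] on a regular grid of kernel centres covering
#' every position whose kernel and search window fit inside the frames.
#' Confidence is the best-lag NCC clamped to [0, 1]; border positions
#' (excluded from the grid) carry confidence 0.
#'
#' @param frame_a,frame_b Consecutive frames (equal-sized matrices).
#' @param cfg A [tracker_config()].
#' @param imaging An [imaging_config()] (supplies pitch and PRF for the
#'   velocity-limit displacement cap).
#' @return An object of class `displacement_field`: list with kernel-grid
#'   `rows`/`cols` (1-based centres), matrices `dx`, `dy` (px), `quality`
#'   and `confidence` (rows x cols of the grid), and the search geometry.
#' @export
track_pair <- function(frame_a, frame_b, cfg = tracker_config(),
                       imaging = imaging_config()) {
  if (!all(dim(frame_a) == dim(frame_b))) {
    bsi_validation_error("frames have mismatched shapes")
  }
  geo <- resolve_search(cfg, imaging)
  h <- (cfg$kernel_size - 1L) %/% 2L
  m <- h + geo$radius
  ny <- nrow(frame_a); nx <- ncol(frame_a)
  rows <- seq(m + 1L, ny - m, by = cfg$grid_stride)
  cols <- seq(m + 1L, nx - m, by = cfg$grid_stride)
  if (length(rows) < 2L || length(cols) < 2L) {
    bsi_validation_error("frame too small for the kernel and search window")
  }
  centers <- expand.grid(row = rows, col = cols)
  r <- cpp_match_grid(frame_a, frame_b,
                      as.integer(centers$row - 1L),
                      as.integer(centers$col - 1L),
                      h, geo$radius, as.integer(cfg$metric == "sad"),
                      geo$d_cap,
                      as.integer(cfg$subpixel == "gaussian"))
  sub <- cfg$subpixel != "none"
  nr <- length(rows); nc <- length(cols)
  structure(list(
    rows = rows, cols = cols,
    dx = matrix(if (sub) r[, 4] else r[, 2], nr, nc),
    dy = matrix(if (sub) r[, 3] else r[, 1], nr, nc),
    quality = matrix(r[, 5], nr, nc),
    confidence = matrix(clamp(r[, 5], 0, 1), nr, nc),
    d_cap = geo$d_cap, radius = geo$radius
  ), class = "displacement_field")
}

#' Convert displacements to velocities
#'
#' `v = d * pixel_pitch * prf` per component: a displacement in
#' pixels/frame times the pixel size (mm, converted to m) times the frame
#' rate. At the defaults (0.0825 mm, 6 kHz) 2 px maps to 0.99 m/s.
#'
#' @param d A `displacement_field` from [track_pair()], or a numeric
#'   displacement (px).
#' @param imaging An [imaging_config()].
#' @return For a field: list with matrices `vx`, `vy` (m/s) on the kernel
#'   grid. For a numeric: velocity in m/s.
#' @export
displacement_to_velocity <- function(d, imaging = imaging_config()) {
  f <- imaging$pixel_pitch * 1e-3 * imaging$prf
  if (is.numeric(d)) return(d * f)
  stopifnot(inherits(d, "displacement_field"))
  list(vx = d$dx * f, vy = d$dy * f, rows = d$rows, cols = d$cols)
}

# stack of the 8 neighbour values of each cell of M (NA outside edges)
neighbor_stack <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  out <- array(NA_real_, c(nr, nc, nrow(offs)))
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    src_r <- seq_len(nr) + di
    src_c <- seq_len(nc) + dj
    ok_r <- src_r >= 1 & src_r <= nr
    ok_c <- src_c >= 1 & src_c <= nc
    out[ok_r, ok_c, k] <- M[src_r[ok_r], src_c[ok_c]]
  }
  out
}

# normalized-median vector validation (Westerweel-Scarano test):
# outliers are replaced by the component-wise neighbourhood median
median_validate <- function(dx, dy, thresh = 2, eps0 = 0.1) {
  res <- lapply(list(dx, dy), function(M) {
    nb <- neighbor_stack(M)
    med <- apply(nb, c(1, 2), stats::median, na.rm = TRUE)
    resid <- apply(abs(nb - rep(med, 8)), c(1, 2), stats::median, na.rm = TRUE)
    list(med = med, r = abs(M - med) / (resid + eps0))
  })
  bad <- pmax(res[[1]]$r, res[[2]]$r) > thresh
  dx[bad] <- res[[1]]$med[bad]
  dy[bad] <- res[[2]]$med[bad]
  list(dx = dx, dy = dy, n_outliers = sum(bad))
}

# Separable Gaussian smoothing on the kernel grid. The grid is padded by
# linear extrapolation before convolving, so the filter is exact on
# linear fields up to the boundary — a truncated kernel at the edge
# would otherwise flatten near-wall gradients, exactly where wall shear
# is sampled.
smooth_grid <- function(M, sigma) {
  if (sigma <= 0) return(M)
  half <- max(1L, ceiling(3 * sigma))
  w <- exp(-(-half:half)^2 / (2 * sigma^2))
  w <- w / sum(w)
  pad_rows <- function(X) {
    top <- outer(half:1, seq_len(ncol(X)),
                 function(k, j) X[1, j] + k * (X[1, j] - X[2, j]))
    n <- nrow(X)
    bot <- outer(1:half, seq_len(ncol(X)),
                 function(k, j) X[n, j] + k * (X[n, j] - X[n - 1, j]))
    rbind(top, X, bot)
  }
  conv_rows <- function(X) {
    P <- pad_rows(X)
    out <- 0
    for (k in seq_along(w)) {
      out <- out + w[k] * P[(k - 1) + seq_len(nrow(X)), , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(M))))
}

# separable bilinear interpolation from a kernel grid (values at 1-based
# rows/cols `ri`/`cj`) to the full pixel grid, with nearest-edge clamping
# outside the grid hull
interp_from_grid <- function(vals, ri, cj, ny, nx) {
  yi <- seq_len(ny); xi <- seq_len(nx)
  i0 <- clamp(findInterval(yi, ri), 1L, length(ri) - 1L)
  fy <- clamp((yi - ri[i0]) / (ri[i0 + 1L] - ri[i0]), 0, 1)
  j0 <- clamp(findInterval(xi, cj), 1L, length(cj) - 1L)
  fx <- clamp((xi - cj[j0]) / (cj[j0 + 1L] - cj[j0]), 0, 1)
  a <- vals[i0, j0, drop = FALSE] * (1 - fy) + vals[i0 + 1L, j0, drop = FALSE] * fy
  b <- vals[i0, j0 + 1L, drop = FALSE] * (1 - fy) +
    vals[i0 + 1L, j0 + 1L, drop = FALSE] * fy
  a * matrix(1 - fx, ny, nx, byrow = TRUE) + b * matrix(fx, ny, nx, byrow = TRUE)
}

#' Track a whole cine loop
#'
#' Runs [track_pair()] on every consecutive tissue frame pair,
#' post-validates the kernel-grid vectors (normalized-median outlier
#' replacement and light Gaussian smoothing, see [tracker_config()]), and
#' fills the cine's pixel-dense velocity and confidence channels by
#' bilinear interpolation of the kernel-grid estimates (nearest-edge values beyond
#' the tracked grid, with confidence forced to 0 in that untracked
#' border). The last frame repeats the final pair's estimate so the
#' channels cover every frame.
#'
#' @param cine A `cine_loop` with a tissue channel.
#' @param cfg A [tracker_config()].
#' @return The cine with `velocity` and `confidence` channels filled.
#' @export
track_cine <- function(cine, cfg = tracker_config()) {
  validate_cine(cine)
  d <- dim(cine$tissue)
  imaging <- imaging_config(pixel_pitch = cine$meta$pixel_pitch,
                            prf = cine$meta$prf,
                            n_x = d[3], n_y = d[2])
  velocity <- array(0, c(d, 2L))
  confidence <- array(0, d)
  for (k in seq_len(d[1] - 1L)) {
    df <- track_pair(cine$tissue[k, , ], cine$tissue[k + 1L, , ],
                     cfg, imaging)
    if (cfg$validate_vectors) {
      mv <- median_validate(df$dx, df$dy)
      df$dx <- mv$dx
      df$dy <- mv$dy
      if (mv$n_outliers > 0) {
        bsi_log("debug", "pair ", k, ": replaced ", mv$n_outliers,
                " outlier vectors")
      }
    }
    df$dx <- smooth_grid(df$dx, cfg$smooth_sigma)
    df$dy <- smooth_grid(df$dy, cfg$smooth_sigma)
    # the tracking limit is hard: vectors pushed past the velocity-limit
    # search distance by refinement or smoothing are rescaled onto it
    dmag <- sqrt(df$dx^2 + df$dy^2)
    over <- dmag > df$d_cap
    if (any(over)) {
      sc <- df$d_cap / dmag[over]
      df$dx[over] <- df$dx[over] * sc
      df$dy[over] <- df$dy[over] * sc
    }
    v <- displacement_to_velocity(df, imaging)
    velocity[k, , , 1] <- interp_from_grid(v$vx, df$rows, df$cols, d[2], d[3])
    velocity[k, , , 2] <- interp_from_grid(v$vy, df$rows, df$cols, d[2], d[3])
    cf <- interp_from_grid(df$confidence, df$rows, df$cols, d[2], d[3])
    out_rows <- seq_len(d[2]) < min(df$rows) | seq_len(d[2]) > max(df$rows)
    out_cols <- seq_len(d[3]) < min(df$cols) | seq_len(d[3]) > max(df$cols)
    cf[out_rows, ] <- 0
    cf[, out_cols] <- 0
    confidence[k, , ] <- cf
  }
  velocity[d[1], , , ] <- velocity[d[1] - 1L, , , ]
  confidence[d[1], , ] <- confidence[d[1] - 1L, , ]
  cine$velocity <- velocity
  cine$confidence <- clamp(confidence, 0, 1)
  bsi_log("info", "tracked ", d[1] - 1L, " frame pairs")
  validate_cine(cine)
}

#' Per-frame saturation summary
#'
#' Compares estimated against true peak speeds frame by frame and flags
#' frames whose true peak exceeds the tracking limit. Because the search
#' distance is proportional to `v_max`, the estimated peak saturates near
#' the limit (within half-pixel sub-pixel slack) while match confidence
#' degrades — the tracker cannot follow speckle beyond its maximum search
#' distance.
#'
#' @param estimated A tracked `cine_loop` carrying a `truth` stack, or a
#'   `T x n_y x n_x x 2` velocity array.
#' @param truth Ground-truth velocity array (ignored when `estimated` is a
#'   cine).
#' @param v_max Tracking velocity limit, m/s.
#' @param confidence Optional confidence stack (taken from the cine when
#'   available).
#' @return data.frame with `frame`, `true_max`, `est_max`,
#'   `mean_confidence`, `saturated`.
#' @export
saturation_report <- function(estimated, truth = NULL, v_max = 2.0,
                              confidence = NULL) {
  if (inherits(estimated, "cine_loop")) {
    confidence <- confidence %||% estimated$confidence
    truth <- truth %||% estimated$truth
    estimated <- estimated$velocity
  }
  if (is.null(estimated) || is.null(truth)) {
    bsi_validation_error("need both estimated and true velocity stacks")
  }
  stopifnot(all(dim(estimated) == dim(truth)))
  nT <- dim(estimated)[1]
  speed <- function(v, k) sqrt(v[k, , , 1]^2 + v[k, , , 2]^2)
  out <- data.frame(
    frame = seq_len(nT),
    true_max = vapply(seq_len(nT), function(k) max(speed(truth, k)), 0),
    est_max = vapply(seq_len(nT), function(k) max(speed(estimated, k)), 0),
    mean_confidence = if (is.null(confidence)) NA_real_ else
      vapply(seq_len(nT), function(k) mean(confidence[k, , ]), 0)
  )
  out$saturated <- out$true_max > v_max
  out
}
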