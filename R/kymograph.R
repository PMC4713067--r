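# Algorithm I: difference-of-Gaussians edge extraction, leading-edge
# tracking along a sampling line, kymograph construction, and measurement of
# the protrusion/retraction period T, persistence length dl and retrograde
# flow rate dx/dt.

#' Extract edges with a difference-of-Gaussians filter
#'
#' The DoG response is `blur(frame, sigma_small) - blur(frame, sigma_large)`;
#' pixels where `|response|` exceeds `k` times the response standard
#' deviation form the edge map. A constant frame yields an empty map.
#'
#' @param frame numeric image matrix.
#' @param sigma_small,sigma_large Gaussian sigmas in pixels,
#'   `sigma_small < sigma_large`.
#' @param k threshold in units of the response sd (default 2).
#' @return logical edge-map matrix with the signed response in
#'   `attr(, "response")` and the threshold in `attr(, "threshold")`.
#' @export
extract_edges <- function(frame, sigma_small = 1, sigma_large = 3, k = 2) {
  stopifnot(sigma_small < sigma_large, k > 0)
  response <- gaussian_blur(frame, sigma_small) - gaussian_blur(frame, sigma_large)
  s <- stats::sd(response)
  thr <- k * s
  # a (near-)constant frame leaves only floating-point dust in the response
  flat <- s <= 1e-9 * max(abs(frame), 1)
  edge <- if (flat) matrix(FALSE, nrow(frame), ncol(frame))
          else abs(response) > thr
  attr(edge, "response") <- response
  attr(edge, "threshold") <- thr
  edge
}

#' A sampling line for kymographs and edge tracking
#'
#' Coordinates are 0-based pixels, `x` = column, `y` = row. The first
#' endpoint declares the cell-body end of the line: the leading edge is the
#' edge pixel farthest from it.
#'
#' @param p1 cell-body endpoint `c(x, y)`.
#' @param p2 outward endpoint `c(x, y)`.
#' @return an object of class `sampling_line`.
#' @export
sampling_line <- function(p1, p2) {
  stopifnot(length(p1) == 2, length(p2) == 2)
  len <- sqrt(sum((p2 - p1)^2))
  if (len < 20) stop("sampling line must be at least 20 px long")
  structure(list(p1 = as.numeric(p1), p2 = as.numeric(p2), length_px = len),
            class = "sampling_line")
}

#' Default sampling line for a synthetic stack
#'
#' A horizontal line through the image mid-row, running from the cell body
#' (left) outward (right), perpendicular to the leading edge of the
#' generator's geometry.
#'
#' @param stack an `image_stack_sequence`.
#' @return a [sampling_line()].
#' @export
default_sampling_line <- function(stack) {
  nr <- stack$config$image_shape[1]; nc <- stack$config$image_shape[2]
  y <- floor(nr / 2)
  sampling_line(c(1, y), c(nc - 2, y))
}

# Points along a line at 1-px spacing; returns 1-based (row, col) matrices
# and arc-length positions in pixels.
#' @noRd
line_points <- function(line) {
  n <- floor(line$length_px) + 1L
  s <- seq(0, line$length_px, length.out = n)
  ux <- (line$p2 - line$p1) / line$length_px
  x <- line$p1[1] + s * ux[1]
  y <- line$p1[2] + s * ux[2]
  list(row = y + 1, col = x + 1, s_px = s)
}

#' @noRd
height_zero_index <- function(stack) {
  k <- which(abs(stack$config$heights_um) < 1e-9)
  if (!length(k)) 1L else k[1]
}

# Position of the leading edge along the line in one frame: the outermost
# run of at least min_run_px samples with POSITIVE supra-threshold DoG
# response (the bright edge rim gives a positive band-pass response, while
# the filter's negative side-lobe just outside the cell would mislocate an
# unsigned rule outward), localized at the run's response peak with
# parabolic sub-pixel refinement. Returns NA if no such run.
#' @noRd
edge_position_on_line <- function(plane, lp, sigma_small, sigma_large, k,
                                  min_run_px = 2L) {
  edge <- extract_edges(plane, sigma_small, sigma_large, k)
  if (!any(edge)) return(NA_real_)
  resp <- attr(edge, "response")
  thr <- attr(edge, "threshold")
  samp <- bilinear_sample(resp, lp$row, lp$col)
  above <- samp > thr
  if (!any(above)) return(NA_real_)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  cand <- which(runs$values & runs$lengths >= min_run_px)
  if (!length(cand)) return(NA_real_)
  last <- max(cand)
  i2 <- ends[last]; i1 <- i2 - runs$lengths[last] + 1L
  seg <- samp[i1:i2]
  idx <- i1 + which.max(seg) - 1L
  # parabolic refinement on the sampled response
  off <- 0
  if (idx > 1 && idx < length(samp)) {
    y1 <- samp[idx - 1]; y2 <- samp[idx]; y3 <- samp[idx + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) off <- 0.5 * (y1 - y3) / den
    off <- min(max(off, -0.5), 0.5)
  }
  lp$s_px[idx] + off * (lp$s_px[2] - lp$s_px[1])
}

#' Track the leading edge along a sampling line
#'
#' For every frame of the height-0 sequence the leading-edge position is the
#' outermost supra-threshold DoG feature along the line (farthest from the
#' cell-body endpoint). Frames without any edge on the line are filled by
#' linear interpolation and flagged; more than 10% such gaps raises a
#' recorded warning.
#'
#' @param stack an `image_stack_sequence`.
#' @param line a [sampling_line()]; default [default_sampling_line()].
#' @param sigma_small,sigma_large,k DoG parameters, see [extract_edges()].
#' @param min_run_px minimal length (samples) of a supra-threshold run to
#'   count as an edge; suppresses isolated noise pixels.
#' @return an `edge_profile`: data.frame with `t_s`, `position_um`,
#'   `interpolated`; attributes `pixel_um`, `line`, `warnings`.
#' @export
track_leading_edge <- function(stack, line = default_sampling_line(stack),
                               sigma_small = 1, sigma_large = 3, k = 2,
                               min_run_px = 3L) {
  stopifnot(inherits(stack, "image_stack_sequence"),
            inherits(line, "sampling_line"))
  h0 <- height_zero_index(stack)
  lp <- line_points(line)
  n <- length(stack$frames)
  pos_px <- vapply(seq_len(n), function(i)
    edge_position_on_line(stack$frames[[i]][[h0]], lp,
                          sigma_small, sigma_large, k, min_run_px),
    numeric(1))
  gaps <- is.na(pos_px)
  if (all(gaps)) stop("no edge detected on the line in any frame")
  warnings <- character()
  if (mean(gaps) > 0.10)
    warnings <- sprintf("edge missing in %.0f%% of frames (>10%%)",
                        100 * mean(gaps))
  t_s <- (seq_len(n) - 1L) * stack$config$frame_interval_s
  if (any(gaps))
    pos_px[gaps] <- stats::approx(t_s[!gaps], pos_px[!gaps],
                                  xout = t_s[gaps], rule = 2)$y
  prof <- data.frame(t_s = t_s,
                     position_um = pos_px * stack$config$pixel_um,
                     interpolated = gaps)
  attr(prof, "pixel_um") <- stack$config$pixel_um
  attr(prof, "line") <- line
  attr(prof, "warnings") <- warnings
  class(prof) <- c("edge_profile", "data.frame")
  prof
}

#' Build a kymograph along a sampling line
#'
#' Column `t` holds bilinear intensity samples of the height-0 plane of frame
#' `t` along the line at 1-px spacing.
#'
#' @inheritParams track_leading_edge
#' @return a `kymograph`: matrix (position along line x time) with fields
#'   `spatial_step_um`, `time_step_s` and `t_s` stored as attributes.
#' @export
build_kymograph <- function(stack, line = default_sampling_line(stack)) {
  stopifnot(inherits(stack, "image_stack_sequence"),
            inherits(line, "sampling_line"))
  h0 <- height_zero_index(stack)
  lp <- line_points(line)
  m <- vapply(stack$frames,
              function(fr) bilinear_sample(fr[[h0]], lp$row, lp$col),
              numeric(length(lp$s_px)))
  structure(m,
            spatial_step_um = stack$config$pixel_um *
              (lp$s_px[2] - lp$s_px[1]),
            time_step_s = stack$config$frame_interval_s,
            t_s = (seq_len(ncol(m)) - 1L) * stack$config$frame_interval_s,
            line = line,
            class = c("kymograph", "matrix"))
}

# Interior local minima of the smoothed profile, separated by
# >= min_period_s; kept greedily by depth.
#' @noRd
profile_minima <- function(profile, min_period_s = 20, smooth_window = 3L) {
  x <- profile$position_um
  t_s <- profile$t_s
  if (smooth_window > 1) {
    kern <- rep(1 / smooth_window, smooth_window)
    xs <- as.numeric(stats::filter(x, kern, sides = 2))
    xs[is.na(xs)] <- x[is.na(xs)]
  } else xs <- x
  cand <- which(diff(sign(diff(xs))) > 0) + 1L
  if (!length(cand)) return(integer())
  keep <- integer()
  for (i in cand[order(xs[cand])]) {
    if (!length(keep) || all(abs(t_s[i] - t_s[keep]) >= min_period_s))
      keep <- c(keep, i)
  }
  sort(keep)
}

#' Measure the protrusion/retraction period
#'
#' Cycles are delimited by successive local minima of the smoothed edge
#' profile (3-frame smoothing, minima separated by at least `min_period_s`);
#' the period T is the mean inter-minimum interval. Minimum times are refined
#' to sub-frame precision by intersecting the retraction and protrusion lines
#' around each sampled minimum, so the period is not quantized to the frame
#' interval.
#'
#' @param profile an `edge_profile` from [track_leading_edge()].
#' @param min_period_s minimal separation between cycle minima, seconds.
#' @param smooth_window smoothing window in frames.
#' @return list with `period_s`, `per_cycle_s`, `n_cycles`, `minima_t_s`
#'   (refined), `minima_idx`.
#' @export
measure_period <- function(profile, min_period_s = 20, smooth_window = 3L) {
  idx <- profile_minima(profile, min_period_s, smooth_window)
  if (length(idx) < 2) stop("no cycles: fewer than 2 profile minima found")
  t_min <- cycle_corners(profile, idx)$troughs[, "t"]
  intervals <- diff(t_min)
  list(period_s = mean(intervals), per_cycle_s = intervals,
       n_cycles = length(intervals), minima_t_s = t_min,
       minima_idx = idx)
}

# Sub-sample refinement of a sawtooth corner near sample m, bracketed by
# [lo, hi]: the profile is modelled as two lines meeting between two
# adjacent samples. Breakpoints up to two frames before / one frame after m
# are tried (the sampled extremum can sit a frame or two off the true corner
# when noise shifts the smoothed minimum); for each, the two legs are fitted
# disjointly and the breakpoint with the smallest total residual wins. The
# corner is the intersection of the winning leg fits, refitted robustly: a
# point is dropped from a leg only when its residual is both a MAD outlier
# and larger than `scale` (one pixel) in absolute terms. Falls back to the
# raw sample when no valid breakpoint exists or the intersection leaves its
# bracket.
#' @noRd
refine_corner <- function(t_s, x, lo, m, hi, scale = 0.1) {
  raw <- c(t = t_s[m], v = x[m])
  fit_line <- function(s) {
    f <- stats::lsfit(t_s[s], x[s])
    if (length(s) >= 4L) {
      # a single badly mislocalized frame must not tilt the leg fit
      r <- abs(f$residuals)
      bad <- which.max(r)
      if (r[bad] > 2.5 * stats::mad(f$residuals) && r[bad] > scale)
        f <- stats::lsfit(t_s[s[-bad]], x[s[-bad]])
    }
    f
  }
  dt <- stats::median(diff(t_s))
  best <- NULL
  for (b in max(lo + 1L, m - 2L):min(hi - 2L, m + 1L)) {
    if (b < lo + 1L || b > hi - 2L) next
    # plain fits for breakpoint selection: every candidate uses the same
    # total point count, so raw SSEs are comparable
    f1 <- stats::lsfit(t_s[lo:b], x[lo:b])
    f2 <- stats::lsfit(t_s[(b + 1L):hi], x[(b + 1L):hi])
    sse <- sum(f1$residuals^2) + sum(f2$residuals^2)
    if (is.null(best) || sse < best$sse) best <- list(sse = sse, b = b)
  }
  if (is.null(best)) return(raw)
  f1 <- fit_line(lo:best$b)
  f2 <- fit_line((best$b + 1L):hi)
  if (abs(f1$coefficients[2] - f2$coefficients[2]) < 1e-12) return(raw)
  t_star <- (f2$coefficients[1] - f1$coefficients[1]) /
    (f1$coefficients[2] - f2$coefficients[2])
  if (t_star < t_s[best$b] - 0.5 * dt || t_star > t_s[best$b + 1L] + 0.5 * dt)
    return(raw)
  c(t = unname(t_star),
    v = unname(f1$coefficients[1] + f1$coefficients[2] * t_star))
}

# Refined cycle corners of an edge profile: per cycle the peak (corner of
# maximal protrusion) and the troughs at the delimiting minima.
# Returns list(peaks, troughs): each a matrix with columns t, v.
#' @noRd
cycle_corners <- function(profile, idx) {
  t_s <- profile$t_s
  x <- profile$position_um
  px <- attr(profile, "pixel_um")
  if (is.null(px)) px <- 0.1
  n_cyc <- length(idx) - 1L
  pk_idx <- vapply(seq_len(n_cyc), function(i) {
    seg <- idx[i]:idx[i + 1L]
    seg[which.max(x[seg])]
  }, integer(1))
  peaks <- t(vapply(seq_len(n_cyc), function(i)
    refine_corner(t_s, x, idx[i], pk_idx[i], idx[i + 1L], px),
    numeric(2)))
  troughs <- t(vapply(seq_along(idx), function(j) {
    # outer minima are bracketed by the pre-/post-cycle extremum
    lo <- if (j > 1) pk_idx[j - 1L] else which.max(x[seq_len(idx[1L])])
    hi <- if (j <= n_cyc) pk_idx[j]
          else idx[j] - 1L + which.max(x[idx[j]:length(x)])
    refine_corner(t_s, x, lo, idx[j], hi, px)
  }, numeric(2)))
  list(peaks = peaks, troughs = troughs)
}

#' Measure the persistence length
#'
#' Per cycle (between successive minima), the persistence length dl is the
#' maximal edge position within the cycle minus the position at the
#' cycle-start minimum, in micrometers; the result is the mean over cycles.
#' Because the protrusion/retraction reversal generally falls between frames,
#' both extrema are refined to sub-frame precision by intersecting the lines
#' fitted to the profile on either side of the sampled extremum.
#'
#' @inheritParams measure_period
#' @return list with `persistence_um`, `per_cycle_um`, `n_cycles`.
#' @export
measure_persistence <- function(profile, min_period_s = 20,
                                smooth_window = 3L) {
  idx <- profile_minima(profile, min_period_s, smooth_window)
  if (length(idx) < 2) stop("no cycles: fewer than 2 profile minima found")
  corners <- cycle_corners(profile, idx)
  per_cycle <- corners$peaks[, "v"] -
    corners$troughs[seq_len(nrow(corners$peaks)), "v"]
  list(persistence_um = mean(per_cycle), per_cycle_um = per_cycle,
       n_cycles = length(per_cycle))
}

#' Retraction windows of an edge profile
#'
#' Per cycle, the frames during which the edge retracts — the phase when
#' retrograde streaks are visible in the kymograph. Because the sampled
#' extrema carry up to one frame of corner uncertainty, each window is inset
#' by one frame: it runs from the frame after the sampled protrusion maximum
#' to the frame before the sampled cycle minimum. Degenerate (empty) windows
#' are dropped.
#'
#' @inheritParams measure_period
#' @return list of `c(start_s, end_s)` windows.
#' @export
retraction_windows <- function(profile, min_period_s = 20,
                               smooth_window = 3L) {
  idx <- profile_minima(profile, min_period_s, smooth_window)
  if (length(idx) < 2) stop("no cycles: fewer than 2 profile minima found")
  x <- profile$position_um
  t_s <- profile$t_s
  wins <- lapply(seq_len(length(idx) - 1L), function(i) {
    seg <- idx[i]:idx[i + 1L]
    m <- seg[which.max(x[seg])]
    c(t_s[min(m + 1L, idx[i + 1L])], t_s[max(idx[i + 1L] - 1L, m + 1L)])
  })
  Filter(function(w) w[2] > w[1] - 1e-9, wins)
}

# Alignment score of a kymograph window under candidate velocity v: the
# mean pairwise correlation of the columns after shearing each by v*t.
# Correlation is sharp for both texture streaks and the moving edge step,
# and is invariant to intensity offset and gain.
#' @noRd
shear_score <- function(W, t_rel, v_px_per_s) {
  L <- nrow(W)
  shifts <- v_px_per_s * t_rel
  lo <- max(1 - min(shifts), 1)
  hi <- min(L - max(shifts), L)
  if (hi - lo < 8) return(NA_real_)
  xout <- seq(ceiling(lo), floor(hi))
  A <- vapply(seq_len(ncol(W)), function(j)
    stats::approx(seq_len(L), W[, j], xout = xout + shifts[j], rule = 2)$y,
    numeric(length(xout)))
  cc <- suppressWarnings(stats::cor(A))
  mean(cc[upper.tri(cc)], na.rm = TRUE)
}

#' Measure the retrograde flow rate from kymograph streaks
#'
#' Within each retraction window the streak slope is found by exhaustively
#' scoring candidate slopes on a grid: for each candidate the window is
#' sheared so that features moving at that velocity align, and the mean
#' pairwise correlation of the aligned columns is maximal at the true slope.
#' The rate is the mean absolute slope across windows, in
#' micrometers/second.
#'
#' @param kymo a `kymograph` from [build_kymograph()].
#' @param windows list of `c(start_s, end_s)` time windows (e.g. from
#'   [retraction_windows()]).
#' @param max_rate_um_s bound of the slope search grid.
#' @param grid_step_um_s slope grid step (default 0.0025 um/s).
#' @param row_limits optional list (parallel to `windows`) of
#'   `c(first_row, last_row)` restricting each window to the kymograph rows
#'   holding streak structure — typically the region that stays behind the
#'   edge throughout the window (see [streak_row_limits()]). Without it the
#'   static cell-to-background step can outweigh the moving texture.
#' @return list with `retro_rate_um_s`, `per_window_um_s` (signed slopes; NA
#'   for skipped windows), `n_windows`.
#' @export
measure_retrograde_flow <- function(kymo, windows,
                                    max_rate_um_s = 0.3,
                                    grid_step_um_s = 0.0025,
                                    row_limits = NULL) {
  stopifnot(inherits(kymo, "kymograph"), length(windows) >= 1)
  t_s <- attr(kymo, "t_s")
  dx <- attr(kymo, "spatial_step_um")
  grid <- seq(0, max_rate_um_s, by = grid_step_um_s)
  grid <- c(0, as.vector(rbind(grid[-1], -grid[-1])))   # ordered by |v|
  per_window <- vapply(seq_along(windows), function(wi) {
    w <- windows[[wi]]
    cols <- which(t_s >= w[1] - 1e-9 & t_s <= w[2] + 1e-9)
    if (length(cols) < 2) return(NA_real_)
    rows <- seq_len(nrow(kymo))
    if (!is.null(row_limits)) {
      rl <- row_limits[[wi]]
      rows <- rows[rows >= rl[1] & rows <= rl[2]]
      if (length(rows) < 8) return(NA_real_)
    }
    W <- kymo[rows, cols, drop = FALSE]
    if (stats::sd(W) < 1e-12) return(NA_real_)   # flat window: skip
    t_rel <- t_s[cols] - mean(t_s[cols])
    scores <- vapply(grid, function(v) shear_score(W, t_rel, v / dx),
                     numeric(1))
    if (all(is.na(scores))) return(NA_real_)
    grid[which.max(scores)]
  }, numeric(1))
  if (all(is.na(per_window)))
    stop("no window with usable contrast structure")
  list(retro_rate_um_s = mean(abs(per_window), na.rm = TRUE),
       per_window_um_s = per_window,
       n_windows = sum(!is.na(per_window)))
}

#' Streak row limits for retrograde-flow windows
#'
#' For each retraction window, the kymograph rows holding retrograde-moving
#' structure: everything from the cell-body end of the line out to the
#' farthest position the edge reaches within the window (plus a margin for
#' the edge halo). During retraction the internal texture, the rim and the
#' edge itself all translate at the retrograde rate, while the background
#' beyond the sweep is static and would dilute or dominate the slope score.
#'
#' @param profile an `edge_profile`.
#' @param windows list of retraction windows (see [retraction_windows()]).
#' @param margin_um margin added beyond the edge for its halo, micrometers.
#' @return list of `c(first_row, last_row)` per window.
#' @export
streak_row_limits <- function(profile, windows, margin_um = 0.6) {
  px <- attr(profile, "pixel_um")
  if (is.null(px)) px <- 0.1
  lapply(windows, function(w) {
    sel <- profile$t_s >= w[1] - 1e-9 & profile$t_s <= w[2] + 1e-9
    outer <- if (any(sel)) max(profile$position_um[sel])
             else max(profile$position_um)
    c(1L, ceiling((outer + margin_um) / px) + 1L)
  })
}

#' Full Algorithm I measurement for one stack and line
#'
#' Convenience wrapper: tracks the edge, measures period, persistence and
#' retrograde flow along one sampling line.
#'
#' @inheritParams track_leading_edge
#' @inheritParams measure_retrograde_flow
#' @param min_period_s,smooth_window cycle-detection parameters.
#' @return list with `period_s`, `persistence_um`, `retro_rate_um_s`,
#'   `n_cycles`, `profile`, `kymograph`.
#' @export
cycle_metrics <- function(stack, line = default_sampling_line(stack),
                          sigma_small = 1, sigma_large = 3, k = 2,
                          min_period_s = 20, smooth_window = 3L,
                          max_rate_um_s = 0.3, grid_step_um_s = 0.0025) {
  profile <- track_leading_edge(stack, line, sigma_small, sigma_large, k)
  per <- measure_period(profile, min_period_s, smooth_window)
  pers <- measure_persistence(profile, min_period_s, smooth_window)
  kymo <- build_kymograph(stack, line)
  wins <- retraction_windows(profile, min_period_s, smooth_window)
  flow <- measure_retrograde_flow(kymo, wins, max_rate_um_s, grid_step_um_s,
                                  row_limits = streak_row_limits(profile,
                                                                 wins))
  list(period_s = per$period_s, persistence_um = pers$persistence_um,
       retro_rate_um_s = flow$retro_rate_um_s, n_cycles = per$n_cycles,
       profile = profile, kymograph = kymo,
       per_cycle = list(period_s = per$per_cycle_s,
                        persistence_um = pers$per_cycle_um,
                        retro_um_s = flow$per_window_um_s))
}
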