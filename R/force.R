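# Optical-trap force analysis: bead deflection to force via the trap
# stiffness, nanopositioner-feedback compensation of the lateral bead path,
# automatic event detection, classification into the four stereotyped
# behaviours (VP, VR, LP, LR), and the lamellipodial protrusion rate from
# averaged compensated traces.

#' Convert bead deflection to force
#'
#' `F = k * deflection`, with the lateral stiffness applied to x and y and
#' the axial stiffness to z.
#'
#' @param deflection_nm n x 3 matrix (or length-3 vector) of deflections in
#'   nm, columns x, y, z.
#' @param stiffness_pn_nm `c(k_xy, k_z)` in pN/nm.
#' @return n x 3 matrix of forces in pN, columns `Fx`, `Fy`, `Fz`.
#' @export
displacement_to_force <- function(deflection_nm,
                                  stiffness_pn_nm = c(0.10, 0.08)) {
  stopifnot(all(stiffness_pn_nm > 0), length(stiffness_pn_nm) == 2)
  d <- if (is.null(dim(deflection_nm))) matrix(deflection_nm, ncol = 3)
       else as.matrix(deflection_nm)
  stopifnot(ncol(d) == 3)
  out <- cbind(stiffness_pn_nm[1] * d[, 1], stiffness_pn_nm[1] * d[, 2],
               stiffness_pn_nm[2] * d[, 3])
  colnames(out) <- c("Fx", "Fy", "Fz")
  out
}

#' Undo nanopositioner feedback on the lateral bead path
#'
#' The compensated lateral path splices the stage motion back into the QPD
#' position: `compensated(t) = qpd_xy(t) + (stage_xy(t) - stage_xy(0))`, with
#' the stage axis oriented so that each recentering jump equals the bead
#' displacement it cancelled. With a stationary stage the compensated path is
#' identically the raw QPD path. Stage jumps that are not preceded by a
#' lateral threshold crossing (`r = sqrt(x^2 + y^2)` on the raw QPD trace)
#' are flagged as inconsistencies.
#'
#' @param trace a `bead_trace` from [generate_bead_trace()] or
#'   [read_bead_trace()].
#' @return data.frame `t_s`, `x`, `y` (compensated, nm), `r_raw_nm` (raw
#'   lateral displacement); attribute `flags` lists sample indices of
#'   unexplained stage jumps.
#' @export
compensate_feedback <- function(trace) {
  stopifnot(inherits(trace, "bead_trace"))
  qpd <- trace$qpd_nm
  stage <- trace$stage_nm
  stopifnot(nrow(qpd) == nrow(stage), nrow(qpd) == length(trace$t_s))
  comp <- qpd[, 1:2, drop = FALSE] +
    sweep(stage, 2, stage[1, ], "-")
  r_raw <- sqrt(qpd[, 1]^2 + qpd[, 2]^2)
  thr <- trace$config$feedback_threshold_nm
  jumps <- which(rowSums(abs(diff(stage))) > 1e-9) + 1L
  flags <- if (!is.null(thr))
    jumps[r_raw[jumps - 1L] <= thr] else integer()
  out <- data.frame(t_s = trace$t_s, x = comp[, 1], y = comp[, 2],
                    r_raw_nm = r_raw)
  attr(out, "flags") <- flags
  out
}

#' Build the force time course of a bead trace
#'
#' Forces are the measured (QPD) deflection times the trap stiffness;
#' the compensated lateral path is attached for protrusion-rate analysis.
#'
#' @param trace a `bead_trace`.
#' @param stiffness_pn_nm `c(k_xy, k_z)` in pN/nm; defaults to the trace's
#'   configured stiffness.
#' @return a `force_trace`: data.frame `t_s`, `Fx`, `Fy`, `Fz` (pN),
#'   `comp_x_nm`, `comp_y_nm`.
#' @export
force_trace <- function(trace,
                        stiffness_pn_nm = trace$config$stiffness_pn_nm) {
  F <- displacement_to_force(trace$qpd_nm, stiffness_pn_nm)
  comp <- compensate_feedback(trace)
  out <- data.frame(t_s = trace$t_s, Fx = F[, 1], Fy = F[, 2], Fz = F[, 3],
                    comp_x_nm = comp$x, comp_y_nm = comp$y)
  class(out) <- c("force_trace", "data.frame")
  out
}

#' Detect force events
#'
#' Maximal intervals where the total force magnitude stays at or above
#' `floor_pn` for at least `min_duration_s`; intervals separated by gaps
#' shorter than `merge_gap_s` are merged.
#'
#' @param ft a `force_trace`.
#' @param floor_pn detection floor in pN (default 1).
#' @param min_duration_s minimal event duration, seconds (default 2).
#' @param merge_gap_s maximal sub-floor gap to bridge, seconds (default 1).
#' @return list of `c(start_s, end_s)` windows (possibly empty).
#' @export
detect_force_events <- function(ft, floor_pn = 1, min_duration_s = 2,
                                merge_gap_s = 1) {
  stopifnot(inherits(ft, "force_trace"))
  mag <- sqrt(ft$Fx^2 + ft$Fy^2 + ft$Fz^2)
  above <- mag >= floor_pn
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values], ends[r$values])
  # merge across short gaps
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    gap_s <- ft$t_s[iv[i, 1]] - ft$t_s[merged[nrow(merged), 2]]
    if (gap_s < merge_gap_s) merged[nrow(merged), 2] <- iv[i, 2]
    else merged <- rbind(merged, iv[i, ])
  }
  keep <- (ft$t_s[merged[, 2]] - ft$t_s[merged[, 1]]) >= min_duration_s
  merged <- merged[keep, , drop = FALSE]
  lapply(seq_len(nrow(merged)),
         function(i) c(ft$t_s[merged[i, 1]], ft$t_s[merged[i, 2]]))
}

#' Classify a force event into VP / VR / LP / LR
#'
#' The event axis is vertical when the peak `|Fz|` exceeds the peak lateral
#' magnitude `sqrt(Fx^2 + Fy^2)`, lateral otherwise. The sense is a push when
#' the dominant deflection moves the bead away from the cell (for the
#' vertical axis, up is away), a retraction otherwise. The away-from-cell
#' direction is supplied per recording.
#'
#' @param ft a `force_trace`, already restricted to the event window (or use
#'   `window`).
#' @param away_xy unit vector (x, y) pointing away from the cell boundary.
#' @param window optional `c(start_s, end_s)` to restrict `ft`.
#' @param floor_pn detection floor; below it the window holds no event.
#' @return one of `"VP"`, `"VR"`, `"LP"`, `"LR"`, or `"no event"`.
#' @export
classify_event <- function(ft, away_xy = c(1, 0), window = NULL,
                           floor_pn = 1) {
  stopifnot(inherits(ft, "force_trace"), length(away_xy) == 2)
  if (!is.null(window))
    ft <- ft[ft$t_s >= window[1] & ft$t_s <= window[2], , drop = FALSE]
  if (!nrow(ft)) return("no event")
  lat <- sqrt(ft$Fx^2 + ft$Fy^2)
  vert <- abs(ft$Fz)
  if (max(lat, vert) < floor_pn) return("no event")
  away <- away_xy / sqrt(sum(away_xy^2))
  if (max(vert) > max(lat)) {
    push <- ft$Fz[which.max(vert)] > 0          # +z (up) = away from cell
    if (push) "VP" else "VR"
  } else {
    i <- which.max(lat)
    push <- (ft$Fx[i] * away[1] + ft$Fy[i] * away[2]) > 0
    if (push) "LP" else "LR"
  }
}

#' Maximum force of a classified event
#'
#' The peak of the behaviour-relevant magnitude within the window: `|Fz|` for
#' vertical events, `sqrt(Fx^2 + Fy^2)` for lateral events.
#'
#' @inheritParams classify_event
#' @param behaviour the event class; `NULL` classifies first.
#' @return peak force in pN.
#' @export
max_event_force <- function(ft, away_xy = c(1, 0), window = NULL,
                            behaviour = NULL) {
  if (!is.null(window))
    ft <- ft[ft$t_s >= window[1] & ft$t_s <= window[2], , drop = FALSE]
  if (is.null(behaviour)) behaviour <- classify_event(ft, away_xy)
  if (identical(behaviour, "no event")) return(0)
  if (behaviour %in% c("VP", "VR")) max(abs(ft$Fz))
  else max(sqrt(ft$Fx^2 + ft$Fy^2))
}

#' Event table of a bead trace
#'
#' Detects, classifies and measures all events of a trace.
#'
#' @param trace a `bead_trace`.
#' @param away_xy away-from-cell unit vector.
#' @param floor_pn,min_duration_s,merge_gap_s see [detect_force_events()].
#' @return data.frame `start_s`, `end_s`, `behaviour`, `max_force_pn`.
#' @export
force_events <- function(trace, away_xy = c(1, 0), floor_pn = 1,
                         min_duration_s = 2, merge_gap_s = 1) {
  ft <- force_trace(trace)
  wins <- detect_force_events(ft, floor_pn, min_duration_s, merge_gap_s)
  if (!length(wins))
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      behaviour = character(), max_force_pn = numeric()))
  beh <- vapply(wins, function(w)
    classify_event(ft, away_xy, window = w, floor_pn = floor_pn),
    character(1))
  fmax <- vapply(seq_along(wins), function(i)
    max_event_force(ft, away_xy, window = wins[[i]], behaviour = beh[i]),
    numeric(1))
  data.frame(start_s = vapply(wins, `[`, numeric(1), 1),
             end_s = vapply(wins, `[`, numeric(1), 2),
             behaviour = beh, max_force_pn = fmax)
}

# Rising phase of a lateral displacement series: the longest run of samples
# whose local slope (least squares over a min_duration_s window) is at least
# min_rate_nm_s. Returns c(start_idx, end_idx) or NULL.
#' @noRd
rising_phase <- function(t_s, r_nm, min_rate_nm_s = 5, min_duration_s = 3) {
  n <- length(r_nm)
  dt <- stats::median(diff(t_s))
  w <- max(3L, round(min_duration_s / dt))
  if (n < w + 1L) return(NULL)
  # local slope by centered least squares over w samples
  half <- w %/% 2L
  slope <- rep(NA_real_, n)
  for (i in (half + 1L):(n - half)) {
    sel <- (i - half):(i + half)
    slope[i] <- stats::cov(t_s[sel], r_nm[sel]) / stats::var(t_s[sel])
  }
  longest_run <- function(ok) {
    if (!any(ok)) return(NULL)
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    runs[which.max(runs[, 2] - runs[, 1]), ]
  }
  best <- longest_run(!is.na(slope) & slope >= min_rate_nm_s)
  if (is.null(best)) return(NULL)
  # tighten with a relative threshold: the centered slope stays above half
  # the ramp slope only while the window lies inside the rising phase, so
  # this trims the spill-over past the ramp corners
  thr <- max(min_rate_nm_s, stats::median(slope[best[1]:best[2]]) / 2)
  best <- longest_run(!is.na(slope) & slope >= thr)
  if (is.null(best) || t_s[best[2]] - t_s[best[1]] < min_duration_s)
    return(NULL)
  c(best[1], best[2])
}

#' Lamellipodial protrusion rate from compensated traces
#'
#' Each compensated lateral path is reduced to its total lateral displacement
#' `r(t) = sqrt(x^2 + y^2)`; traces are aligned by maximizing the
#' cross-correlation of their rising phases over integer-sample lags,
#' averaged, and the rate is the least-squares slope of the averaged rising
#' phase. Traces without a detected rising phase (sustained slope of at least
#' `min_rate_nm_s` over `min_duration_s`) are excluded and logged.
#'
#' @param comp_paths list of compensated paths (data.frames with `t_s`, `x`,
#'   `y`, as from [compensate_feedback()]); at least 2.
#' @param min_rate_nm_s minimal sustained slope of a rising phase, nm/s.
#' @param min_duration_s minimal rising-phase duration, seconds.
#' @return list with `rate_nm_s`, `n_traces` used, `excluded` (indices),
#'   `averaged` (data.frame `t_s`, `r_nm` of the aligned average).
#' @export
protrusion_rate <- function(comp_paths, min_rate_nm_s = 5,
                            min_duration_s = 3) {
  stopifnot(length(comp_paths) >= 2)
  rs <- lapply(comp_paths, function(p) sqrt(p$x^2 + p$y^2))
  ts <- lapply(comp_paths, function(p) p$t_s)
  phases <- Map(function(t, r) rising_phase(t, r, min_rate_nm_s,
                                            min_duration_s), ts, rs)
  excluded <- which(vapply(phases, is.null, logical(1)))
  use <- setdiff(seq_along(comp_paths), excluded)
  if (!length(use)) stop("no trace with a detected rising phase")
  ref <- use[1]
  dt <- stats::median(diff(ts[[ref]]))
  n_ref <- length(rs[[ref]])
  lags <- integer(length(comp_paths))
  ref_seg <- phases[[ref]][1]:phases[[ref]][2]
  ref_r <- rs[[ref]]
  for (i in use[-1]) {
    r_i <- rs[[i]]
    best <- c(0L, -Inf)
    for (lag in -(n_ref - 1L):(length(r_i) - 1L)) {
      idx_i <- ref_seg + lag
      valid <- idx_i >= 1 & idx_i <= length(r_i)
      if (sum(valid) < max(4L, length(ref_seg) %/% 2L)) next
      a <- ref_r[ref_seg[valid]]; b <- r_i[idx_i[valid]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      sc <- stats::cor(a, b)
      if (sc > best[2]) best <- c(lag, sc)
    }
    lags[i] <- best[1]
  }
  # average r over the common aligned support; keep rising-window overlap
  onset <- vapply(use, function(i) phases[[i]][1] - lags[i], numeric(1))
  endr <- vapply(use, function(i) phases[[i]][2] - lags[i], numeric(1))
  lo <- max(c(1, onset)); hi <- min(c(n_ref, endr))
  if (hi - lo < 3) stop("aligned rising phases do not overlap")
  idx <- seq(ceiling(lo), floor(hi))
  avg <- rowMeans(vapply(use, function(i) {
    ii <- pmin(pmax(idx + lags[i], 1L), length(rs[[i]]))
    rs[[i]][ii]
  }, numeric(length(idx))))
  t_avg <- ts[[ref]][idx]
  fit <- stats::lsfit(t_avg, avg)
  list(rate_nm_s = unname(fit$coefficients[2]), n_traces = length(use),
       excluded = excluded,
       averaged = data.frame(t_s = t_avg, r_nm = avg))
}
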