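# Filopodium tip tracking. Replaces the manual frame-by-frame tip clicking
# with an automatic tracker: per frame the image is segmented, thinned to a
# skeleton (Zhang-Suen), and each track's tip advances to the skeleton
# endpoint nearest its previous position; the tip is then refined to
# sub-pixel precision from the intensity profile along the rod axis (the
# half-maximum crossing, corrected by the rod's own half-width measured from
# its cross-section at the same relative level).

# Sub-pixel rod length along direction d from base, in pixels.
# Returns NA when no supra-half signal is found along the ray.
#' @noRd
rod_length_subpx <- function(img, base_px, d, scan_px, bg, step = 0.25) {
  u <- seq(0, scan_px, by = step)
  ax <- bilinear_sample(img, base_px[2] + u * d[2] + 1,
                        base_px[1] + u * d[1] + 1)
  half <- bg + 0.5 * (max(ax) - bg)
  above <- ax >= half
  if (!any(above)) return(NA_real_)
  last <- max(which(above))
  u_tip <- if (last == length(u)) u[last] else {
    # linear interpolation of the crossing
    f <- (ax[last] - half) / (ax[last] - ax[last + 1L])
    u[last] + f * step
  }
  # rod half-width at the same relative level, from cross-sections; the
  # minimum over several stations is robust to crossings with other rods
  perp <- c(-d[2], d[1])
  rho <- Inf
  for (frac in c(0.3, 0.5, 0.7)) {
    cpt <- base_px + frac * u_tip * d
    v <- seq(-4, 4, by = step)
    cs <- bilinear_sample(img, cpt[2] + v * perp[2] + 1,
                          cpt[1] + v * perp[1] + 1)
    above_c <- cs >= half
    if (!any(above_c)) next
    runs <- rle(above_c)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    centre <- which.min(abs(v))
    in_run <- which(runs$values & starts <= centre & ends >= centre)
    if (!length(in_run)) next
    w <- (runs$lengths[in_run[1]] - 1) * step / 2
    rho <- min(rho, w)
  }
  if (!is.finite(rho)) rho <- 0
  max(u_tip - rho, 0)
}

#' Track filopodium tips through an image sequence
#'
#' Per frame, the image is thresholded midway between the background median
#' and the maximum, thinned to a skeleton, and each tip advances to the
#' skeleton endpoint nearest its previous position within `search_radius_px`.
#' The tip position and length are then refined to sub-pixel precision from
#' intensity profiles. A tip with no endpoint in range truncates its track
#' (recorded in the `lost_at_frame` attribute).
#'
#' @param frames list of image matrices (the height-0 movie), or the list
#'   returned by [generate_filopodium_tracks()] (its `frames`, `pixel_um` and
#'   `frame_interval_s` are then used).
#' @param seeds n x 2 matrix of initial tip positions, 0-based pixels (x, y).
#' @param bases n x 2 matrix of base positions, 0-based pixels (x, y).
#' @param pixel_um pixel size in micrometers.
#' @param frame_interval_s seconds between frames.
#' @param search_radius_px search radius for the next tip (default 10 px).
#' @return list of tracks; each a data.frame `t_s`, `tip_x`, `tip_y`,
#'   `length_um` with attributes `base_px` and `lost_at_frame` (NA when the
#'   track ran to the end).
#' @export
track_tips <- function(frames, seeds, bases,
                       pixel_um = 0.1, frame_interval_s = 2,
                       search_radius_px = 10) {
  if (!is.null(frames$frames)) {
    pixel_um <- frames$pixel_um
    frame_interval_s <- frames$frame_interval_s
    frames <- frames$frames
  }
  seeds <- matrix(seeds, ncol = 2)
  bases <- matrix(bases, ncol = 2)
  stopifnot(nrow(seeds) == nrow(bases))
  n_filo <- nrow(seeds)
  n_frames <- length(frames)
  t_s <- (seq_len(n_frames) - 1L) * frame_interval_s

  tipx <- matrix(NA_real_, n_frames, n_filo)
  tipy <- matrix(NA_real_, n_frames, n_filo)
  lens <- matrix(NA_real_, n_frames, n_filo)
  lost <- rep(NA_integer_, n_filo)
  prev <- seeds

  for (i in seq_len(n_frames)) {
    img <- frames[[i]]
    bg <- stats::median(img)
    thr <- bg + 0.5 * (max(img) - bg)
    mask <- img > thr
    skel <- thin_mask(mask)
    eps <- skeleton_endpoints(skel)           # (row, col), 1-based
    for (j in seq_len(n_filo)) {
      if (!is.na(lost[j])) next
      if (nrow(eps) == 0) { lost[j] <- i; next }
      dists <- sqrt((eps[, 2] - 1 - prev[j, 1])^2 +
                    (eps[, 1] - 1 - prev[j, 2])^2)
      kbest <- which.min(dists)
      if (dists[kbest] > search_radius_px) { lost[j] <- i; next }
      ep <- c(eps[kbest, 2] - 1, eps[kbest, 1] - 1)   # 0-based (x, y)
      v <- ep - bases[j, ]
      vn <- sqrt(sum(v^2))
      if (vn < 1e-6) { lost[j] <- i; next }
      d <- v / vn
      len_px <- rod_length_subpx(img, bases[j, ], d, vn + 5, bg)
      if (is.na(len_px)) { lost[j] <- i; next }
      tip <- bases[j, ] + len_px * d
      tipx[i, j] <- tip[1]; tipy[i, j] <- tip[2]
      lens[i, j] <- len_px * pixel_um
      prev[j, ] <- tip
    }
  }
  lapply(seq_len(n_filo), function(j) {
    ok <- !is.na(lens[, j])
    tr <- data.frame(t_s = t_s[ok], tip_x = tipx[ok, j], tip_y = tipy[ok, j],
                     length_um = lens[ok, j])
    attr(tr, "base_px") <- bases[j, ]
    attr(tr, "lost_at_frame") <- lost[j]
    tr
  })
}

#' Maximum filopodium length
#'
#' The maximum over frames of the base-to-tip distance, in micrometers.
#'
#' @param track a track data.frame with a `length_um` column (from
#'   [track_tips()] or [generate_filopodium_tracks()]).
#' @return maximal length in micrometers.
#' @export
max_length <- function(track) {
  if (!nrow(track)) stop("empty track")
  max(track$length_um)
}

#' Filopodium protrusion (growth) rate
#'
#' The least-squares slope of length versus time over the growth phase: the
#' frames from the start of the track until the length first comes within
#' `tol_um` of its maximum. Requires at least 3 such frames and a positive
#' slope.
#'
#' @param track a track data.frame with `t_s` and `length_um`.
#' @param tol_um plateau tolerance in micrometers (default 0.1, one pixel at
#'   the default pixel size).
#' @return list with `rate_um_s`, `n_frames`, `window_s`.
#' @export
protrusion_rate_filo <- function(track, tol_um = 0.1) {
  if (nrow(track) < 3) stop("no growth phase: fewer than 3 frames")
  len <- track$length_um
  reach <- which(len >= max(len) - tol_um)[1]
  if (reach < 3) stop("no growth phase: length plateaus immediately")
  sel <- seq_len(reach)
  fit <- stats::lsfit(track$t_s[sel], len[sel])
  rate <- unname(fit$coefficients[2])
  if (rate <= 0) stop("no growth phase: non-positive slope")
  list(rate_um_s = rate, n_frames = reach,
       window_s = c(track$t_s[1], track$t_s[reach]))
}
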