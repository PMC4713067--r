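# Algorithm II: defocus-based vertical-motion analysis. A pixel is taken to
# be in focus at a given plane when its intensity equalises with the
# background (phase objects are invisible at focus and gain contrast with
# defocus); per frame, the number of in-focus pixels at each height is
# normalized by the total across heights, giving the fractional height of
# the lamellipodium.

#' Background intensity of a plane
#'
#' The exact median of all pixel intensities of the plane.
#'
#' @param plane numeric image matrix.
#' @return scalar median intensity.
#' @export
background_intensity <- function(plane) {
  if (!length(plane)) stop("empty plane")
  stats::median(plane)
}

#' Default in-focus tolerance of a plane
#'
#' "Equalises with the background" is degenerate under noise; the default
#' tolerance band is 1.5 robust standard deviations (1.4826 MAD) of the
#' plane. When a region of interest is supplied, the MAD is taken over the
#' pixels outside it: those are background, so the tolerance estimates the
#' camera noise and is comparable across planes (cell contrast would inflate
#' a whole-plane MAD on defocused planes and skew the in-focus counts).
#'
#' @param plane numeric image matrix.
#' @param roi optional logical matrix; the tolerance is computed from pixels
#'   outside it.
#' @return non-negative tolerance in intensity units.
#' @export
focus_tolerance <- function(plane, roi = NULL) {
  vals <- if (is.null(roi) || all(roi)) plane else plane[!roi]
  1.5 * stats::mad(vals)
}

#' In-focus pixel mask of a plane
#'
#' A pixel is in focus iff its intensity is within `tol` of the background
#' intensity and it lies inside the region of interest.
#'
#' @param plane numeric image matrix.
#' @param background background intensity (see [background_intensity()]).
#' @param tol non-negative tolerance in intensity units.
#' @param roi logical matrix restricting the analysed region (the
#'   lamellipodium); see [lamellipodium_roi()].
#' @return logical matrix.
#' @export
in_focus_mask <- function(plane, background = background_intensity(plane),
                          tol = focus_tolerance(plane),
                          roi = matrix(TRUE, nrow(plane), ncol(plane))) {
  stopifnot(tol >= 0, identical(dim(plane), dim(roi)))
  abs(plane - background) <= tol & roi
}

#' Lamellipodium region of interest of one frame
#'
#' The union of the DoG edge maps over the frame's planes, cleaned of small
#' connected components (supra-threshold noise pixels), dilated by `margin`
#' pixels and morphologically closed. Counting all image pixels would be
#' dominated by featureless background, so the in-focus statistics are
#' restricted to the neighbourhood of detected lamellipodial structure; the
#' union over heights is needed because structure is invisible in the very
#' plane where it is in focus — the premise of the defocus analysis — so the
#' height-0 map alone misses the adherent lamellipodium. Finally, pixels
#' that stay within twice the in-focus tolerance of the background at every
#' height carry no height information (they are background swept in by the
#' dilation) and are removed again.
#'
#' @param planes one plane (matrix) or a frame's list of planes.
#' @param margin dilation radius in pixels.
#' @param min_component_px edge-map components smaller than this are dropped
#'   before dilation.
#' @param close_px radius of a morphological closing applied after dilation;
#'   fills the holes the band-pass edge detector leaves inside smoothly
#'   textured regions.
#' @param sigma_small,sigma_large,k DoG parameters, see [extract_edges()].
#' @return logical ROI matrix.
#' @export
lamellipodium_roi <- function(planes, margin = 2L, min_component_px = 10L,
                              close_px = 4L,
                              sigma_small = 1, sigma_large = 3, k = 2) {
  if (is.matrix(planes)) planes <- list(planes)
  clean <- function(e) {
    # drop isolated supra-threshold noise before pooling across planes
    if (min_component_px > 1L && any(e)) {
      lab <- label_components(e)
      sizes <- tabulate(lab[lab > 0L])
      e <- matrix(lab %in% which(sizes >= min_component_px),
                  nrow(e), ncol(e))
    }
    e
  }
  edge <- Reduce(`|`, lapply(planes, function(p) {
    e <- unclass(extract_edges(p, sigma_small, sigma_large, k))
    attributes(e) <- attributes(e)["dim"]
    clean(e)
  }))
  roi <- close_mask(dilate_mask(edge, margin), close_px)
  if (length(planes) > 1 && any(roi) && !all(roi)) {
    rel_dev <- Reduce(pmax, lapply(planes, function(p) {
      tol <- focus_tolerance(p, roi)
      if (tol <= 0) tol <- .Machine$double.eps
      abs(p - background_intensity(p)) / tol
    }))
    roi <- roi & rel_dev > 2
  }
  roi
}

#' Fractional number of in-focus pixels per height over time
#'
#' For every frame and height, the count of in-focus ROI pixels divided by
#' the total count across all heights of that frame. Frames with zero total
#' are emitted as all-zero columns and flagged, keeping the time axis
#' aligned.
#'
#' @param stack an `image_stack_sequence`.
#' @param tol in-focus tolerance; `NULL` (default) uses [focus_tolerance()]
#'   per plane.
#' @param roi `NULL` (default) to derive the ROI per frame with
#'   [lamellipodium_roi()], a single logical matrix, or a list of per-frame
#'   matrices.
#' @param margin ROI dilation margin (used when `roi` is `NULL`).
#' @return a `fractional_height_series`: matrix fraction(height, time) with
#'   attributes `heights_um`, `t_s`, `flagged` (logical per frame) and
#'   `counts` (raw in-focus counts).
#' @export
fractional_height_series <- function(stack, tol = NULL, roi = NULL,
                                     margin = 2L) {
  stopifnot(inherits(stack, "image_stack_sequence"))
  hs <- stack$config$heights_um
  if (length(hs) < 2) stop("need at least 2 heights")
  n <- length(stack$frames)
  counts <- matrix(0L, length(hs), n)
  for (i in seq_len(n)) {
    fr <- stack$frames[[i]]
    roi_i <- if (is.null(roi)) lamellipodium_roi(fr, margin)
             else if (is.list(roi)) roi[[i]] else roi
    for (k in seq_along(hs)) {
      plane <- fr[[k]]
      tol_k <- if (is.null(tol)) focus_tolerance(plane, roi_i) else tol
      counts[k, i] <- sum(in_focus_mask(plane, background_intensity(plane),
                                        tol_k, roi_i))
    }
  }
  totals <- colSums(counts)
  frac <- counts
  nonzero <- totals > 0
  frac[, nonzero] <- sweep(counts[, nonzero, drop = FALSE], 2,
                           totals[nonzero], "/")
  frac[, !nonzero] <- 0
  structure(frac, heights_um = hs,
            t_s = (seq_len(n) - 1L) * stack$config$frame_interval_s,
            flagged = !nonzero, counts = counts,
            class = c("fractional_height_series", "matrix"))
}

#' Maximal height reached by the lamellipodium
#'
#' Per frame, the reached height is the highest plane whose in-focus fraction
#' is at least `threshold`; given cycle boundaries, the per-cycle maximum of
#' the reached height is also returned.
#'
#' @param series a [fractional_height_series()].
#' @param threshold minimal fraction for a height to count as reached
#'   (default 0.1).
#' @param cycle_bounds_s optional vector of cycle boundary times (e.g.
#'   `minima_t_s` from [measure_period()]).
#' @return list with `per_frame_um` (reached height per frame; 0-height
#'   planes count, frames with no height reached give `NA`) and, when
#'   `cycle_bounds_s` is given, `per_cycle_um`.
#' @export
max_height_trace <- function(series, threshold = 0.1,
                             cycle_bounds_s = NULL) {
  stopifnot(inherits(series, "fractional_height_series"), threshold > 0)
  hs <- attr(series, "heights_um")
  t_s <- attr(series, "t_s")
  per_frame <- apply(series, 2, function(col) {
    k <- which(col >= threshold)
    if (!length(k)) NA_real_ else hs[max(k)]
  })
  out <- list(per_frame_um = per_frame, t_s = t_s)
  if (!is.null(cycle_bounds_s) && length(cycle_bounds_s) >= 2) {
    out$per_cycle_um <- vapply(seq_len(length(cycle_bounds_s) - 1L),
      function(i) {
        sel <- t_s >= cycle_bounds_s[i] & t_s <= cycle_bounds_s[i + 1L]
        if (!any(sel) || all(is.na(per_frame[sel]))) NA_real_
        else max(per_frame[sel], na.rm = TRUE)
      }, numeric(1))
  }
  out
}
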