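# Synthetic growth-cone data with known ground truth.
#
# The generators emulate the three kinds of recordings the analysis consumes:
#  * phase-contrast Z-stack movies of a lamellipodial leading edge undergoing
#    sawtooth protrusion/retraction cycles, with retrograde-moving internal
#    texture and a vertical lift of the edge during retraction;
#  * optical-trap bead traces (QPD position + nanopositioner stage position)
#    with scheduled push/retraction events, thermal noise and lateral
#    feedback recentering;
#  * thin filopodial rods elongating from fixed bases.
#
# Contrast model: phase objects are rendered invisible (intensity equal to
# the background) in the plane where they are in focus, and acquire contrast
# that grows and saturates with defocus distance; defocus additionally blurs
# the image with sigma = defocus_blur_per_um * |dz|. A thin bright halo marks
# the leading edge at every plane so the edge is trackable at height 0
# throughout the cycle.

#' Ground-truth motility parameters for the lamellipodium generator
#'
#' The protrusion/retraction cycle is an asymmetric sawtooth: the edge
#' advances at `protrude_rate_um_s` until it has protruded `persistence_um`,
#' then retracts at `retro_rate_um_s` back to baseline. The three quantities
#' period, persistence and retraction rate determine the protrusion rate
#' (`T = dl/v_p + dl/v_r`), so `protrude_rate_um_s` defaults to the derived
#' value and, if supplied, must be consistent.
#'
#' @param period_s cycle period T in seconds.
#' @param persistence_um persistence length dl in micrometers: the maximal
#'   protrusion after which the edge starts to retract.
#' @param retro_rate_um_s retrograde flow rate dx/dt in micrometers/second;
#'   also the speed of the retracting edge and of the rearward-moving
#'   internal texture.
#' @param protrude_rate_um_s leading-edge advance speed; `NULL` (default)
#'   derives it from the other three parameters.
#' @param lift_profile function mapping cycle phase in `[0, 1)` to edge
#'   height in micrometers; defaults to a bump peaking near maximal
#'   retraction (see [lift_profile_bump()]).
#' @param phase0 cycle phase at the first frame (default 0.25,
#'   mid-protrusion): recordings do not start exactly at a cycle minimum.
#' @param n_cycles number of complete cycles covered by the movie.
#' @param noise_sd additive Gaussian intensity noise (camera noise).
#' @param seed integer RNG seed; identical seed and parameters give
#'   bit-identical output.
#' @return an object of class `motility_params`.
#' @export
motility_params <- function(period_s = 86.5,
                            persistence_um = 1.48,
                            retro_rate_um_s = 0.08,
                            protrude_rate_um_s = NULL,
                            lift_profile = lift_profile_bump(),
                            phase0 = 0.25,
                            n_cycles = 5L,
                            noise_sd = 2,
                            seed = 1L) {
  stopifnot(period_s > 0, persistence_um > 0, retro_rate_um_s >= 0,
            n_cycles >= 1, noise_sd >= 0, is.function(lift_profile),
            phase0 >= 0, phase0 < 1)
  t_retract <- persistence_um / retro_rate_um_s
  if (t_retract >= period_s)
    stop("retraction alone (dl / retro_rate = ", signif(t_retract, 4),
         " s) exceeds the period; increase retro_rate_um_s or period_s")
  derived_vp <- persistence_um / (period_s - t_retract)
  if (is.null(protrude_rate_um_s)) {
    protrude_rate_um_s <- derived_vp
  } else if (abs(protrude_rate_um_s - derived_vp) > 1e-9) {
    stop("protrude_rate_um_s inconsistent with period/persistence/retro ",
         "(expected ", signif(derived_vp, 6), " um/s)")
  }
  structure(list(period_s = period_s, persistence_um = persistence_um,
                 retro_rate_um_s = retro_rate_um_s,
                 protrude_rate_um_s = protrude_rate_um_s,
                 lift_profile = lift_profile, phase0 = phase0,
                 n_cycles = as.integer(n_cycles),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "motility_params")
}

#' Default vertical lift profile of the leading edge
#'
#' A Gaussian bump in cycle phase, peaking late in the retraction (the edge
#' lifts up around maximal retraction) and returning to the substrate early
#' in the next protrusion. The bump is evaluated on the circular phase
#' distance so the profile is continuous across the cycle wrap.
#'
#' @param peak_um maximal height in micrometers.
#' @param center cycle phase of the peak, in `[0, 1)`.
#' @param width Gaussian width in phase units.
#' @return a function of phase.
#' @export
lift_profile_bump <- function(peak_um = 5, center = 0.9, width = 0.08) {
  force(peak_um); force(center); force(width)
  function(phase) {
    d <- abs(phase %% 1 - center)
    d <- pmin(d, 1 - d)
    peak_um * exp(-d^2 / (2 * width^2))
  }
}

#' Imaging geometry and acquisition settings
#'
#' @param pixel_um pixel size in micrometers (default 0.1, a 100x objective
#'   on a typical CCD).
#' @param frame_interval_s time between stacks, seconds; must lie in
#'   `[1, 10]` (acquisition at 0.1-1 Hz).
#' @param heights_um ordered plane heights above the coverslip, micrometers.
#' @param image_shape `(rows, cols)` of every plane.
#' @param background_level background intensity.
#' @param defocus_blur_per_um blur sigma in pixels per micrometer of defocus.
#'   The default (0.6 px/um) is deliberately gentle: the height-0 movie must
#'   remain analyzable while the edge lifts through the full height range, as
#'   it is in the recordings this generator emulates.
#' @param focus_scale_um defocus distance over which phase contrast develops
#'   (contrast is `1 - exp(-(dz/focus_scale_um)^2)` of its saturated value).
#' @return an object of class `imaging_config`.
#' @export
imaging_config <- function(pixel_um = 0.1,
                           frame_interval_s = 5,
                           heights_um = 0:6,
                           image_shape = c(60L, 160L),
                           background_level = 100,
                           defocus_blur_per_um = 0.6,
                           focus_scale_um = 0.7) {
  stopifnot(pixel_um > 0, length(image_shape) == 2, all(image_shape >= 8))
  if (length(heights_um) == 0) stop("heights_um must not be empty")
  if (is.unsorted(heights_um, strictly = TRUE))
    stop("heights_um must be strictly increasing")
  if (frame_interval_s < 1 || frame_interval_s > 10)
    stop("frame_interval_s must be within [1, 10] s (0.1-1 Hz acquisition)")
  structure(list(pixel_um = pixel_um, frame_interval_s = frame_interval_s,
                 heights_um = as.numeric(heights_um),
                 image_shape = as.integer(image_shape),
                 background_level = background_level,
                 defocus_blur_per_um = defocus_blur_per_um,
                 focus_scale_um = focus_scale_um),
            class = "imaging_config")
}

#' Analytic sawtooth edge displacement
#'
#' Displacement of the leading edge above its cycle-start baseline, in
#' micrometers, at recording time `t_s` (the recording starts at cycle phase
#' `params$phase0`). Cycles start at the minimum: protrusion at the (derived)
#' protrusion rate, then retraction at `retro_rate_um_s`.
#'
#' @param t_s time(s) in seconds.
#' @param params a [motility_params()] object.
#' @return displacement(s) in `[0, persistence_um]`.
#' @export
sawtooth_edge <- function(t_s, params) {
  T <- params$period_s
  dl <- params$persistence_um
  vr <- params$retro_rate_um_s
  vp <- params$protrude_rate_um_s
  t_p <- dl / vp
  ph <- (t_s + params$phase0 * T) %% T
  ifelse(ph < t_p, vp * ph, pmax(dl - vr * (ph - t_p), 0))
}

# Cumulative rearward shift of the internal texture: stationary during
# protrusion, moving at -retro_rate during retraction.
#' @noRd
texture_shift <- function(t_s, params) {
  T <- params$period_s
  dl <- params$persistence_um
  vr <- params$retro_rate_um_s
  t_p <- dl / params$protrude_rate_um_s
  tt <- t_s + params$phase0 * T
  n_full <- floor(tt / T)
  ph <- tt %% T
  -(n_full * dl + pmax(ph - t_p, 0) * vr)
}

# Smooth positive 1-D texture on [0, extent_um], values in [0.25, 1].
# The 1.2 um correlation length matches the micron-scale ruffles and bundles
# that make up retrograde-moving phase-contrast features, and survives the
# defocus blur of lifted frames.
#' @noRd
make_texture <- function(extent_um, knot_um = 0.7) {
  xk <- seq(-2 * knot_um, extent_um + 2 * knot_um, by = knot_um)
  yk <- stats::runif(length(xk))
  f <- stats::splinefun(xk, yk, method = "natural")
  function(x) {
    v <- f(pmin(pmax(x, xk[1]), xk[length(xk)]))
    0.25 + 0.75 * pmin(pmax(v, 0), 1)
  }
}

#' Generate a synthetic lamellipodium Z-stack movie
#'
#' Renders a bright-rimmed cell region whose leading edge follows the
#' sawtooth of `params` along the image x axis (cell body on the left),
#' internal texture that translates rearward at the retrograde rate during
#' retraction (producing dark kymograph streaks), and a vertical lift of the
#' region following `params$lift_profile`, rendered with the defocus contrast
#' model described above.
#'
#' @param params a [motility_params()] object.
#' @param config an [imaging_config()] object.
#' @return an object of class `image_stack_sequence`: list with `frames`
#'   (per time point, a list of one matrix per height), `config`, `params`,
#'   and `ground_truth` (data.frame: frame, t_s, phase, edge_um, height_um).
#' @export
generate_lamellipodium_stack <- function(params, config = imaging_config()) {
  stopifnot(inherits(params, "motility_params"),
            inherits(config, "imaging_config"))
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  width_um <- (nc - 1) * config$pixel_um
  if (params$persistence_um > 0.4 * width_um)
    stop("persistence_um too large for the field of view (",
         signif(width_um, 4), " um wide)")
  hs <- config$heights_um
  h_rng <- range(hs)
  dt <- config$frame_interval_s
  # cover n_cycles complete cycles: with a mid-cycle start the movie spans
  # n_cycles + 1 minima
  n_frames <- ceiling((params$n_cycles + 1) * params$period_s / dt) + 1L
  t_s <- (seq_len(n_frames) - 1L) * dt

  set.seed(params$seed)
  total_shift <- (params$n_cycles + 2) * params$persistence_um + 2
  texture <- make_texture(width_um + total_shift)

  x_px <- (seq_len(nc) - 1) * config$pixel_um   # column-centre positions, um
  # baseline edge position: cell must stay under half the field so the
  # plane median reads the background
  x0 <- 0.35 * width_um - 0.5 * params$persistence_um
  edge_um <- x0 + sawtooth_edge(t_s, params)
  phase <- ((t_s + params$phase0 * params$period_s) %% params$period_s) /
    params$period_s
  height_um <- params$lift_profile(phase)
  if (any(height_um < h_rng[1] - 1e-9 | height_um > h_rng[2] + 1e-9))
    stop("lift_profile leaves the configured height range [",
         h_rng[1], ", ", h_rng[2], "] um")

  halo_amp <- 60; halo_w <- 0.12                # um
  tex_base <- 10; tex_amp <- 30
  rim_um <- 1.0; rim_contrast <- 0.25           # organelle-free rim zone
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    xe <- edge_um[i]
    he <- height_um[i]
    # anti-aliased cell occupancy along x
    occ <- pmin(pmax((xe - x_px) / config$pixel_um + 0.5, 0), 1)
    # the thin rim behind the edge is nearly transparent; full texture
    # contrast develops rim_um behind the edge
    rim <- rim_contrast + (1 - rim_contrast) *
      pmin(pmax(((xe - rim_um) - x_px) / 0.3, 0), 1)
    dev_tex <- occ * rim *
      (tex_base + tex_amp * texture(x_px - texture_shift(t_s[i], params)))
    halo <- halo_amp * exp(-((x_px - xe) / halo_w)^2)
    planes <- vector("list", length(hs))
    for (k in seq_along(hs)) {
      dz <- abs(hs[k] - he)
      g <- 1 - exp(-(dz / config$focus_scale_um)^2)
      prof <- g * dev_tex + halo
      sigma <- config$defocus_blur_per_um * dz
      if (sigma > 0) {
        kern <- gaussian_kernel_1d(sigma)
        half <- (length(kern) - 1L) %/% 2L
        padded <- c(rep(prof[1], half), prof, rep(prof[nc], half))
        prof <- as.numeric(stats::filter(padded, kern, sides = 2))[half + seq_len(nc)]
      }
      img <- matrix(rep(prof, each = nr), nrow = nr) + config$background_level
      if (params$noise_sd > 0)
        img <- img + matrix(stats::rnorm(nr * nc, 0, params$noise_sd), nr, nc)
      planes[[k]] <- img
    }
    frames[[i]] <- planes
  }
  structure(list(frames = frames, config = config, params = params,
                 ground_truth = data.frame(frame = seq_len(n_frames),
                                           t_s = t_s, phase = phase,
                                           edge_um = edge_um,
                                           height_um = height_um)),
            class = "image_stack_sequence")
}

#' Assemble an image stack sequence from raw planes
#'
#' Wraps externally built (or manipulated) planes in the container the
#' analyzers consume. Every frame must have one plane per configured height
#' and all planes must share the configured shape.
#'
#' @param frames list (over time) of lists (over heights) of numeric
#'   matrices.
#' @param config an [imaging_config()].
#' @param ground_truth optional ground-truth data.frame.
#' @return an `image_stack_sequence`.
#' @export
image_stack_sequence <- function(frames, config, ground_truth = NULL) {
  stopifnot(inherits(config, "imaging_config"), length(frames) >= 1)
  nh <- length(config$heights_um)
  ok <- vapply(frames, function(fr) {
    length(fr) == nh && all(vapply(fr, function(p)
      identical(dim(p), as.integer(config$image_shape)), logical(1)))
  }, logical(1))
  if (!all(ok))
    stop("every frame needs one plane per height, all of image_shape")
  structure(list(frames = frames, config = config, params = NULL,
                 ground_truth = ground_truth),
            class = "image_stack_sequence")
}

#' Configuration of the optical-trap bead simulator
#'
#' @param stiffness_pn_nm trap stiffness `(k_xy, k_z)` in pN/nm; defaults to
#'   the measured values 0.10 (lateral) and 0.08 (axial).
#' @param feedback_threshold_nm lateral displacement beyond which the
#'   nanopositioner recenters the bead (default 200 nm, the QPD linear range).
#' @param thermal_sd_nm sd of thermal position fluctuations, nm. The default
#'   6.4 nm is the equipartition value `sqrt(kB T / k_xy)` at room
#'   temperature for k_xy = 0.10 pN/nm.
#' @param event_schedule list of events from [bead_event()]; must not overlap.
#' @param sample_rate_hz sampling rate of the recorded trace.
#' @param duration_s total trace duration; default covers the schedule + 5 s.
#' @param seed integer RNG seed.
#' @return an object of class `bead_sim_config`.
#' @export
bead_sim_config <- function(stiffness_pn_nm = c(0.10, 0.08),
                            feedback_threshold_nm = 200,
                            thermal_sd_nm = 6.4,
                            event_schedule = list(),
                            sample_rate_hz = 10,
                            duration_s = NULL,
                            seed = 1L) {
  stopifnot(length(stiffness_pn_nm) == 2, all(stiffness_pn_nm > 0),
            feedback_threshold_nm > 0, thermal_sd_nm >= 0, sample_rate_hz > 0)
  if (length(event_schedule)) {
    ivals <- t(vapply(event_schedule,
                      function(e) c(e$start_s, e$start_s + e$duration_s),
                      numeric(2)))
    o <- order(ivals[, 1])
    ivals <- ivals[o, , drop = FALSE]
    if (nrow(ivals) > 1 && any(ivals[-1, 1] < ivals[-nrow(ivals), 2]))
      stop("event schedule contains overlapping events")
  }
  if (is.null(duration_s)) {
    duration_s <- if (length(event_schedule))
      max(vapply(event_schedule, function(e) e$start_s + e$duration_s,
                 numeric(1))) + 5 else 10
  }
  structure(list(stiffness_pn_nm = as.numeric(stiffness_pn_nm),
                 feedback_threshold_nm = feedback_threshold_nm,
                 thermal_sd_nm = thermal_sd_nm,
                 event_schedule = event_schedule,
                 sample_rate_hz = sample_rate_hz,
                 duration_s = duration_s, seed = as.integer(seed)),
            class = "bead_sim_config")
}

#' A scheduled bead-driving event
#'
#' @param start_s event start, seconds.
#' @param direction one of `"+x","-x","+y","-y","+z","-z"`.
#' @param speed_nm_s driving speed, nm/s (non-negative).
#' @param duration_s event duration, seconds (non-negative).
#' @return a list describing the event.
#' @export
bead_event <- function(start_s, direction, speed_nm_s, duration_s) {
  dirs <- c("+x", "-x", "+y", "-y", "+z", "-z")
  if (!direction %in% dirs)
    stop("direction must be one of ", paste(dirs, collapse = ", "))
  if (speed_nm_s < 0) stop("speed_nm_s must be non-negative")
  if (duration_s < 0) stop("duration_s must be non-negative")
  list(start_s = start_s, direction = direction,
       speed_nm_s = speed_nm_s, duration_s = duration_s)
}

#' @noRd
direction_vector <- function(direction) {
  sgn <- if (substr(direction, 1, 1) == "+") 1 else -1
  axis <- match(substr(direction, 2, 2), c("x", "y", "z"))
  v <- c(0, 0, 0); v[axis] <- sgn
  v
}

#' Simulate an optical-trap bead trace with nanopositioner feedback
#'
#' Between events the bead fluctuates about the trap centre with sd
#' `thermal_sd_nm`; during an event it is driven at the scheduled speed. When
#' the lateral QPD displacement `r = sqrt(x^2 + y^2)` exceeded the feedback
#' threshold at the previous sample, the stage jumps so the bead returns to
#' the trap centre (z is never recentered). The ground-truth force is
#' stiffness times the true (noise-free) deflection.
#'
#' @param config a [bead_sim_config()] object.
#' @return object of class `bead_trace`: list with `t_s`, `qpd_nm` (n x 3
#'   matrix, bead position relative to trap centre), `stage_nm` (n x 2 stage
#'   position), `true_deflection_nm` (n x 3), `ground_truth_force_pn`
#'   (n x 3), `config`.
#' @export
generate_bead_trace <- function(config) {
  stopifnot(inherits(config, "bead_sim_config"))
  dt <- 1 / config$sample_rate_hz
  n <- max(2L, floor(config$duration_s / dt) + 1L)
  t_s <- (seq_len(n) - 1L) * dt

  # cumulative driven displacement u(t)
  vel <- matrix(0, n, 3)
  for (e in config$event_schedule) {
    active <- t_s >= e$start_s & t_s < e$start_s + e$duration_s
    vel[active, ] <- vel[active, ] +
      matrix(direction_vector(e$direction) * e$speed_nm_s,
             sum(active), 3, byrow = TRUE)
  }
  u <- apply(vel * dt, 2, cumsum)
  u <- rbind(0, u[-n, , drop = FALSE])   # displacement accrued before sample

  set.seed(config$seed)
  noise <- if (config$thermal_sd_nm > 0)
    matrix(stats::rnorm(n * 3, 0, config$thermal_sd_nm), n, 3)
  else matrix(0, n, 3)

  stage <- matrix(0, n, 2)
  qpd <- matrix(0, n, 3)
  true_defl <- matrix(0, n, 3)
  thr <- config$feedback_threshold_nm
  for (i in seq_len(n)) {
    if (i > 1) {
      stage[i, ] <- stage[i - 1, ]
      r_prev <- sqrt(sum(qpd[i - 1, 1:2]^2))
      if (r_prev > thr)
        stage[i, ] <- stage[i, ] + qpd[i - 1, 1:2]
    }
    true_defl[i, ] <- u[i, ] - c(stage[i, ], 0)
    qpd[i, ] <- true_defl[i, ] + noise[i, ]
  }
  force <- cbind(config$stiffness_pn_nm[1] * true_defl[, 1],
                 config$stiffness_pn_nm[1] * true_defl[, 2],
                 config$stiffness_pn_nm[2] * true_defl[, 3])
  colnames(qpd) <- colnames(true_defl) <- c("x", "y", "z")
  colnames(force) <- c("Fx", "Fy", "Fz")
  colnames(stage) <- c("x", "y")
  structure(list(t_s = t_s, qpd_nm = qpd, stage_nm = stage,
                 true_deflection_nm = true_defl,
                 ground_truth_force_pn = force, config = config),
            class = "bead_trace")
}

#' Generate elongating filopodial rods with ground truth
#'
#' Thin bright rods elongate from fixed bases at `rate_um_s` until they reach
#' `max_len_um`, rendered into a single-height image sequence.
#'
#' @param n number of filopodia.
#' @param rate_um_s elongation rate, micrometers/second.
#' @param max_len_um maximal length, micrometers.
#' @param frame_interval_s seconds between frames.
#' @param seed integer RNG seed.
#' @param start_len_um initial length (default 0.5 um).
#' @param duration_s movie duration; default long enough to reach
#'   `max_len_um` plus three extra frames.
#' @param pixel_um pixel size.
#' @param image_shape `(rows, cols)`.
#' @param background_level,amplitude background and rod intensity.
#' @param noise_sd additive Gaussian intensity noise.
#' @param bases optional n x 2 matrix of base positions (0-based px, x then
#'   y); default placed near the image centre.
#' @param angles_deg optional rod directions in degrees; default random.
#' @return list with `tracks` (per filopodium: data.frame `t_s`, `tip_x`,
#'   `tip_y` in 0-based pixels, `length_um`, plus attributes `base_px`),
#'   `frames` (list of matrices), `pixel_um`, `frame_interval_s`.
#' @export
generate_filopodium_tracks <- function(n = 1L, rate_um_s = 0.10,
                                       max_len_um = 3.36,
                                       frame_interval_s = 2,
                                       seed = 1L,
                                       start_len_um = 0.5,
                                       duration_s = NULL,
                                       pixel_um = 0.1,
                                       image_shape = c(120L, 120L),
                                       background_level = 20,
                                       amplitude = 80,
                                       noise_sd = 2,
                                       bases = NULL,
                                       angles_deg = NULL) {
  stopifnot(n >= 1, rate_um_s >= 0, max_len_um > 0, start_len_um >= 0,
            start_len_um <= max_len_um, frame_interval_s > 0)
  if (is.null(duration_s)) {
    duration_s <- if (rate_um_s > 0)
      (max_len_um - start_len_um) / rate_um_s + 3 * frame_interval_s
    else 10 * frame_interval_s
  }
  n_frames <- floor(duration_s / frame_interval_s) + 1L
  t_s <- (seq_len(n_frames) - 1L) * frame_interval_s
  nr <- image_shape[1]; nc <- image_shape[2]

  set.seed(seed)
  if (is.null(angles_deg)) angles_deg <- stats::runif(n, 0, 360)
  max_px <- max_len_um / pixel_um
  if (is.null(bases)) {
    # auto-placed bases near the centre must leave room for full-length rods
    if (max_px > min(nr, nc) / 2 - 9)
      stop("max_len_um does not fit in the field of view")
    cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
    bases <- cbind(cx + stats::runif(n, -5, 5), cy + stats::runif(n, -5, 5))
  }
  bases <- matrix(bases, ncol = 2)

  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)   # x coordinate per pixel
  ys <- matrix(rep(0:(nr - 1), nc), nr, nc)
  halfwidth_px <- 1.0

  lengths_um <- pmin(start_len_um + rate_um_s * t_s, max_len_um)
  frames <- vector("list", n_frames)
  tipx <- matrix(0, n_frames, n); tipy <- matrix(0, n_frames, n)
  noise_list <- lapply(seq_len(n_frames), function(i)
    if (noise_sd > 0) matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
    else matrix(0, nr, nc))
  for (i in seq_len(n_frames)) {
    img <- matrix(0, nr, nc)
    for (j in seq_len(n)) {
      a <- angles_deg[j] * pi / 180
      d <- c(cos(a), sin(a))
      len_px <- lengths_um[i] / pixel_um
      tip <- bases[j, ] + d * len_px
      tipx[i, j] <- tip[1]; tipy[i, j] <- tip[2]
      # distance from every pixel to the base-tip segment
      px <- xs - bases[j, 1]; py <- ys - bases[j, 2]
      tproj <- pmin(pmax(px * d[1] + py * d[2], 0), len_px)
      dist <- sqrt((px - tproj * d[1])^2 + (py - tproj * d[2])^2)
      cov <- pmin(pmax(halfwidth_px - dist + 0.5, 0), 1)
      img <- pmax(img, cov)
    }
    frames[[i]] <- background_level + amplitude * img + noise_list[[i]]
  }
  tracks <- lapply(seq_len(n), function(j) {
    tr <- data.frame(t_s = t_s, tip_x = tipx[, j], tip_y = tipy[, j],
                     length_um = lengths_um)
    attr(tr, "base_px") <- bases[j, ]
    attr(tr, "angle_deg") <- angles_deg[j]
    tr
  })
  list(tracks = tracks, frames = frames, pixel_um = pixel_um,
       frame_interval_s = frame_interval_s,
       background_level = background_level)
}
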