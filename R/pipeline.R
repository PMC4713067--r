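# File I/O for stacks and bead traces, pipeline configuration, and the
# end-to-end driver: generate -> analyze (kymograph, fractional height,
# force, filopodia) -> summarize. All CSV output is comma-separated, header
# row, UTF-8, "." decimal; image coordinates are 0-based with x = column.

#' Write an image stack sequence to a multi-page TIFF with sidecars
#'
#' Pages are grouped by height (one series per height, page order = time).
#' Alongside `path`, a JSON config echo (`<path>.json`) and, when ground
#' truth is present, a ground-truth CSV (`<path>.ground_truth.csv` with
#' frame, t_s, true_edge_um, true_height_um) are written.
#'
#' @param stack an `image_stack_sequence`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack_sequence"))
  hs <- stack$config$heights_um
  pages <- list()
  for (k in seq_along(hs))
    for (i in seq_along(stack$frames))
      pages[[length(pages) + 1L]] <- stack$frames[[i]][[k]]
  write_tiff(pages, path)
  cfg <- stack$config
  jsonlite::write_json(
    list(pixel_um = cfg$pixel_um, frame_interval_s = cfg$frame_interval_s,
         heights_um = cfg$heights_um, image_shape = cfg$image_shape,
         background_level = cfg$background_level,
         defocus_blur_per_um = cfg$defocus_blur_per_um,
         focus_scale_um = cfg$focus_scale_um),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(stack$ground_truth)) {
    gt <- stack$ground_truth
    utils::write.csv(
      data.frame(frame = gt$frame, t_s = gt$t_s,
                 true_edge_um = gt$edge_um, true_height_um = gt$height_um),
      paste0(path, ".ground_truth.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read an image stack sequence from a multi-page TIFF
#'
#' Expects the sidecar JSON written by [write_stack()]; the page count must
#' be divisible by the number of configured heights.
#'
#' @param path TIFF path.
#' @return an `image_stack_sequence` (without ground truth).
#' @export
read_stack <- function(path) {
  cfg_path <- paste0(path, ".json")
  if (!file.exists(cfg_path)) stop("missing sidecar config: ", cfg_path)
  j <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  config <- imaging_config(pixel_um = j$pixel_um,
                           frame_interval_s = j$frame_interval_s,
                           heights_um = j$heights_um,
                           image_shape = j$image_shape,
                           background_level = j$background_level,
                           defocus_blur_per_um = j$defocus_blur_per_um,
                           focus_scale_um = j$focus_scale_um)
  pages <- read_tiff(path)
  nh <- length(config$heights_um)
  if (length(pages) %% nh != 0)
    stop("page count mismatch: found ", length(pages),
         " pages, not divisible by ", nh, " heights")
  nf <- length(pages) %/% nh
  frames <- lapply(seq_len(nf), function(i)
    lapply(seq_len(nh), function(k) pages[[(k - 1L) * nf + i]]))
  structure(list(frames = frames, config = config, params = NULL,
                 ground_truth = NULL),
            class = "image_stack_sequence")
}

#' Write a bead trace to CSV
#'
#' Columns: t_s, qpd_x_nm, qpd_y_nm, qpd_z_nm, stage_x_nm, stage_y_nm. A JSON
#' sidecar (`<path>.json`) echoes stiffness, threshold and sample rate.
#'
#' @param trace a `bead_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bead_trace <- function(trace, path) {
  stopifnot(inherits(trace, "bead_trace"))
  utils::write.csv(
    data.frame(t_s = trace$t_s,
               qpd_x_nm = trace$qpd_nm[, 1], qpd_y_nm = trace$qpd_nm[, 2],
               qpd_z_nm = trace$qpd_nm[, 3],
               stage_x_nm = trace$stage_nm[, 1],
               stage_y_nm = trace$stage_nm[, 2]),
    path, row.names = FALSE)
  cfg <- trace$config
  jsonlite::write_json(
    list(stiffness_pn_nm = cfg$stiffness_pn_nm,
         feedback_threshold_nm = cfg$feedback_threshold_nm,
         sample_rate_hz = cfg$sample_rate_hz),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a bead trace from CSV
#'
#' @param path CSV path written by [write_bead_trace()] (or following its
#'   schema); the JSON sidecar supplies stiffness and threshold when present.
#' @param stiffness_pn_nm,feedback_threshold_nm,sample_rate_hz overrides when
#'   no sidecar exists.
#' @return a `bead_trace` (without ground truth).
#' @export
read_bead_trace <- function(path, stiffness_pn_nm = c(0.10, 0.08),
                            feedback_threshold_nm = 200,
                            sample_rate_hz = NULL) {
  d <- utils::read.csv(path)
  need <- c("t_s", "qpd_x_nm", "qpd_y_nm", "qpd_z_nm",
            "stage_x_nm", "stage_y_nm")
  if (!all(need %in% names(d)))
    stop("bead trace CSV must have columns: ", paste(need, collapse = ", "))
  cfg_path <- paste0(path, ".json")
  if (file.exists(cfg_path)) {
    j <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    stiffness_pn_nm <- j$stiffness_pn_nm
    feedback_threshold_nm <- j$feedback_threshold_nm
    sample_rate_hz <- j$sample_rate_hz
  }
  if (is.null(sample_rate_hz))
    sample_rate_hz <- 1 / stats::median(diff(d$t_s))
  config <- bead_sim_config(stiffness_pn_nm = stiffness_pn_nm,
                            feedback_threshold_nm = feedback_threshold_nm,
                            thermal_sd_nm = 0, event_schedule = list(),
                            sample_rate_hz = sample_rate_hz,
                            duration_s = max(d$t_s))
  structure(list(t_s = d$t_s,
                 qpd_nm = cbind(x = d$qpd_x_nm, y = d$qpd_y_nm,
                                z = d$qpd_z_nm),
                 stage_nm = cbind(x = d$stage_x_nm, y = d$stage_y_nm),
                 true_deflection_nm = NULL, ground_truth_force_pn = NULL,
                 config = config),
            class = "bead_trace")
}

# Rolling hash of a string, reported as 8 hex digits; used to stamp outputs
# with the configuration they came from.
#' @noRd
config_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Bundles the generator settings, algorithm parameters, output directory and
#' seed for [run_pipeline()]. Unknown algorithm parameters are rejected.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed.
#' @param motility a [motility_params()] object (its `seed` is re-derived
#'   from `seed`).
#' @param imaging an [imaging_config()] object.
#' @param bead a [bead_sim_config()] object, or `NULL` to skip the force
#'   stage.
#' @param filo list of arguments for [generate_filopodium_tracks()], or
#'   `NULL` to skip the filopodia stage.
#' @param algorithm named list of analysis parameters; allowed names:
#'   `sigma_small`, `sigma_large`, `k`, `min_period_s`, `smooth_window`,
#'   `max_rate_um_s`, `grid_step_um_s`, `tol`, `roi_margin`,
#'   `height_threshold`, `floor_pn`, `min_duration_s`, `merge_gap_s`,
#'   `away_xy`.
#' @param condition label for the simulated condition.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            motility = motility_params(),
                            imaging = imaging_config(),
                            bead = bead_sim_config(
                              event_schedule = list(
                                bead_event(2, "+x", 50, 10)),
                              duration_s = 20),
                            filo = list(n = 2L),
                            algorithm = list(),
                            condition = "control") {
  allowed <- c("sigma_small", "sigma_large", "k", "min_period_s",
               "smooth_window", "max_rate_um_s", "grid_step_um_s", "tol",
               "roi_margin", "height_threshold", "floor_pn",
               "min_duration_s", "merge_gap_s", "away_xy")
  unknown <- setdiff(names(algorithm), allowed)
  if (length(unknown))
    stop("unknown algorithm parameter(s): ", paste(unknown, collapse = ", "))
  defaults <- list(sigma_small = 1, sigma_large = 3, k = 2,
                   min_period_s = 20, smooth_window = 3L,
                   max_rate_um_s = 0.3, grid_step_um_s = 0.0025, tol = NULL,
                   roi_margin = 2L, height_threshold = 0.1, floor_pn = 1,
                   min_duration_s = 2, merge_gap_s = 1, away_xy = c(1, 0))
  algorithm <- utils::modifyList(defaults, algorithm)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 motility = motility, imaging = imaging, bead = bead,
                 filo = filo, algorithm = algorithm, condition = condition),
            class = "pipeline_config")
}

#' Run the end-to-end pipeline
#'
#' Generates the configured synthetic data, runs every analysis stage whose
#' inputs are available, writes all CSV/TIFF outputs and a JSON run log
#' (parameters, seed, config hash, per-stage status and warnings) into
#' `config$out_dir`. A failing stage is recorded and the remaining
#' independent stages still run. Deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with per-stage results and `errors`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  alg <- config$algorithm
  errors <- list()
  results <- list()
  note <- function(stage, e) errors[[stage]] <<- conditionMessage(e)

  # --- simulate ------------------------------------------------------------
  stack <- NULL; beads <- NULL; filo <- NULL
  tryCatch({
    mp <- config$motility; mp$seed <- config$seed
    stack <- generate_lamellipodium_stack(mp, config$imaging)
    write_stack(stack, file.path(config$out_dir, "stack.tif"))
    if (!is.null(config$bead)) {
      bc <- config$bead; bc$seed <- config$seed + 1000L
      beads <- generate_bead_trace(bc)
      write_bead_trace(beads, file.path(config$out_dir, "bead_trace.csv"))
    }
    if (!is.null(config$filo)) {
      fa <- utils::modifyList(list(seed = config$seed + 2000L), config$filo)
      filo <- do.call(generate_filopodium_tracks, fa)
    }
    results$simulate <- "ok"
  }, error = function(e) note("simulate", e))

  # --- kymograph (Algorithm I) --------------------------------------------
  tryCatch({
    if (is.null(stack)) stop("no stack available")
    line <- default_sampling_line(stack)
    cm <- cycle_metrics(stack, line, alg$sigma_small, alg$sigma_large,
                        alg$k, alg$min_period_s, alg$smooth_window,
                        alg$max_rate_um_s, alg$grid_step_um_s)
    utils::write.csv(
      data.frame(line_id = 1L, T_s = cm$period_s, dl_um = cm$persistence_um,
                 dxdt_um_s = cm$retro_rate_um_s, n_cycles = cm$n_cycles),
      file.path(config$out_dir, "cycle_metrics.csv"), row.names = FALSE)
    results$kymo <- cm
  }, error = function(e) note("kymo", e))

  # --- fractional height (Algorithm II) -----------------------------------
  tryCatch({
    if (is.null(stack)) stop("no stack available")
    fhs <- fractional_height_series(stack, tol = alg$tol,
                                    margin = alg$roi_margin)
    hs <- attr(fhs, "heights_um"); t_s <- attr(fhs, "t_s")
    long <- data.frame(t_s = rep(t_s, each = length(hs)),
                       height_um = rep(hs, length(t_s)),
                       fraction = as.vector(fhs),
                       flagged = rep(attr(fhs, "flagged"),
                                     each = length(hs)))
    utils::write.csv(long, file.path(config$out_dir, "fractional_height.csv"),
                     row.names = FALSE)
    mh <- max_height_trace(fhs, alg$height_threshold)
    utils::write.csv(
      data.frame(t_s = t_s, reached_height_um = mh$per_frame_um),
      file.path(config$out_dir, "max_height.csv"), row.names = FALSE)
    results$height <- fhs
  }, error = function(e) note("height", e))

  # --- force ---------------------------------------------------------------
  tryCatch({
    if (is.null(beads)) stop("no bead trace available (bead config missing)")
    ft <- force_trace(beads)
    utils::write.csv(
      data.frame(t_s = ft$t_s, F_x = ft$Fx, F_y = ft$Fy, F_z = ft$Fz,
                 comp_x_nm = ft$comp_x_nm, comp_y_nm = ft$comp_y_nm),
      file.path(config$out_dir, "force_trace.csv"), row.names = FALSE)
    ev <- force_events(beads, alg$away_xy, alg$floor_pn,
                       alg$min_duration_s, alg$merge_gap_s)
    utils::write.csv(ev, file.path(config$out_dir, "force_events.csv"),
                     row.names = FALSE)
    results$force <- ev
  }, error = function(e) note("force", e))

  # --- filopodia -----------------------------------------------------------
  tryCatch({
    if (is.null(filo)) stop("no filopodia movie available")
    seeds <- t(vapply(filo$tracks, function(tr)
      c(tr$tip_x[1], tr$tip_y[1]), numeric(2)))
    bases <- t(vapply(filo$tracks, function(tr) attr(tr, "base_px"),
                      numeric(2)))
    tracks <- track_tips(filo, seeds, bases)
    long <- do.call(rbind, lapply(seq_along(tracks), function(j)
      cbind(filo_id = j, tracks[[j]])))
    utils::write.csv(long, file.path(config$out_dir, "filopodia_tracks.csv"),
                     row.names = FALSE)
    summ <- do.call(rbind, lapply(seq_along(tracks), function(j) {
      rate <- tryCatch(protrusion_rate_filo(tracks[[j]])$rate_um_s,
                       error = function(e) NA_real_)
      data.frame(filo_id = j, max_length_um = max_length(tracks[[j]]),
                 rate_um_s = rate)
    }))
    utils::write.csv(summ, file.path(config$out_dir, "filopodia_summary.csv"),
                     row.names = FALSE)
    results$filo <- summ
  }, error = function(e) note("filo", e))

  # --- stats ---------------------------------------------------------------
  tryCatch({
    rows <- list()
    if (!is.null(results$kymo)) {
      pc <- results$kymo$per_cycle
      rows <- c(rows, list(
        summarize_group(pc$period_s, config$condition, "s"),
        summarize_group(pc$persistence_um, config$condition, "um"),
        summarize_group(abs(pc$retro_um_s[!is.na(pc$retro_um_s)]),
                        config$condition, "um/s")))
      rows[[1]]$metric <- "period"; rows[[2]]$metric <- "persistence"
      rows[[3]]$metric <- "retrograde_flow"
    }
    if (!is.null(results$filo) && nrow(results$filo)) {
      s1 <- summarize_group(results$filo$max_length_um, config$condition,
                            "um"); s1$metric <- "filo_max_length"
      s2 <- summarize_group(results$filo$rate_um_s[
        !is.na(results$filo$rate_um_s)], config$condition, "um/s")
      s2$metric <- "filo_rate"
      rows <- c(rows, list(s1, s2))
    }
    if (!length(rows)) stop("no upstream results to summarize")
    summary <- do.call(rbind, rows)[, c("label", "metric", "n", "mean",
                                        "sem", "unit")]
    names(summary)[1] <- "condition"
    utils::write.csv(summary, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    results$stats <- summary
  }, error = function(e) note("stats", e))

  cfg_json <- jsonlite::toJSON(
    list(seed = config$seed, condition = config$condition,
         algorithm = alg[!vapply(alg, is.null, logical(1))]),
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(config_hash = config_hash(as.character(cfg_json)),
         seed = config$seed, condition = config$condition,
         r_version = as.character(getRversion()),
         stages_ok = names(results), errors = errors),
    file.path(config$out_dir, "run_log.json"), auto_unbox = TRUE)
  invisible(c(results, list(errors = errors)))
}
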