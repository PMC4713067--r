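# Algorithm I: DoG edge extraction, edge tracking, kymograph construction,
# and the period / persistence / retrograde-flow estimators.

test_that("DoG localizes a step edge within one pixel", {
  img <- matrix(0, 40, 100)
  img[, 50:100] <- 100
  edge <- extract_edges(img, 1, 3)
  resp <- attr(edge, "response")
  # strongest response along a middle row sits at the step
  expect_lte(abs(which.max(abs(resp[20, ])) - 50), 1)
  expect_true(any(edge[, 48:52]))
})

test_that("a constant image yields an empty edge map", {
  img <- matrix(17, 30, 40)
  edge <- extract_edges(img)
  expect_false(any(edge))
})

test_that("noiseless frames give edge positions within one pixel of truth", {
  p <- small_params(noise_sd = 0)
  st <- generate_lamellipodium_stack(p, small_config())
  prof <- track_leading_edge(st)
  # the sampling line starts at x = 1 px, so positions are offset by 1 px
  err_px <- (prof$position_um + st$config$pixel_um -
               st$ground_truth$edge_um) / st$config$pixel_um
  expect_lt(max(abs(err_px)), 1)
})

test_that("a static edge tracks to a constant profile", {
  img <- matrix(100, 40, 120)
  img[, 1:60] <- 140
  st <- raw_stack(replicate(8, img + matrix(rnorm(4800, 0, 1), 40), simplify = FALSE))
  prof <- track_leading_edge(st)
  expect_lt(diff(range(prof$position_um)), 0.15)
})

test_that("dropout frames are linearly interpolated and flagged", {
  img1 <- matrix(100, 40, 120); img1[, 1:50] <- 140
  img3 <- matrix(100, 40, 120); img3[, 1:60] <- 140
  blank <- matrix(100, 40, 120)               # no edge at all
  st <- raw_stack(list(img1, blank, img3))
  prof <- track_leading_edge(st)
  expect_true(prof$interpolated[2])
  expect_equal(prof$position_um[2],
               mean(prof$position_um[c(1, 3)]))
  expect_match(attr(prof, "warnings"), "10%")
  # no edge anywhere is a failure
  st_empty <- raw_stack(replicate(3, blank, simplify = FALSE))
  expect_error(track_leading_edge(st_empty), "no edge")
})

test_that("kymographs sample the line exactly", {
  cm <- matrix(23.5, 40, 120)
  st <- raw_stack(replicate(6, cm, simplify = FALSE))
  line <- sampling_line(c(2, 20), c(100, 20))
  ky <- build_kymograph(st, line)
  expect_true(all(ky == 23.5))
  expect_equal(dim(ky), c(99L, 6L))           # length L px over N frames
  expect_error(sampling_line(c(0, 0), c(5, 5)), "20 px")
})

test_that("streak slope matches an independent orientation-scoring oracle", {
  # bump pattern translating at known velocity, <= 64 x 64
  set.seed(42)
  n_rows <- 60; n_frames <- 8; dt <- 5; v_true <- -0.08; px <- 0.1
  base <- 30 + 8 * sin((1:n_rows) / 3) + rnorm(n_rows, 0, 1)
  planes <- lapply(seq_len(n_frames), function(j) {
    shift <- v_true / px * (j - 1) * dt
    row <- approx(seq_len(n_rows), base, xout = seq_len(n_rows) - shift,
                  rule = 2)$y
    matrix(rep(row, 30), nrow = n_rows) + matrix(rnorm(n_rows * 30, 0, 0.5),
                                                 n_rows)
  })
  st <- raw_stack(lapply(planes, t), frame_interval_s = dt)
  ky <- build_kymograph(st, sampling_line(c(0, 15), c(n_rows - 1, 15)))
  res <- measure_retrograde_flow(ky, list(c(0, (n_frames - 1) * dt)))

  # oracle: exhaustive variance-of-sheared-mean scan, written independently
  grid <- seq(-0.3, 0.3, by = 0.0025)
  t_rel <- (seq_len(n_frames) - 1) * dt - mean((seq_len(n_frames) - 1) * dt)
  oracle_score <- function(v) {
    shifts <- v / px * t_rel
    xo <- seq(ceiling(1 - min(shifts)), floor(nrow(ky) - max(shifts)))
    if (length(xo) < 5) return(-Inf)
    m <- rowMeans(sapply(seq_len(n_frames), function(j)
      approx(seq_len(nrow(ky)), ky[, j], xout = xo + shifts[j], rule = 2)$y))
    var(m)
  }
  v_oracle <- grid[which.max(vapply(grid, oracle_score, numeric(1)))]
  expect_lte(abs(res$per_window_um_s[1] - v_oracle), 0.0025 + 1e-9)
  expect_lte(abs(res$retro_rate_um_s - abs(v_true)), 0.005)
})

test_that("period, persistence and flow recover a noiseless 90 s sawtooth", {
  p <- motility_params(period_s = 90, persistence_um = 1.5,
                       retro_rate_um_s = 0.08, n_cycles = 3L, noise_sd = 0,
                       seed = 2L)
  st <- generate_lamellipodium_stack(p, small_config())
  cm <- cycle_metrics(st)
  expect_lte(abs(cm$period_s - 90), 5)               # one frame interval
  expect_lte(abs(cm$persistence_um - 1.5), 0.1)      # one pixel
  expect_lte(abs(cm$retro_rate_um_s - 0.08), 0.005)
})

test_that("monotone and flat profiles fail with 'no cycles'", {
  mono <- data.frame(t_s = seq(0, 100, 5),
                     position_um = seq(1, 3, length.out = 21),
                     interpolated = FALSE)
  class(mono) <- c("edge_profile", "data.frame")
  expect_error(measure_period(mono), "no cycles")
  expect_error(measure_persistence(mono), "no cycles")
  flat <- mono; flat$position_um <- rep(2, 21)
  expect_error(measure_persistence(flat), "no cycles")
})

test_that("flow scales linearly and is zero for static streaks", {
  st1 <- generate_lamellipodium_stack(
    motility_params(retro_rate_um_s = 0.08, n_cycles = 2L, seed = 4L),
    small_config())
  st2 <- generate_lamellipodium_stack(
    motility_params(retro_rate_um_s = 0.16, n_cycles = 2L, seed = 4L),
    small_config())
  r1 <- cycle_metrics(st1)$retro_rate_um_s
  r2 <- cycle_metrics(st2)$retro_rate_um_s
  expect_equal(r2 / r1, 2, tolerance = 0.15)

  # vertical (static) structure scores best at zero slope
  img <- matrix(100, 40, 120)
  img[, seq(5, 115, by = 9)] <- 60
  st0 <- raw_stack(replicate(6, img, simplify = FALSE))
  ky0 <- build_kymograph(st0)
  res0 <- measure_retrograde_flow(ky0, list(c(0, 25)))
  expect_equal(res0$retro_rate_um_s, 0)
})

test_that("cycle metrics are invariant to intensity offset and gain", {
  p <- small_params(seed = 9L)
  st <- generate_lamellipodium_stack(p, small_config())
  st2 <- st
  st2$frames <- lapply(st$frames, function(fr) lapply(fr, function(m)
    3 * m + 40))
  cm1 <- cycle_metrics(st)
  cm2 <- cycle_metrics(st2)
  expect_equal(cm1$period_s, cm2$period_s)
  expect_equal(cm1$persistence_um, cm2$persistence_um)
  expect_equal(cm1$retro_rate_um_s, cm2$retro_rate_um_s)
})

test_that("time reversal preserves the period and flips streak slopes", {
  p <- small_params(seed = 6L)
  st <- generate_lamellipodium_stack(p, small_config())
  prof <- track_leading_edge(st)
  ky <- build_kymograph(st)
  wins <- retraction_windows(prof)
  rl <- streak_row_limits(prof, wins)
  fl <- measure_retrograde_flow(ky, wins, row_limits = rl)

  t_max <- max(prof$t_s)
  prof_rev <- prof
  prof_rev$position_um <- rev(prof$position_um)
  ky_rev <- ky
  ky_rev[] <- ky[, rev(seq_len(ncol(ky)))]
  wins_rev <- lapply(rev(wins), function(w) c(t_max - w[2], t_max - w[1]))
  fl_rev <- measure_retrograde_flow(ky_rev, wins_rev,
                                    row_limits = rev(rl))

  expect_equal(measure_period(prof_rev)$period_s,
               measure_period(prof)$period_s, tolerance = 0.05)
  ok <- !is.na(fl$per_window_um_s) & !is.na(rev(fl_rev$per_window_um_s))
  expect_equal(fl$per_window_um_s[ok],
               -rev(fl_rev$per_window_um_s)[ok], tolerance = 1e-9)
})
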