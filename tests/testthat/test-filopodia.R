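# Filopodium tip tracking and the length / growth-rate measurements.

track_from_generator <- function(g, j = 1) {
  seeds <- t(vapply(g$tracks, function(tr) c(tr$tip_x[1], tr$tip_y[1]),
                    numeric(2)))
  bases <- t(vapply(g$tracks, function(tr) attr(tr, "base_px"), numeric(2)))
  track_tips(g, seeds, bases)
}

test_that("the tracker recovers the elongation speed of a clean rod", {
  g <- generate_filopodium_tracks(n = 1, rate_um_s = 0.10, max_len_um = 4,
                                  frame_interval_s = 2, seed = 1,
                                  noise_sd = 0)
  tk <- track_from_generator(g)[[1]]
  expect_equal(nrow(tk), length(g$frames))
  rate <- protrusion_rate_filo(tk)$rate_um_s
  expect_lte(abs(rate - 0.10), 0.01)
  # per-frame tracked length tracks the truth within a pixel
  expect_lt(max(abs(tk$length_um - g$tracks[[1]]$length_um)), 0.1)
})

test_that("a static rod shows no tip displacement", {
  g <- generate_filopodium_tracks(n = 1, rate_um_s = 0, max_len_um = 3,
                                  start_len_um = 2.5, frame_interval_s = 2,
                                  seed = 2, noise_sd = 0, duration_s = 10)
  tk <- track_from_generator(g)[[1]]
  disp <- sqrt(diff(tk$tip_x)^2 + diff(tk$tip_y)^2)
  expect_lt(max(disp), 0.5)
  expect_error(protrusion_rate_filo(tk), "no growth")
})

test_that("two crossing rods keep distinct tracks", {
  # rods crossing mid-field at 4 um length; tips stay >= 10 px apart
  bases <- rbind(c(40, 80), c(40, 120))
  angles <- c(30, -30)
  g <- generate_filopodium_tracks(n = 2, rate_um_s = 0.10, max_len_um = 8,
                                  start_len_um = 5, frame_interval_s = 2,
                                  seed = 3, noise_sd = 0,
                                  image_shape = c(200L, 200L),
                                  bases = bases, angles_deg = angles)
  tks <- track_from_generator(g)
  for (j in 1:2) {
    err <- sqrt((tks[[j]]$tip_x - g$tracks[[j]]$tip_x[seq_len(nrow(tks[[j]]))])^2 +
                (tks[[j]]$tip_y - g$tracks[[j]]$tip_y[seq_len(nrow(tks[[j]]))])^2)
    expect_lt(stats::median(err), 2)
    expect_gte(nrow(tks[[j]]), length(g$frames) - 2)
  }
})

test_that("maximum length is the maximum over frames", {
  tr <- data.frame(t_s = c(0, 2, 4), tip_x = 0, tip_y = 0,
                   length_um = c(3.0, 3.36, 2.9))
  expect_equal(max_length(tr), 3.36)
  expect_equal(max_length(tr[2, ]), 3.36)   # single-frame track
  expect_error(max_length(tr[0, ]), "empty")
})

test_that("a long rod's maximum length is recovered within a pixel", {
  g <- generate_filopodium_tracks(n = 1, rate_um_s = 0.13, max_len_um = 8.04,
                                  frame_interval_s = 2, seed = 4,
                                  noise_sd = 0, image_shape = c(200L, 200L))
  tk <- track_from_generator(g)[[1]]
  expect_lte(abs(max_length(tk) - 8.04), 0.1)
})

test_that("growth-then-pause fits the slope on the growth phase only", {
  tr <- data.frame(t_s = seq(0, 38, 2),
                   tip_x = 0, tip_y = 0,
                   length_um = pmin(0.5 + 0.12 * seq(0, 38, 2), 2.42))
  out <- protrusion_rate_filo(tr)
  expect_equal(out$rate_um_s, 0.12, tolerance = 1e-9)
  expect_lte(out$window_s[2], 18)           # plateau (reached at t = 16) cut
  const <- tr; const$length_um <- rep(2, nrow(tr))
  expect_error(protrusion_rate_filo(const), "no growth")
})

test_that("tracking is invariant to the rod's orientation", {
  rates <- vapply(c(0, 37, 124, 211), function(a) {
    g <- generate_filopodium_tracks(n = 1, rate_um_s = 0.10, max_len_um = 4,
                                    frame_interval_s = 2, seed = 5,
                                    noise_sd = 0, angles_deg = a)
    protrusion_rate_filo(track_from_generator(g)[[1]])$rate_um_s
  }, numeric(1))
  expect_lt(max(abs(rates - 0.10)), 0.01)
})
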