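# The generators are first-class code: fixed seeds give bit-identical
# output, noiseless construction is analytically exact, and stored ground
# truth obeys its own invariants.

test_that("lamellipodium generator is deterministic under a fixed seed", {
  p <- motility_params(period_s = 90, retro_rate_um_s = 0.08, n_cycles = 1L,
                       seed = 7L)
  cfg <- small_config()
  a <- generate_lamellipodium_stack(p, cfg)
  b <- generate_lamellipodium_stack(p, cfg)
  expect_identical(a$frames, b$frames)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("noiseless, lift-free stacks are analytically exact", {
  p <- small_params(noise_sd = 0,
                    lift_profile = function(ph) rep(0, length(ph)))
  st <- generate_lamellipodium_stack(p, small_config())
  gt <- st$ground_truth

  # true edge equals the analytic sawtooth
  x0 <- gt$edge_um - sawtooth_edge(gt$t_s, p)
  expect_true(all(abs(x0 - x0[1]) < 1e-12))

  # ground-truth trajectory has the exact period and amplitude
  fine_t <- seq(0, p$period_s, by = 0.01)
  expect_equal(sawtooth_edge(fine_t, p), sawtooth_edge(fine_t + p$period_s, p))
  expect_equal(max(sawtooth_edge(fine_t, p)) - min(sawtooth_edge(fine_t, p)),
               p$persistence_um, tolerance = 1e-6)

  # with the edge in focus at height 0, non-zero planes hold only defocused
  # signal: their median is the background and they are smoother than the
  # in-focus plane
  i <- 3L
  p0 <- st$frames[[i]][[1]]
  p5 <- st$frames[[i]][[which(st$config$heights_um == 5)]]
  expect_equal(median(p5), st$config$background_level)
  roughness <- function(m) mean(abs(diff(t(m))))
  expect_lt(roughness(p5), roughness(p0))
})

test_that("generator rejects impossible geometries and timings", {
  expect_error(generate_lamellipodium_stack(
    motility_params(persistence_um = 10, retro_rate_um_s = 0.5),
    small_config()), "field of view")
  expect_error(imaging_config(heights_um = numeric()), "empty")
  expect_error(imaging_config(frame_interval_s = 0.5), "0.1-1 Hz")
  expect_error(motility_params(period_s = 10, persistence_um = 1.48,
                               retro_rate_um_s = 0.08), "exceeds the period")
  expect_error(motility_params(protrude_rate_um_s = 1), "inconsistent")
})

test_that("bead trace: quiet trap is exactly quiet", {
  cfg <- bead_sim_config(thermal_sd_nm = 0, event_schedule = list(),
                         duration_s = 5)
  tr <- generate_bead_trace(cfg)
  expect_true(all(tr$qpd_nm == 0))
  expect_true(all(tr$stage_nm == 0))
  expect_true(all(tr$ground_truth_force_pn == 0))
})

test_that("bead trace: feedback recenters on threshold crossings", {
  # 50 nm/s for 20 s = 1000 nm total against a 200 nm threshold
  cfg <- bead_sim_config(thermal_sd_nm = 0,
                         event_schedule = list(bead_event(1, "+x", 50, 20)),
                         duration_s = 25)
  tr <- generate_bead_trace(cfg)
  jumps <- which(rowSums(abs(diff(tr$stage_nm))) > 0) + 1L
  expect_gte(length(jumps), 4L)

  # recentering happens iff lateral r crossed the threshold at the previous
  # sample, and z is never recentered (the stage has no z axis)
  r <- sqrt(tr$qpd_nm[, 1]^2 + tr$qpd_nm[, 2]^2)
  n <- length(r)
  stage_moved <- rowSums(abs(diff(tr$stage_nm))) > 0
  expect_identical(unname(stage_moved),
                   unname(r[-n] > cfg$feedback_threshold_nm))
  expect_equal(ncol(tr$stage_nm), 2L)

  # lateral excursion never exceeds threshold + one sample of motion
  dt <- 1 / cfg$sample_rate_hz
  expect_lte(max(r), cfg$feedback_threshold_nm + 50 * dt + 1e-9)
})

test_that("bead ground-truth force is stiffness times true deflection", {
  cfg <- bead_sim_config(thermal_sd_nm = 5, seed = 3L,
                         event_schedule = list(bead_event(1, "+z", 25, 5),
                                               bead_event(10, "+x", 60, 4)),
                         duration_s = 20)
  tr <- generate_bead_trace(cfg)
  expect_identical(tr$ground_truth_force_pn[, 1],
                   cfg$stiffness_pn_nm[1] * tr$true_deflection_nm[, 1])
  expect_identical(tr$ground_truth_force_pn[, 3],
                   cfg$stiffness_pn_nm[2] * tr$true_deflection_nm[, 3])

  # +z to 125 nm at k_z = 0.08 -> 10 pN, z untouched by feedback
  cfgz <- bead_sim_config(thermal_sd_nm = 0,
                          event_schedule = list(bead_event(1, "+z", 25, 5)),
                          duration_s = 10)
  trz <- generate_bead_trace(cfgz)
  expect_equal(max(trz$ground_truth_force_pn[, 3]), 10)
})

test_that("bead simulator is deterministic and validates its schedule", {
  cfg <- bead_sim_config(seed = 11L,
                         event_schedule = list(bead_event(1, "+x", 40, 5)))
  expect_identical(generate_bead_trace(cfg)$qpd_nm,
                   generate_bead_trace(cfg)$qpd_nm)
  expect_error(bead_event(0, "+x", -5, 1), "non-negative")
  expect_error(bead_event(0, "+x", 5, -1), "non-negative")
  expect_error(bead_event(0, "up", 5, 1), "direction")
  expect_error(bead_sim_config(event_schedule = list(
    bead_event(0, "+x", 10, 5), bead_event(3, "+y", 10, 5))), "overlapping")
})

test_that("filopodium rods elongate linearly to the configured cap", {
  g <- generate_filopodium_tracks(n = 1, rate_um_s = 0.10, max_len_um = 5,
                                  frame_interval_s = 2, seed = 1,
                                  start_len_um = 0.5, duration_s = 30,
                                  noise_sd = 0)
  tr <- g$tracks[[1]]
  expect_equal(tr$length_um[tr$t_s == 30], 3.5)      # 0.5 + 0.10 * 30
  expect_equal(tr$length_um, pmin(0.5 + 0.10 * tr$t_s, 5))

  g0 <- generate_filopodium_tracks(n = 1, rate_um_s = 0, max_len_um = 2,
                                   start_len_um = 1.5, frame_interval_s = 2,
                                   seed = 1, noise_sd = 0)
  expect_true(all(g0$tracks[[1]]$length_um == 1.5))

  expect_identical(generate_filopodium_tracks(n = 2, seed = 5)$frames,
                   generate_filopodium_tracks(n = 2, seed = 5)$frames)
})
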