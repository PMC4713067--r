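# Force analysis: stiffness conversion, feedback compensation, event
# detection and classification, and the protrusion rate from averaged
# compensated traces.

test_that("deflection converts to force linearly with the trap stiffness", {
  expect_equal(displacement_to_force(c(100, 0, 0), c(0.10, 0.08)),
               matrix(c(10, 0, 0), 1, dimnames = list(NULL, c("Fx", "Fy", "Fz"))))
  expect_equal(unname(displacement_to_force(c(0, 0, 0))[1, ]), c(0, 0, 0))
  expect_equal(displacement_to_force(c(0, 0, 125), c(0.10, 0.08))[1, "Fz"],
               c(Fz = 10))
  d <- matrix(rnorm(30), 10, 3)
  expect_equal(displacement_to_force(2 * d), 2 * displacement_to_force(d))
  expect_error(displacement_to_force(c(1, 1, 1), c(0, 0.08)))
})

test_that("compensation is the identity when the stage never moves", {
  cfg <- bead_sim_config(thermal_sd_nm = 5, seed = 2L,
                         event_schedule = list(bead_event(1, "+x", 10, 5)),
                         duration_s = 10)        # stays under threshold
  tr <- generate_bead_trace(cfg)
  expect_true(all(tr$stage_nm == 0))
  comp <- compensate_feedback(tr)
  expect_identical(cbind(comp$x, comp$y), unname(tr$qpd_nm[, 1:2]))
  expect_length(attr(comp, "flags"), 0)
})

test_that("lateral displacement r follows sqrt(x^2 + y^2)", {
  cfg <- bead_sim_config(thermal_sd_nm = 0, duration_s = 2)
  tr <- generate_bead_trace(cfg)
  tr$qpd_nm[3, ] <- c(120, 160, 0)               # 3-4-5: r = 200, at threshold
  comp <- compensate_feedback(tr)
  expect_equal(comp$r_raw_nm[3], 200)
  expect_false(200 > cfg$feedback_threshold_nm)  # exactly at, not beyond
})

test_that("compensated push through several recenterings is a clean ramp", {
  cfg <- bead_sim_config(thermal_sd_nm = 0,
                         event_schedule = list(bead_event(1, "+x", 50, 20)),
                         duration_s = 25)
  tr <- generate_bead_trace(cfg)
  expect_gte(sum(rowSums(abs(diff(tr$stage_nm))) > 0), 4)
  comp <- compensate_feedback(tr)
  ramp <- comp$t_s >= 1 & comp$t_s <= 21
  fit <- stats::lsfit(comp$t_s[ramp], comp$x[ramp])
  expect_lte(abs(fit$coefficients[2] - 50), 2)
  expect_lt(max(abs(fit$residuals)), 5)
})

test_that("the four stereotyped behaviours classify 4/4", {
  cfg <- bead_sim_config(thermal_sd_nm = 2, seed = 1L,
                         event_schedule = four_behaviour_schedule(),
                         duration_s = 140)
  ev <- force_events(generate_bead_trace(cfg), away_xy = c(1, 0))
  expect_equal(nrow(ev), 4L)
  expect_equal(ev$behaviour, c("VP", "VR", "LP", "LR"))
  expect_equal(ev$max_force_pn, c(10, 10, 14, 14), tolerance = 0.1)
})

test_that("classification depends on direction, not magnitude", {
  t_s <- seq(0, 10, 0.1)
  mk <- function(fx, fy, fz) {
    out <- data.frame(t_s = t_s, Fx = fx, Fy = fy, Fz = fz,
                      comp_x_nm = 0, comp_y_nm = 0)
    class(out) <- c("force_trace", "data.frame")
    out
  }
  ramp <- seq(0, 10, length.out = length(t_s))
  expect_equal(classify_event(mk(0, 0, ramp), c(1, 0)), "VP")
  expect_equal(classify_event(mk(-0.8 * ramp, 0, 0), c(1, 0)), "LR")
  # scaling all forces leaves the label unchanged
  for (s in c(0.5, 3, 10))
    expect_equal(classify_event(mk(-0.8 * s * ramp, 0, 0), c(1, 0)), "LR")
  # sub-floor window holds no event
  expect_equal(classify_event(mk(0, 0, 0.05 * ramp), c(1, 0)), "no event")
  expect_equal(max_event_force(mk(0, 0, 0 * ramp), c(1, 0)), 0)
})

test_that("two events yield two per-event maxima, not one", {
  cfg <- bead_sim_config(thermal_sd_nm = 0,
                         event_schedule = list(bead_event(2, "+x", 25, 2),
                                               bead_event(10, "-x", 25, 2),
                                               bead_event(20, "+x", 40, 2),
                                               bead_event(28, "-x", 40, 2)),
                         duration_s = 35)
  ev <- force_events(generate_bead_trace(cfg))
  expect_equal(nrow(ev), 2L)
  expect_equal(sort(ev$max_force_pn), c(5, 8), tolerance = 1e-6)
})

test_that("identical noiseless ramps average to exactly the ramp rate", {
  mk <- function() {
    cfg <- bead_sim_config(thermal_sd_nm = 0,
                           event_schedule = list(bead_event(2, "+x", 80, 10)),
                           duration_s = 16)
    compensate_feedback(generate_bead_trace(cfg))
  }
  pr <- protrusion_rate(list(mk(), mk()))
  expect_equal(pr$rate_nm_s, 80, tolerance = 1e-6)
  expect_equal(pr$n_traces, 2L)
})

test_that("protrusion rate recovers 100 nm/s from noisy shifted traces", {
  paths <- lapply(1:5, function(s) {
    cfg <- bead_sim_config(thermal_sd_nm = 10, seed = s,
                           event_schedule = list(
                             bead_event(2 + 0.4 * s, "+x", 100, 8)),
                           duration_s = 18)
    compensate_feedback(generate_bead_trace(cfg))
  })
  pr <- protrusion_rate(paths)
  expect_lte(abs(pr$rate_nm_s - 100), 5)

  # mixed slow traces average in between (30 and 50 nm/s)
  slow <- lapply(c(30, 50), function(v) {
    cfg <- bead_sim_config(thermal_sd_nm = 0,
                           event_schedule = list(bead_event(2, "+x", v, 10)),
                           duration_s = 16)
    compensate_feedback(generate_bead_trace(cfg))
  })
  pr2 <- protrusion_rate(slow)
  expect_gt(pr2$rate_nm_s, 30)
  expect_lt(pr2$rate_nm_s, 50)
})

test_that("flat traces are excluded; all-flat input fails", {
  flat_cfg <- bead_sim_config(thermal_sd_nm = 1, seed = 9L, duration_s = 15)
  flat <- compensate_feedback(generate_bead_trace(flat_cfg))
  rise_cfg <- bead_sim_config(thermal_sd_nm = 1, seed = 10L,
                              event_schedule = list(bead_event(2, "+x", 60, 8)),
                              duration_s = 15)
  rise <- compensate_feedback(generate_bead_trace(rise_cfg))
  pr <- protrusion_rate(list(rise, flat, rise))
  expect_equal(pr$excluded, 2L)
  expect_error(protrusion_rate(list(flat, flat)), "rising phase")
})

test_that("scheduled speeds round-trip through the full force pipeline", {
  for (v in c(40, 80)) {
    cfg <- bead_sim_config(thermal_sd_nm = 15, seed = as.integer(v),
                           event_schedule = list(bead_event(2, "+x", v, 12)),
                           duration_s = 20)
    paths <- lapply(1:3, function(s) {
      cfg$seed <- cfg$seed + s
      compensate_feedback(generate_bead_trace(cfg))
    })
    pr <- protrusion_rate(paths)
    expect_lte(abs(pr$rate_nm_s - v) / v, 0.05)
  }
})
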