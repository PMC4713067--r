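#!/usr/bin/env Rscript
# Optical-trap force analysis: per condition, bead traces are scheduled so
# that the peak deflection realizes the reported mean maximum force for each
# stereotyped behaviour (LP, VP, LR, VR); the event pipeline must detect,
# classify and measure them. Then the lamellipodial protrusion rate is
# estimated from averaged feedback-compensated traces per condition.

source(file.path("analysis", "00_conditions.R"))

# deflection (nm) realizing a force: F / k along the relevant axis
schedule_for <- function(beh, force_pn) {
  k <- if (beh %in% c("LP", "LR")) trap_stiffness[1] else trap_stiffness[2]
  defl <- force_pn / k
  dir <- switch(beh, LP = "+x", LR = "-x", VP = "+z", VR = "-z")
  rel <- switch(beh, LP = "-x", LR = "+x", VP = "-z", VR = "+z")
  # drive out over 5 s, hold, release so events separate
  list(bead_event(5, dir, defl / 5, 5), bead_event(20, rel, defl / 5, 5))
}

rows <- list()
for (i in seq_len(nrow(force_conditions))) {
  fc <- force_conditions[i, ]
  tr <- generate_bead_trace(bead_sim_config(
    stiffness_pn_nm = trap_stiffness, thermal_sd_nm = 4, seed = 300L + i,
    event_schedule = schedule_for(fc$behaviour, fc$force_pn),
    duration_s = 35))
  ev <- force_events(tr, away_xy = c(1, 0))
  main <- ev[which.max(ev$max_force_pn), ]   # the scheduled (strongest) event
  rows[[i]] <- data.frame(condition = fc$condition,
                          behaviour_true = fc$behaviour,
                          behaviour_detected = main$behaviour,
                          force_true_pn = fc$force_pn,
                          force_measured_pn = main$max_force_pn)
}
events <- do.call(rbind, rows)
write.csv(events, file.path(results_dir, "force_events.csv"),
          row.names = FALSE)
ok <- sum(events$behaviour_true == events$behaviour_detected)
message(sprintf("classification: %d/%d behaviours correct; mean force error %+.2f pN",
                ok, nrow(events),
                mean(events$force_measured_pn - events$force_true_pn)))
message("  (peaks of noisy traces read high by ~2.5 x the thermal force sd;",
        " the same holds for any measured maximum)")

message("protrusion rate from 5 averaged compensated traces per condition")
rate_rows <- lapply(seq_len(nrow(protrusion_conditions)), function(i) {
  pc <- protrusion_conditions[i, ]
  paths <- lapply(1:5, function(k)
    compensate_feedback(generate_bead_trace(bead_sim_config(
      thermal_sd_nm = 10, seed = 400L + 10L * i + k,
      event_schedule = list(bead_event(2 + 0.3 * k, "+x", pc$rate_nm_s, 8)),
      duration_s = 18))))
  est <- protrusion_rate(paths)$rate_nm_s
  message(sprintf("  %-8s %.1f nm/s (true %.0f)", pc$condition, est,
                  pc$rate_nm_s))
  data.frame(condition = pc$condition, rate_true_nm_s = pc$rate_nm_s,
             rate_measured_nm_s = est, n_traces = 5L)
})
write.csv(do.call(rbind, rate_rows),
          file.path(results_dir, "protrusion_rates.csv"), row.names = FALSE)
message("wrote ", file.path(results_dir, "force_events.csv"), " and ",
        file.path(results_dir, "protrusion_rates.csv"))
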