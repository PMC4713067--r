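#!/usr/bin/env Rscript
# Vertical (axial) motion of the lamellipodium: the fractional number of
# in-focus pixels per height over time, in a control-like condition (edge
# lifts to ~5 um around maximal retraction) versus a transiently retracted,
# lift-suppressed condition.

source(file.path("analysis", "00_conditions.R"))

run_height <- function(label, lift) {
  st <- generate_lamellipodium_stack(
    motility_params(seed = 7L, lift_profile = lift, n_cycles = 3L))
  fhs <- fractional_height_series(st)
  hs <- attr(fhs, "heights_um"); t_s <- attr(fhs, "t_s")
  long <- data.frame(condition = label,
                     t_s = rep(t_s, each = length(hs)),
                     height_um = rep(hs, length(t_s)),
                     fraction = as.vector(fhs),
                     flagged = rep(attr(fhs, "flagged"), each = length(hs)))
  mh <- max_height_trace(fhs)
  list(long = long,
       frac5 = fhs[hs == 5, ],
       reached = data.frame(condition = label, t_s = t_s,
                            reached_um = mh$per_frame_um))
}

message("control-like lift (bump to 5 um near maximal retraction)")
ctl <- run_height("control", lift_profile_bump())
message("lift-suppressed (flat, the transient-retraction phenotype)")
flat <- run_height("no_lift", function(ph) rep(0, length(ph)))

write.csv(rbind(ctl$long, flat$long),
          file.path(results_dir, "fractional_height_long.csv"),
          row.names = FALSE)
write.csv(rbind(ctl$reached, flat$reached),
          file.path(results_dir, "reached_height.csv"), row.names = FALSE)

message(sprintf("  in-focus fraction at 5 um: control peak %.2f vs flat max %.2f",
                max(ctl$frac5), max(flat$frac5)))
message(sprintf("  reached height: control max %.0f um, flat max %.0f um",
                max(ctl$reached$reached_um, na.rm = TRUE),
                max(flat$reached$reached_um, na.rm = TRUE)))

png(file.path(results_dir, "fractional_height.png"), 900, 400)
par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
for (d in list(ctl, flat)) {
  plot(d$reached$t_s, d$frac5, type = "l", xlab = "time (s)",
       ylab = "fraction in focus at 5 um", ylim = c(0, 0.7),
       main = d$reached$condition[1])
}
dev.off()
message("wrote ", file.path(results_dir, "fractional_height.png"))
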