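# Shared condition registry for the analysis scripts: the reported
# per-condition means that the synthetic recordings are generated at.
# Sourced by the numbered drivers; not a script itself.

library(gcmotility)

results_dir <- file.path("results")
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)

# Lamellipodial cycle parameters per condition (period s, persistence um,
# retrograde flow um/s): control, Rac1 inhibition (EHop-016 20 uM) and
# partial Arp2/3 inhibition (CK-548 50 uM, after recovery).
cycle_conditions <- data.frame(
  condition = c("control", "EH20", "CK50"),
  period_s = c(86.5, 129.6, 115.1),
  persistence_um = c(1.48, 1.56, 1.90),
  retro_um_s = c(0.08, 0.05, 0.09)
)

# Average maximum force (pN) per stereotyped behaviour and condition.
force_conditions <- data.frame(
  condition = rep(c("control", "EH10", "EH20", "CK25", "CK50"), each = 4),
  behaviour = rep(c("LP", "VP", "LR", "VR"), 5),
  force_pn = c(14.0, 10.4, 15.5, 10.1,
               9.9, 4.0, 8.7, 3.4,
               8.5, 2.3, 4.1, 2.0,
               6.9, 2.3, 6.0, 2.1,
               5.0, 2.2, 5.2, 1.9)
)

# Lateral protrusion rate of lamellipodia against a trapped bead (nm/s):
# up to 100 in control, 30-50 under 10 uM EH, 10-20 under 20 uM EH.
protrusion_conditions <- data.frame(
  condition = c("control", "EH10", "EH20"),
  rate_nm_s = c(100, 40, 15)
)

# Filopodia: maximum length (um) and growth rate (um/s) per condition.
filo_conditions <- data.frame(
  condition = c("control", "CK25", "CK50", "EH10", "EH20"),
  max_len_um = c(3.36, 5.67, 6.33, 4.14, 8.04),
  rate_um_s = c(0.10, 0.09, 0.07, 0.09, 0.13)
)

trap_stiffness <- c(0.10, 0.08)   # k_xy, k_z in pN/nm
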