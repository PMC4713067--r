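#!/usr/bin/env Rscript
# Filopodia motility: per condition, rods elongate at the reported growth
# rate to the reported maximum length; the tip tracker measures both back
# from the rendered movies (3 seeds per condition).

source(file.path("analysis", "00_conditions.R"))

rows <- list()
for (i in seq_len(nrow(filo_conditions))) {
  fc <- filo_conditions[i, ]
  for (s in 1:3) {
    g <- generate_filopodium_tracks(
      n = 1, rate_um_s = fc$rate_um_s, max_len_um = fc$max_len_um,
      frame_interval_s = 2, seed = 500L + 10L * i + s,
      image_shape = c(200L, 200L))
    tk <- track_tips(g,
                     cbind(g$tracks[[1]]$tip_x[1], g$tracks[[1]]$tip_y[1]),
                     matrix(attr(g$tracks[[1]], "base_px"), ncol = 2))[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      condition = fc$condition, seed = s,
      max_len_true_um = fc$max_len_um, max_len_um = max_length(tk),
      rate_true_um_s = fc$rate_um_s,
      rate_um_s = protrusion_rate_filo(tk)$rate_um_s)
  }
}
tracks <- do.call(rbind, rows)
write.csv(tracks, file.path(results_dir, "filopodia_per_rod.csv"),
          row.names = FALSE)

summary <- do.call(rbind, lapply(unique(tracks$condition), function(cond) {
  sel <- tracks$condition == cond
  data.frame(condition = cond,
             max_len_um = mean(tracks$max_len_um[sel]),
             max_len_true_um = tracks$max_len_true_um[sel][1],
             rate_um_s = mean(tracks$rate_um_s[sel]),
             rate_true_um_s = tracks$rate_true_um_s[sel][1])
}))
write.csv(summary, file.path(results_dir, "filopodia_summary.csv"),
          row.names = FALSE)
for (i in seq_len(nrow(summary)))
  message(sprintf("  %-8s length %.2f um (true %.2f), rate %.3f um/s (true %.2f)",
                  summary$condition[i], summary$max_len_um[i],
                  summary$max_len_true_um[i], summary$rate_um_s[i],
                  summary$rate_true_um_s[i]))
message("wrote ", file.path(results_dir, "filopodia_summary.csv"))
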