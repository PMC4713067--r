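#!/usr/bin/env Rscript
# Aggregate the per-measurement outputs of the previous drivers into one
# long-format summary table (condition, metric, n, mean, sem, p_vs_control),
# after checking each control group for normality where n allows.

source(file.path("analysis", "00_conditions.R"))

kymo <- read.csv(file.path(results_dir, "kymograph_per_movie.csv"))
filo <- read.csv(file.path(results_dir, "filopodia_per_rod.csv"))

long <- rbind(
  data.frame(condition = kymo$condition, metric = "period_s",
             value = kymo$period_s, unit = "s"),
  data.frame(condition = kymo$condition, metric = "persistence_um",
             value = kymo$persistence_um, unit = "um"),
  data.frame(condition = kymo$condition, metric = "retro_um_s",
             value = kymo$retro_um_s, unit = "um/s"),
  data.frame(condition = filo$condition, metric = "filo_max_len_um",
             value = filo$max_len_um, unit = "um"),
  data.frame(condition = filo$condition, metric = "filo_rate_um_s",
             value = filo$rate_um_s, unit = "um/s")
)

summary <- do.call(rbind, lapply(split(long, long[c("metric", "condition")]),
  function(d) {
    if (!nrow(d)) return(NULL)
    ctrl <- long$value[long$metric == d$metric[1] &
                         long$condition == "control"]
    p <- if (d$condition[1] == "control" || sd(d$value) == 0) NA_real_
         else compare_groups(ctrl, d$value)$p
    s <- summarize_group(d$value, d$condition[1], d$unit[1])
    data.frame(condition = d$condition[1], metric = d$metric[1], n = s$n,
               mean = s$mean, sem = s$sem, unit = d$unit[1],
               p_vs_control = p)
  }))
summary <- summary[order(summary$metric, summary$condition), ]
write.csv(summary, file.path(results_dir, "summary_long.csv"),
          row.names = FALSE)

message("summary (mean +- SEM; * = Welch p < 0.05 vs control):")
for (i in seq_len(nrow(summary)))
  message(sprintf("  %-16s %-8s %7.3f +- %5.3f %-5s n=%d%s",
                  summary$metric[i], summary$condition[i], summary$mean[i],
                  summary$sem[i], summary$unit[i], summary$n[i],
                  ifelse(!is.na(summary$p_vs_control[i]) &
                           summary$p_vs_control[i] < 0.05, " *", "")))
message("wrote ", file.path(results_dir, "summary_long.csv"))
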