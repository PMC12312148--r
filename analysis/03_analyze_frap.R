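#!/usr/bin/env Rscript
# Estimate half times, diffusion coefficients and recovery fractions for
# the simulated FRAP traces and compare the inside-domain and
# outside-domain populations. Writes results/frap_results.csv and
# results/frap_summary.csv.

suppressPackageStartupMessages(library(memphase))
data_dir <- "scratch/data"
stopifnot(dir.exists(data_dir))  # run 01_simulate_data.R first

files <- sort(list.files(data_dir, pattern = "^frap_.*\\.csv$"))
files <- setdiff(files, "frap_truth.csv")
rows <- NULL
results <- list()
for (f in files) {
  tr <- read_frap_trace(file.path(data_dir, f))
  ex <- attr(tr, "extras")
  res <- frap_analyze(tr)
  rows <- rbind(rows, data.frame(
    file = f, vesicle_id = ex$vesicle_id[1], label = ex$label[1],
    t_half = res$t_half, D = res$D, recovery_R = res$recovery_R))
  results[[f]] <- res
}
write.csv(rows, "results/frap_results.csv", row.names = FALSE)

inside <- rows$label == "inside"
cmp <- compare_frap_groups(
  lapply(results[rows$file[inside]], identity),
  lapply(results[rows$file[!inside]], identity),
  inside_vesicle = rows$vesicle_id[inside],
  outside_vesicle = rows$vesicle_id[!inside])
summary_df <- data.frame(
  mean_D_inside = cmp$mean_inside, sd_D_inside = cmp$sd_inside,
  n_inside = cmp$n_inside, mean_D_outside = cmp$mean_outside,
  sd_D_outside = cmp$sd_outside, n_outside = cmp$n_outside,
  ratio_outside_inside = cmp$ratio_outside_inside,
  n_paired = cmp$n_paired, n_slower_inside = cmp$n_slower_inside)
write.csv(summary_df, "results/frap_summary.csv", row.names = FALSE)

cat(sprintf("inside domains:  D = %.2f um^2/s (s.d. %.2f, n = %d)\n",
            cmp$mean_inside, cmp$sd_inside, cmp$n_inside))
cat(sprintf("outside domains: D = %.2f um^2/s (s.d. %.2f, n = %d)\n",
            cmp$mean_outside, cmp$sd_outside, cmp$n_outside))
cat(sprintf("ratio outside/inside = %.1f; slower inside in %d of %d vesicles\n",
            cmp$ratio_outside_inside, cmp$n_slower_inside, cmp$n_paired))
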