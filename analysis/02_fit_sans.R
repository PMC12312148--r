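#!/usr/bin/env Rscript
# Fit the composite model (BCC paracrystal + vesicles + lamellar stacks +
# background) to the simulated SANS curves and index the BCC reflections.
# Writes results/sans_fits.csv and results/bragg_peaks.csv.

suppressPackageStartupMessages(library(memphase))
data_dir <- "scratch/data"
stopifnot(dir.exists(data_dir))  # run 01_simulate_data.R first

truth <- sans_study_params()
vt <- composite_to_vector(truth)
start <- truth
start$bcc$scale <- 2 * truth$bcc$scale
start$vesicle$scale <- 0.5 * truth$vesicle$scale
start$lamellar$scale <- 2 * truth$lamellar$scale
start$background <- 4 * truth$background
free <- c("bcc.scale", "ves.scale", "lam.scale", "background")
frozen <- setdiff(names(vt), free)

rows <- NULL
for (f in sort(list.files(data_dir, pattern = "^sans_\\d+\\.dat$"))) {
  curve <- read_scattering_curve(file.path(data_dir, f))
  fit <- fit_composite(curve, start = start, frozen = frozen)
  v <- composite_to_vector(fit$params)
  rows <- rbind(rows, data.frame(
    file = f, converged = fit$converged, chi2_red = fit$chi2_reduced,
    scale_bcc = v[["bcc.scale"]], scale_ves = v[["ves.scale"]],
    scale_lam = v[["lam.scale"]], background = v[["background"]],
    err_bcc = abs(v[["bcc.scale"]] - vt[["bcc.scale"]]) / vt[["bcc.scale"]],
    err_ves = abs(v[["ves.scale"]] - vt[["ves.scale"]]) / vt[["ves.scale"]],
    err_lam = abs(v[["lam.scale"]] - vt[["lam.scale"]]) / vt[["lam.scale"]]))
}
write.csv(rows, "results/sans_fits.csv", row.names = FALSE)
cat("composite fits (free scale factors + background):\n")
print(rows[c("file", "chi2_red", "err_bcc", "err_ves", "err_lam")],
      digits = 3)
cat("all scale factors recovered within",
    sprintf("%.1f%%\n", 100 * max(rows[c("err_bcc", "err_ves", "err_lam")])))

# Peak indexing at the fitted lattice constant (46 nm): the first two
# allowed BCC reflections fall at the positions quoted for the measured
# curves (0.02 and 0.027 A^-1), and the lamellar interference maximum for
# the 25 nm bilayer spacing at 0.025 A^-1.
peaks <- bragg_peaks(lattice_a = 460, q_max = 0.221)
write.csv(peaks, "results/bragg_peaks.csv", row.names = FALSE)
cat(sprintf("BCC reflections at a = 460 A: (110) %.4f, (200) %.4f A^-1\n",
            peaks$q[1], peaks$q[2]))
q <- seq(0.018, 0.035, by = 1e-5)
z <- stack_interference(q, truth$lamellar$n_layers,
                        truth$lamellar$spacing_d, truth$lamellar$sigma_d)
cat(sprintf("lamellar interference maximum (D = 250 A): %.4f A^-1\n",
            q[which.max(z)]))
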