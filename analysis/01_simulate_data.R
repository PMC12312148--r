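#!/usr/bin/env Rscript
# Simulate one dataset per modality under the study conditions and write
# them, with ground-truth sidecars, under scratch/data/ (regenerable raw
# data, kept out of the results tables). Later scripts in this directory
# read these files back through the package readers, so the whole chain
# exercises the same formats a measured dataset would use.

suppressPackageStartupMessages(library(memphase))
out <- "scratch/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## SANS: three replicate curves at 5% counting noise over the measured
## window 0.002-0.221 A^-1, from the composite truth parameters.
truth <- sans_study_params()
for (s in 1:3) {
  gen <- gen_sans_curve(truth, relative_noise = 0.05, n_points = 150,
                        seed = s)
  write_scattering_curve(gen$curve, file.path(out, sprintf("sans_%02d.dat", s)))
}
write.csv(data.frame(name = names(composite_to_vector(truth)),
                     value = unname(composite_to_vector(truth))),
          file.path(out, "sans_truth.csv"), row.names = FALSE)
cat("wrote 3 SANS curves (150 points, 5% relative noise)\n")

## FRAP: paired inside/outside-domain traces for 20 vesicles. True D drawn
## around the study means (1.8 inside, 3.4 outside, lognormal vesicle-to-
## vesicle spread), ROI radius 0.9 um, 40 ms sampling.
set.seed(101)
n_ves <- 20
d_in <- 1.8 * exp(rnorm(n_ves, 0, 0.25))
d_out <- 3.4 * exp(rnorm(n_ves, 0, 0.25))
meta <- NULL
for (v in seq_len(n_ves)) {
  for (side in c("inside", "outside")) {
    d_true <- if (side == "inside") d_in[v] else d_out[v]
    gen <- gen_frap_trace(D_true = d_true, roi_radius = 0.9, dt = 0.04,
                          duration = 8, noise_sigma = 0.01,
                          seed = 1000 + 2 * v + (side == "inside"))
    f <- sprintf("frap_v%02d_%s.csv", v, side)
    write_frap_trace(gen$trace, file.path(out, f),
                     extras = data.frame(label = side,
                                         vesicle_id = sprintf("v%02d", v)))
    meta <- rbind(meta, data.frame(file = f, vesicle_id = sprintf("v%02d", v),
                                   label = side, D_true = d_true))
  }
}
write.csv(meta, file.path(out, "frap_truth.csv"), row.names = FALSE)
cat("wrote", 2 * n_ves, "FRAP traces (paired inside/outside)\n")

## GUV micrographs: five vesicles with one bright domain each (2.5-fold,
## 30 degrees wide), SNR 5, 64 nm pixels.
guv_truth <- NULL
for (s in 1:5) {
  ctr <- c(118.5 + 4 * s, 138.5 - 3 * s)
  dom <- list(center_deg = 72 * s - 36, width_deg = 30, fold = 2.5)
  gen <- gen_guv_image(shape = c(256, 256), center = ctr, radius = 40,
                       membrane_amplitude = 100, background = 10,
                       domains = list(dom), noise_sigma = 20,
                       seed = 200 + s)
  f <- sprintf("guv_%02d.tif", s)
  img <- gen$image
  img$pixels <- round(img$pixels)  # 16-bit storage
  write_image(img, file.path(out, f))
  guv_truth <- rbind(guv_truth,
                     data.frame(file = f, cx = ctr[1], cy = ctr[2],
                                radius = 40, domain_center = dom$center_deg,
                                domain_width = 30, domain_fold = 2.5))
}
write.csv(guv_truth, file.path(out, "guv_truth.csv"), row.names = FALSE)
cat("wrote 5 GUV micrographs (one 2.5-fold domain each, SNR 5)\n")

## 31P spectra: temperature-series-like set of lamellar/isotropic
## mixtures plus one hexagonal-bearing control, 1% noise.
mixes <- list(low_T = c(0.9, 0, 0.1), mid_T = c(0.5, 0, 0.5),
              high_T = c(0.3, 0, 0.7), pe_control = c(0.1, 0.9, 0))
nmr_truth <- NULL
for (nm in names(mixes)) {
  gen <- gen_nmr_spectrum(weights = mixes[[nm]], relative_noise = 0.01,
                          seed = 300 + match(nm, names(mixes)))
  write_spectrum(gen$spectrum, file.path(out, sprintf("nmr_%s.csv", nm)))
  nmr_truth <- rbind(nmr_truth,
                     data.frame(file = sprintf("nmr_%s.csv", nm),
                                lamellar = mixes[[nm]][1],
                                hexagonal = mixes[[nm]][2],
                                isotropic = mixes[[nm]][3]))
}
write.csv(nmr_truth, file.path(out, "nmr_truth.csv"), row.names = FALSE)
cat("wrote", length(mixes), "31P spectra\n")
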