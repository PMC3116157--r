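#!/usr/bin/env Rscript
# Step 1: simulate the GdnHCl unfolding experiment for the HCAII Pro237
# mutant panel. Writes one transition-curve CSV per variant (noisy, the
# "measured" data) plus the noiseless model curves, and a denaturant series
# of raw emission spectra for the reference variant.
library(unfoldfit)

seed <- 1L
panel <- hcaii_p237_panel(seed = seed)
dir.create("results/curves", recursive = TRUE, showWarnings = FALSE)
dir.create("results/curves_noiseless", recursive = TRUE, showWarnings = FALSE)
dir.create("results/spectra", recursive = TRUE, showWarnings = FALSE)

noisy <- generate_panel_curves(panel)
clean <- generate_panel_curves(panel, noise_sd = 0)
for (v in names(noisy)) {
  write_curve_csv(noisy[[v]], file.path("results/curves",
                                        paste0(v, ".csv")))
  write_curve_csv(clean[[v]], file.path("results/curves_noiseless",
                                        paste0(v, ".csv")))
}
cat(sprintf("Simulated %d variants x %d concentrations (0-%g M GdnHCl), noise %.2g nm\n",
            length(noisy), length(panel$conc_grid),
            max(panel$conc_grid), panel$noise_sd))

spectra <- generate_spectra(panel$variants$HCAII_pwt,
                            conc_grid = panel$conc_grid,
                            seed = seed, sample_id = "HCAII_pwt")
for (i in seq_along(spectra)) {
  write_spectrum_csv(spectra[[i]],
                     sprintf("results/spectra/HCAII_pwt_%02d.csv", i))
}
cat(sprintf("Wrote %d raw emission spectra (300-450 nm) for HCAII_pwt\n",
            length(spectra)))
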