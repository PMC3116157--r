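#!/usr/bin/env Rscript
# Step 3: assemble the per-variant stability table (dG_NI, dG_IU, dG_NU,
# ddG_NU, m-values) relative to HCAII_pwt, append the literature record for
# P237H (total ddG only), and apply the >2 kcal/mol destabilization
# criterion.
library(unfoldfit)

if (!file.exists("scratch/fits.rds")) {
  stop("run analysis/02_fit_curves.R first")
}
fits <- readRDS("scratch/fits.rds")
panel <- hcaii_p237_panel()

tab <- build_stability_table(fits, reference = panel$reference,
                             literature = panel$literature_ddg)
print(tab)
write_stability_tsv(tab, "results/stability_table.tsv")
write_stability_json(tab, "results/stability_table.json")

flagged <- classify_destabilizing(tab, threshold = 2.0)
cat(sprintf("\nVariants destabilized by more than 2 kcal/mol: %s\n",
            paste(flagged, collapse = ", ")))
cat(sprintf("Most deleterious mutation: %s\n", flagged[1]))
cat("Wrote results/stability_table.{tsv,json}\n")
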