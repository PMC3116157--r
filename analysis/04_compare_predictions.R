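#!/usr/bin/env Rscript
# Step 4: compare the experimentally derived ddG_NU values against a
# structure-based predictor's ddG table and quantify the discrepancy
# (correlation, RMSE, worst-predicted variant).
library(unfoldfit)

if (!file.exists("scratch/fits.rds")) {
  stop("run analysis/02_fit_curves.R first")
}
fits <- readRDS("scratch/fits.rds")
panel <- hcaii_p237_panel()
tab <- build_stability_table(fits, reference = panel$reference,
                             literature = panel$literature_ddg)

pred <- read_prediction_table(system.file("extdata",
                                          "foldx_ddg_synthetic.tsv",
                                          package = "unfoldfit"))
cmp <- suppressWarnings(compare_predictions(tab, pred))
print(cmp)

jsonlite::write_json(
  list(pairs = cmp$pairs, pearson_r = cmp$pearson_r, rmse = cmp$rmse,
       max_abs_deviation = cmp$max_abs_deviation,
       max_deviation_variant = cmp$max_deviation_variant, n = cmp$n),
  "results/prediction_comparison.json", auto_unbox = TRUE, digits = NA)
cat("\nWrote results/prediction_comparison.json\n")
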