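#!/usr/bin/env Rscript
# Step 4 — full cohort evaluation.
#
# Group summaries (median/IQR + Mann-Whitney per variable, per sex), the
# per-measurement ROC/AUC/cut-point report, and the confusion-matrix
# performance of the top variable per sex. Reports land in
# results/evaluation/.

suppressPackageStartupMessages(library(l3bodycomp))

ev <- run_evaluate("results/cohort/cohort.csv", out_dir = "results/evaluation")

cat("Variables with AUC exceeding BSA, per sex:\n")
print(as.data.frame(
  ev$roc_report[ev$roc_report$exceeds_bsa %in% TRUE,
                c("sex", "variable", "auc", "ci_low", "ci_high")]),
  digits = 3)

cat("\nTop variable per sex at its optimal cut-point:\n")
print(as.data.frame(
  ev$top[, c("sex", "variable", "auc", "cutpoint", "accuracy",
             "sensitivity", "specificity")]),
  digits = 3)

sig <- ev$summary[ev$summary$p_value < 0.05, c("sex", "variable", "p_value")]
cat("\nVariables differing significantly between DLT and no-DLT groups:\n")
print(as.data.frame(sig), digits = 3)
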