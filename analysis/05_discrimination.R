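#!/usr/bin/env Rscript

# Step 5 — discrimination: do the two indices predict differently?
#
# For each endpoint, the risk score is the linear predictor of the fully
# adjusted Cox model (model-3 covariates plus baseline blood pressure)
# including either PDI or hPDI; AUCs are compared with the paired DeLong
# test. Static labels: event vs no event over the whole follow-up.

suppressPackageStartupMessages(library(pdicohort))

ds <- read_dataset("results/dataset")
out <- list()
for (oc in OUTCOMES) {
  s <- build_analysis_sample(ds, oc)
  pdi <- model_score_for_roc(s, "pdi")
  hpdi <- model_score_for_roc(s, "hpdi")
  a <- compute_auc(pdi$scores, pdi$labels)
  b <- compute_auc(hpdi$scores, hpdi$labels)
  cmp <- compare_auc(pdi$scores, hpdi$scores, pdi$labels)
  out[[oc]] <- list(
    auc_pdi = a[c("auc", "lower", "upper")],
    auc_hpdi = b[c("auc", "lower", "upper")],
    delta = cmp$delta, p = cmp$p,
    n_pos = a$n_pos, n_neg = a$n_neg)
  cat(sprintf(
    "%-18s: AUC PDI %.3f (%.3f-%.3f) vs hPDI %.3f (%.3f-%.3f), p = %.3f\n",
    oc, a$auc, a$lower, a$upper, b$auc, b$lower, b$upper, cmp$p))
}
jsonlite::write_json(out, "results/roc_comparison.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = 6)
cat("wrote results/roc_comparison.json\n")
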