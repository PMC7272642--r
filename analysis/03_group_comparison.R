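#!/usr/bin/env Rscript
# Two-tailed Welch comparisons of every (value type, band, region) cell
# between the AD and NC groups at the Bonferroni-corrected threshold
# 0.05 / 68 regions / 5 bands = 0.000147. Requires 02_extract_features.R.

library(megspect)

run <- readRDS("results/run_features.rds")
thr <- bonferroni_threshold(0.05, 68, 5)
res <- compare_groups(run$features, threshold = thr)
write.table(res, "results/group_comparison.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sig <- res[res$significant, ]
cat(sprintf("threshold %.6f; %d of %d cells significant\n",
            thr, nrow(sig), nrow(res)))
if (nrow(sig)) {
  print(sig[order(sig$p), c("value_type", "band", "region", "statistic",
                            "p", "direction")], row.names = FALSE)
}
cell <- res[res$value_type == "absEC" & res$band == "alpha1" &
              res$region == "rh_supramarginal", ]
cat(sprintf("designated cell absEC.alpha1.rh_supramarginal: t = %.2f, p = %.2e\n",
            cell$statistic, cell$p))
cat("wrote results/group_comparison.tsv\n")
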