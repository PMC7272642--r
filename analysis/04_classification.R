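#!/usr/bin/env Rscript
# AD-vs-NC discrimination from the 2,040-feature vectors: degree-2
# polynomial-kernel SVM, stratified subject-level 6-fold cross-validation,
# confusion matrix, ROC and AUC. Requires 02_extract_features.R.

library(megspect)

run <- readRDS("results/run_features.rds")
cv <- cross_validate(run$features, spec = classifier_spec(seed = run$config$seed))
print(cv)

jsonlite::write_json(list(
  confusion = cv$confusion, accuracy = cv$accuracy,
  sensitivity = cv$sensitivity, specificity = cv$specificity,
  auc = cv$auc, roc = cv$roc),
  "results/cv_report.json", auto_unbox = TRUE, digits = NA)
write.table(cv$predictions, "results/cv_predictions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# ROC curve figure
png("results/roc_curve.png", width = 600, height = 600)
plot(cv$roc$fpr, cv$roc$tpr, type = "s", lwd = 2,
     xlab = "False positive rate (1 - specificity)",
     ylab = "True positive rate (sensitivity)",
     main = sprintf("AD vs NC, 6-fold CV (AUC = %.2f)", cv$auc))
abline(0, 1, lty = 3)
dev.off()
cat("wrote results/cv_report.json, results/cv_predictions.tsv, results/roc_curve.png\n")
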