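#!/usr/bin/env Rscript
# Stage 5: yield regression and the cross-validated final model.
#
# Screens yield for normality, correlates yield with each vegetation index
# and its abundance-weighted variants (VI, VI*Abd_L, VI*Abd_P, VI*Abd_L-P),
# ranks all linear fits by adjusted R2, and reports leave-one-out
# cross-validated final models for NDRE*Abd_L-P and GNDVI*Abd_L-P.

suppressPackageStartupMessages(library(paddysma))

out <- "results/run"
tab <- read.csv(file.path(out, "plot_table.csv"))

cat(sprintf("Shapiro-Wilk p for yield: %.3f (normality %s at 0.05)\n",
            normality_test(tab$yield),
            if (normality_test(tab$yield) < 0.05) "rejected" else
              "not rejected"))

predictors <- list()
for (vi in vi_names()) {
  for (mode in c("plain", "L", "P", "LP")) {
    nm <- if (mode == "plain") vi else paste0(vi, "_", mode)
    predictors[[nm]] <- combined_index(tab[[vi]], tab, mode)
  }
}
corr <- correlate(tab$yield, predictors)
write.csv(corr, file.path(out, "correlations.csv"), row.names = FALSE)

ranking <- rank_models(tab, vi_names())
write.csv(ranking, file.path(out, "model_ranking.csv"), row.names = FALSE)
cat("\ntop of the model ranking (by adjusted R2):\n")
print(head(ranking, 6), row.names = FALSE)

cat("\nsign pattern across the ten indices:\n")
for (vi in vi_names()) {
  cat(sprintf("  %-10s r(VI)=%+.3f  r(VIxAbd_L)=%+.3f  r(VIxAbd_P)=%+.3f  r(VIxAbd_L-P)=%+.3f\n",
              vi, corr$r[corr$predictor == vi],
              corr$r[corr$predictor == paste0(vi, "_L")],
              corr$r[corr$predictor == paste0(vi, "_P")],
              corr$r[corr$predictor == paste0(vi, "_LP")]))
}

cv <- lapply(c("NDRE", "GNDVI"), function(vi) {
  loocv_fit(combined_index(tab[[vi]], tab, "LP"), tab$yield)
})
names(cv) <- c("NDRE_LP", "GNDVI_LP")
cat("\nleave-one-out final models:\n")
for (nm in names(cv)) {
  m <- cv[[nm]]
  cat(sprintf("  %s: yield = %.3f x + %.3f  (R2 %.3f, RMSE %.3f, %d folds)\n",
              nm, m$slope, m$intercept, m$r_squared, m$rmse, m$K))
}
jsonlite::write_json(lapply(cv, function(m) {
  list(slope = m$slope, intercept = m$intercept, r_squared = m$r_squared,
       rmse = m$rmse, K = m$K)
}), file.path(out, "final_models.json"), auto_unbox = TRUE, digits = NA)
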