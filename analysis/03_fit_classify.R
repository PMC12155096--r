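#!/usr/bin/env Rscript
# Hill fits and curve classification: per compound x channel x run fitted
# IC50/efficacy, curve class and curve rank; checks fitted IC50s of true
# inhibitors against the simulated ground truth.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "_common.R"))

res <- load_pipeline()

cls_dist <- dcast(res$runs[, .N, by = .(assay_id, curve_class)],
                  curve_class ~ assay_id, value.var = "N", fill = 0L)
fwrite(cls_dist, file.path(RESULTS_DIR, "curve_class_distribution.csv"))
message("curve-class distribution by channel (runs):")
print(cls_dist)

# IC50 recovery against ground truth (converged inhibition fits only)
joined <- res$runs[converged == TRUE & efficacy < 0][
  res$library$truth[activity_type == "inhibitor"],
  on = c("compound_id", "assay_id"), nomatch = NULL]
err <- abs(log10(joined$ac50_uM * 1e-6) - log10(joined$true_ac50))
message(sprintf(paste0("IC50 recovery on %d true-inhibitor runs: median ",
                       "|log10 error| = %.3f (%.0f%% within 2-fold)"),
                nrow(joined), median(err), 100 * mean(err < log10(2))))
fwrite(data.table(metric = c("n_runs", "median_abs_log10_ic50_error",
                             "pct_within_2fold"),
                  value = c(nrow(joined), median(err),
                            100 * mean(err < log10(2)))),
       file.path(RESULTS_DIR, "ic50_recovery.csv"))
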