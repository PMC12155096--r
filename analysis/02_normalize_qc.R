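#!/usr/bin/env Rscript
# Normalize raw plates to signed percent activity, estimate and apply the
# per-run DMSO-plate pattern correction, and tabulate plate QC (S/B, CV,
# Z'-factor) per channel, mirroring a screening-statistics table.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "_common.R"))

res <- load_pipeline()

qc_by_assay <- res$qc[, .(
  s_over_b = sprintf("%.1f ± %.1f", mean(s_over_b), sd(s_over_b)),
  cv_percent = sprintf("%.1f ± %.1f", mean(cv_percent), sd(cv_percent)),
  z_prime = sprintf("%.2f ± %.2f", mean(z_prime), sd(z_prime)),
  pass_pct = round(100 * mean(pass), 1)), by = assay_id]

fwrite(qc_by_assay, file.path(RESULTS_DIR, "qc_by_assay.csv"))
message("plate QC by channel (pass = S/B > 2, CV < 10%, Z' > 0.5):")
print(qc_by_assay)

surf_range <- range(unlist(lapply(res$surfaces, range)))
message(sprintf(paste0("pattern-correction surfaces span %.1f .. %.1f%% ",
                       "activity across runs"), surf_range[1], surf_range[2]))
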