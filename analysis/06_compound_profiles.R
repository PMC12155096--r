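#!/usr/bin/env Rscript
# Cross-assay compound profiles: potency (IC50 < 1 uM), selectivity
# (>10-fold vs all other CYPs), pan-CYP inhibition, luciferase counter-screen
# flags, and the screen-level pan-activity summary.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "_common.R"))

res <- load_pipeline()
cyp <- setdiff(unique(res$compounds$assay_id), "LUC")

prof <- res$profiles
s <- pan_summary(prof, cyp)
message(sprintf("unique compounds: %d", s$n_unique))
message(sprintf("inhibit >= 1 CYP: %d (%.1f%%)", s$n_ge1, s$pct_ge1))
message(sprintf("inhibit all 5 CYPs: %d (%.1f%%)", s$n_all, s$pct_all))
message("per-channel inhibitor counts:")
print(s$per_assay)

potent <- prof[potent == TRUE]
selective <- prof[!is.na(selective_for)]
flagged <- prof[luciferase_flag == TRUE]
message(sprintf("potent (IC50 < 1 uM in >= 1 CYP): %d; CYP-selective: %d; luciferase-flagged: %d",
                nrow(potent), nrow(selective), nrow(flagged)))

# potent, selective and luciferase-clean compounds: the candidate list a
# screen of this design would take forward
cand <- prof[potent == TRUE & !is.na(selective_for) & luciferase_flag == FALSE]
fwrite(cand, file.path(RESULTS_DIR, "selective_potent_candidates.csv"))
message(sprintf("candidates (potent, selective, luciferase-clean): %d", nrow(cand)))

summary_json <- list(
  n_unique = s$n_unique,
  n_ge1 = s$n_ge1, pct_ge1 = s$pct_ge1,
  n_all5 = s$n_all, pct_all5 = s$pct_all,
  per_assay = as.list(s$per_assay),
  n_potent = nrow(potent), n_selective = nrow(selective),
  n_luciferase_flagged = nrow(flagged))
jsonlite::write_json(summary_json, file.path(RESULTS_DIR, "profile_summary.json"),
                     auto_unbox = TRUE, digits = NA)
counts <- dcast(prof[, .N, by = .(pan_inhibitor, potent)],
                pan_inhibitor ~ potent, value.var = "N", fill = 0L)
fwrite(counts, file.path(RESULTS_DIR, "pan_potent_counts.csv"))
message("wrote profile summary to results/")
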