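#!/usr/bin/env Rscript
# Triplicate reproducibility calls and final activity outcomes per
# compound x channel; sensitivity / false-positive rate of inhibitor calls
# against the simulated ground truth.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "_common.R"))

res <- load_pipeline()

repro <- dcast(res$compounds[, .N, by = .(assay_id, repro_call)],
               repro_call ~ assay_id, value.var = "N", fill = 0L)
fwrite(repro, file.path(RESULTS_DIR, "reproducibility_calls.csv"))
message("reproducibility calls by channel (compounds):")
print(repro)

outc <- dcast(res$compounds[, .N, by = .(assay_id, outcome)],
              outcome ~ assay_id, value.var = "N", fill = 0L)
fwrite(outc, file.path(RESULTS_DIR, "activity_outcomes.csv"))
message("activity outcomes by channel:")
print(outc)

perf <- res$compounds[assay_id != "LUC", {
  truth_inh <- res$library$truth[assay_id == .BY$assay_id &
                                   activity_type == "inhibitor", compound_id]
  called <- compound_id[outcome == "inhibitor"]
  non <- setdiff(compound_id, truth_inh)
  list(sensitivity = mean(truth_inh %in% called),
       fpr = mean(non %in% called))
}, by = assay_id]
fwrite(perf, file.path(RESULTS_DIR, "call_performance.csv"))
message("inhibitor-call performance vs ground truth:")
print(perf)
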