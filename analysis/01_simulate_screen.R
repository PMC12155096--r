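#!/usr/bin/env Rscript
# Generate the synthetic screen: compound library with per-channel ground
# truth and raw 1536-well plates for five CYP channels plus the luciferase
# counter-screen, three runs each. Writes a library summary; the raw wells
# are regenerated on demand by later steps (they are deterministic in the
# seed).

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "_common.R"))

cfg <- study_config()
print(cfg)
lib <- generate_library(cfg)
print(lib)

summ <- lib$truth[assay_id != "LUC",
                  .(n_inhibitor_channels = sum(activity_type == "inhibitor"),
                    n_activator_channels = sum(activity_type == "activator")),
                  by = compound_id]
summ <- lib$compounds[summ, on = "compound_id"]
class_summary <- summ[, .(
  n = .N,
  frac_inhibitor = mean(n_inhibitor_channels > 0),
  enriched = enriched[1]), by = class_label][order(class_label)]

fwrite(class_summary, file.path(RESULTS_DIR, "library_class_summary.csv"))
message("per-class inhibitor fractions (enriched classes should sit near ",
        "0.8, background near 0.1):")
print(class_summary)

luc <- lib$truth[assay_id == "LUC", mean(activity_type == "inhibitor")]
message(sprintf("luciferase interferers: %.1f%% of samples", 100 * luc))

plates <- simulate_screen(lib, cfg, assays = "CYP1A2")
message(sprintf("one channel simulates to %d wells on %d plates per run",
                nrow(plates[run_id == 1]), uniqueN(plates[run_id == 1, plate_id])))
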