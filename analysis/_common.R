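# Shared setup for the analysis drivers: the study configuration and a
# cached end-to-end pipeline run (rebuilt when the cache is absent).

suppressPackageStartupMessages({
  library(qhtscyp)
  library(data.table)
})

RESULTS_DIR <- "results"
CACHE_FILE <- file.path(RESULTS_DIR, "cache_pipeline.rds")
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

# the emulated study conditions: 1000 samples in 10 structural classes,
# 3 classes enriched for inhibitors (80% vs 10% background), five CYP
# channels plus the luciferase counter-screen, three runs, noise CV 3%,
# spatial background 5% of the DMSO signal
study_config <- function(seed = 20260101 %% 99991)
  screen_config(seed = seed)

load_pipeline <- function() {
  if (file.exists(CACHE_FILE)) return(readRDS(CACHE_FILE))
  message("running the full pipeline (a few minutes) ...")
  res <- run_pipeline(study_config(), keep_plates = FALSE)
  saveRDS(res, CACHE_FILE)
  res
}
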