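#!/usr/bin/env Rscript
# Structural clustering and enrichment: a self-organizing map over the
# library fingerprints, then per-channel Fisher's exact enrichment of
# called inhibitors within each cluster; writes the enrichment tables and
# signed -log10(p) heatmap matrices.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "_common.R"))

res <- load_pipeline()
cyp <- setdiff(unique(res$compounds$assay_id), "LUC")

# grid sized to resolve the ten generated archetype classes into a few
# hexagons each (~30 compounds per occupied cell)
som <- train_som(res$library$compounds$fingerprint, n_rows = 6, n_cols = 5,
                 seed = 11)
print(som)

all_enr <- list()
for (assay in cyp) {
  called <- res$compounds[assay_id == assay & outcome == "inhibitor",
                          compound_id]
  flags <- res$library$compounds$compound_id %in% called
  enr <- fisher_enrich(som$assignments, flags)
  enr[, assay_id := assay]
  all_enr[[assay]] <- enr
  M <- enrichment_heatmap(enr, som)
  fwrite(as.data.table(M),
         file.path(RESULTS_DIR, sprintf("heatmap_%s.csv", assay)))
}
enr <- rbindlist(all_enr)
fwrite(enr, file.path(RESULTS_DIR, "cluster_enrichment.csv"))

sig <- enr[significant == TRUE]
message(sprintf("%d significant cluster-channel pairs (p < 0.01) across %d clusters",
                nrow(sig), uniqueN(enr$cluster_id)))
message("clusters significant in 3+ CYP channels (cf. the common structural classes):")
common <- sig[, .N, by = cluster_id][N >= 3][order(-N)]
print(common)

# how do significant clusters line up with the truly enriched classes?
cls <- res$library$compounds
dom <- cls[, .(dominant = names(which.max(table(som$assignments[.I])))),
           by = .(class_label, enriched)]
dom[, n_sig_channels := vapply(dominant, function(d) sig[cluster_id == d, .N],
                               integer(1))]
fwrite(dom, file.path(RESULTS_DIR, "class_dominant_clusters.csv"))
message("dominant cluster per generated class, with significant channel counts:")
print(dom)
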