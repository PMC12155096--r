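# Fisher's exact enrichment of actives within SOM clusters.

#' Per-cluster enrichment of active compounds
#'
#' For every cluster, builds the 2x2 table (in/out of cluster x
#' active/inactive) and computes the one-sided ("greater") Fisher's exact
#' p-value for enrichment -- the hypergeometric tail `P(X >= k_in)` -- plus
#' the opposite ("less") tail for deficiency of actives. Clusters are
#' significant at raw `p < p_cutoff` (no multiple-testing correction by
#' default, matching the raw `p < 0.01` convention); Benjamini-Hochberg
#' adjusted p-values can be added on request but do not change the
#' `significant` flag.
#'
#' @param assignments per-compound cluster ids (a factor keeps empty
#'   clusters in the output with `n_in = 0`, `p = 1`).
#' @param active_flags logical vector aligned with `assignments`.
#' @param p_cutoff significance cutoff on the raw enrichment p-value.
#' @param adjust `"none"` (default) or `"BH"` to append a `p_adj` column.
#' @return data.table, one row per cluster: `cluster_id`, `n_in`, `k_in`,
#'   `n_out`, `k_out`, `odds_ratio`, `p_value` (enrichment tail),
#'   `p_deficient` (deficiency tail), `neg_log10_p`, `significant`.
#' @export
fisher_enrich <- function(assignments, active_flags, p_cutoff = 0.01,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(length(assignments) == length(active_flags))
  active_flags <- as.logical(active_flags)
  if (anyNA(active_flags)) stop("active_flags must not contain NA", call. = FALSE)
  assignments <- as.factor(assignments)

  N <- length(active_flags)
  K <- sum(active_flags)
  n_in <- as.integer(table(assignments))
  k_in <- as.integer(tapply(active_flags, assignments, sum, default = 0L))
  n_out <- N - n_in
  k_out <- K - k_in

  p_gr <- phyper(k_in - 1L, K, N - K, n_in, lower.tail = FALSE)
  p_ls <- phyper(k_in, K, N - K, n_in, lower.tail = TRUE)
  p_gr[n_in == 0L] <- 1
  p_ls[n_in == 0L] <- 1

  or <- (k_in * (n_out - k_out)) / ((n_in - k_in) * k_out)
  res <- data.table::data.table(
    cluster_id = levels(assignments),
    n_in = n_in, k_in = k_in, n_out = n_out, k_out = k_out,
    odds_ratio = or, p_value = p_gr, p_deficient = p_ls,
    neg_log10_p = -log10(p_gr),
    significant = p_gr < p_cutoff & n_in > 0L)
  if (adjust == "BH") res[, p_adj := stats::p.adjust(p_value, "BH")]
  res[]
}

#' Signed significance heatmap matrix of a SOM enrichment
#'
#' One value per grid cell: `-log10(p)` of the enrichment tail where the
#' cluster's active fraction exceeds the library fraction, minus `-log10(p)`
#' of the deficiency tail where it falls below, 0 for empty cells or cells
#' at exactly the library fraction.
#'
#' @param results a [fisher_enrich()] table covering the grid.
#' @param som the [train_som()] result the assignments came from.
#' @return `n_rows x n_cols` numeric matrix (dimnames: rows/columns).
#' @export
enrichment_heatmap <- function(results, som) {
  N <- results$n_in[1L] + results$n_out[1L]
  K <- results$k_in[1L] + results$k_out[1L]
  overall <- K / N
  val <- numeric(nrow(results))
  frac <- ifelse(results$n_in > 0L, results$k_in / results$n_in, overall)
  up <- frac > overall
  dn <- frac < overall
  val[up] <- -log10(results$p_value[up])
  val[dn] <- log10(results$p_deficient[dn])
  M <- matrix(0, som$n_rows, som$n_cols,
              dimnames = list(paste0("r", seq_len(som$n_rows)),
                              paste0("c", seq_len(som$n_cols))))
  idx <- match(results$cluster_id, som$grid$cluster_id)
  M[cbind(som$grid$row[idx], som$grid$col[idx])] <- val
  M
}
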