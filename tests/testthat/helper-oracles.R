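# Independent oracles used to freeze expected values: straightforward,
# unoptimized re-implementations that share no code with the package paths
# they check.

# dense grid search for the Hill model: n_a log-spaced AC50 values, n_h
# log-spaced slopes, analytic (box-clamped) baseline/efficacy at each node
grid_oracle_rss <- function(conc, y, n_a = 50L, n_h = 20L,
                            bmax = 30, emax = 150) {
  a_grid <- exp(seq(log(min(conc) / 10), log(max(conc) * 10), length.out = n_a))
  h_grid <- exp(seq(log(0.3), log(8), length.out = n_h))
  best <- Inf
  n <- length(y)
  for (a in a_grid) {
    for (h in h_grid) {
      f <- 1 / (1 + (a / conc)^h)
      # unconstrained 2-parameter LS, then clamped variants
      X <- cbind(1, f)
      cands <- list()
      xtx <- crossprod(X)
      if (abs(det(xtx)) > 1e-12) {
        p <- solve(xtx, crossprod(X, y))
        cands[[length(cands) + 1L]] <- c(p)
      }
      for (bf in c(-bmax, bmax))
        cands[[length(cands) + 1L]] <- c(bf, sum(f * (y - bf)) / sum(f * f))
      for (ef in c(-emax, emax))
        cands[[length(cands) + 1L]] <- c(mean(y - ef * f), ef)
      cands[[length(cands) + 1L]] <- c(mean(y), 0)
      for (p in cands) {
        b <- min(bmax, max(-bmax, p[1]))
        e <- min(emax, max(-emax, p[2]))
        rss <- sum((y - b - e * f)^2)
        if (rss < best) best <- rss
      }
    }
  }
  best
}

# hypergeometric upper-tail P(X >= k) by direct log-binomial summation
fisher_tail_oracle <- function(k, K, N, n) {
  if (k > min(K, n)) return(0)
  j <- max(k, max(0L, n - (N - K))):min(K, n)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# plain re-statement of the reproducibility scoring rule: score each run
# outcome, average absolute pairwise differences, apply the printed
# thresholds (1.1 / 2.5 / 25% / 50%) with the no-active guard
repro_oracle <- function(categories, directions) {
  score1 <- function(cat, dir) {
    d <- c(inhibition = -1, activation = 1, none = 0)[[dir]]
    if (cat == "active") 5 * d
    else if (cat == "inconclusive") 2.5 * d
    else 0
  }
  s <- mapply(score1, categories, directions)
  n <- length(s)
  dsum <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dsum <- dsum + abs(s[i] - s[j]); np <- np + 1
  }
  avg <- dsum / np
  pct <- 100 * sum(categories == "inactive") / n
  if (avg < 1.1 && pct < 25) {
    if (any(categories == "active")) "active_match" else "inconclusive"
  } else if (avg < 1.1 && pct > 50) "inactive_match"
  else if (avg > 2.5) "mismatch"
  else "inconclusive"
}

# a hand-built library object with fully specified truth, for tests that
# need exact ground-truth control over the simulator
manual_library <- function(config, truth) {
  ids <- unique(truth$compound_id)
  compounds <- data.table::data.table(
    compound_id = ids, parent_id = ids,
    class_label = "CL01", enriched = FALSE,
    fingerprint = strrep("0f", config$fp_bits / 8))
  truth <- data.table::as.data.table(truth)
  data.table::setkey(truth, compound_id, assay_id)
  structure(list(compounds = compounds, truth = truth, config = config),
            class = "cyp_library")
}

# truth rows for one compound across channels
truth_row <- function(compound_id, assay_id, type = "inactive",
                      ac50 = NA_real_, eff = 0, hill = NA_real_) {
  data.table::data.table(compound_id = compound_id, assay_id = assay_id,
                         activity_type = type, true_ac50 = ac50,
                         true_efficacy = eff, true_hill = hill)
}
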