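library(data.table)

test_that("fingerprints round-trip through hex packing", {
  set.seed(5)
  bits <- matrix(rbinom(10 * 64, 1, 0.3), 10)
  hex <- fp_pack(bits)
  expect_true(all(nchar(hex) == 16L))
  expect_identical(fp_unpack(hex), matrix(as.integer(bits), 10))
  expect_equal(diag(tanimoto(bits)), rep(1, 10))
})

test_that("SOM assignment conserves the library and is deterministic", {
  set.seed(2)
  X <- matrix(rbinom(50 * 64, 1, 0.3), 50)
  s1 <- train_som(X, n_rows = 4, n_cols = 4, seed = 9)
  s2 <- train_som(X, n_rows = 4, n_cols = 4, seed = 9)
  expect_identical(s1$codebook, s2$codebook)
  expect_identical(s1$assignments, s2$assignments)
  expect_length(s1$assignments, 50L)
  expect_true(all(table(s1$assignments) >= 0))
  expect_identical(sum(table(s1$assignments)), 50L)
  expect_match(levels(s1$assignments)[1], "^k1\\.1$")
  one <- train_som(X[1, , drop = FALSE], n_rows = 1, n_cols = 1, seed = 1)
  expect_length(one$assignments, 1L)
})

test_that("two well-separated classes split on a 2-cell map", {
  arch_a <- c(rep(1, 24), rep(0, 40))
  arch_b <- c(rep(0, 40), rep(1, 24))
  ok <- 0L
  for (seed in 1:20) {
    set.seed(seed + 300)
    mk <- function(arch, n) t(vapply(seq_len(n), function(i) {
      flip <- rbinom(length(arch), 1, 0.05)
      (arch + flip) %% 2
    }, numeric(length(arch))))
    X <- rbind(mk(arch_a, 20), mk(arch_b, 20))
    s <- train_som(X, n_rows = 2, n_cols = 1, seed = seed)
    grp <- s$unit
    pure <- length(unique(grp[1:20])) == 1L &&
      length(unique(grp[21:40])) == 1L && grp[1] != grp[21]
    ok <- ok + pure
  }
  expect_gte(ok, 19L)
})

test_that("the map is topographically ordered on a class-structured library", {
  cfg <- screen_config(n_compounds = 500, n_classes = 10, dup_rate = 0,
                       seed = 27)
  lib <- generate_library(cfg)
  X <- fp_unpack(lib$compounds$fingerprint)
  som <- train_som(X, n_rows = 12, n_cols = 9, seed = 4)
  sim <- tanimoto(X)
  cellD <- som_cell_distances(som)
  pairD <- cellD[som$unit, som$unit]
  same <- pairD == 0; diag(same) <- FALSE
  far <- pairD >= 5
  expect_gt(mean(sim[same]), mean(sim[far]))
})

test_that("Fisher enrichment matches closed forms and the tail-sum oracle", {
  # worked example: N = 20, K = 10 actives, cluster of 5 all active
  asg <- factor(c(rep("k1.1", 5), rep("k1.2", 15)))
  act <- c(rep(TRUE, 5), rep(TRUE, 5), rep(FALSE, 10))
  res <- fisher_enrich(asg, act)
  p <- res[cluster_id == "k1.1", p_value]
  expect_equal(p, 252 / 15504, tolerance = 1e-12)
  expect_equal(p, fisher_tail_oracle(5, 10, 20, 5), tolerance = 1e-12)
  expect_false(res[cluster_id == "k1.1", significant])

  # null enrichment: cluster fraction equals library fraction
  asg2 <- factor(rep(c("a", "b"), each = 100))
  act2 <- rep(c(TRUE, FALSE, TRUE, FALSE), each = 50)
  res2 <- fisher_enrich(asg2, act2)
  expect_true(all(res2$p_value > 0.01))

  # cross-check against stats::fisher.test on a few tables
  set.seed(8)
  for (i in 1:10) {
    N <- sample(20:80, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    ks <- 0:min(K, n)
    k <- ks[sample.int(length(ks), 1)]
    tab <- matrix(c(k, n - k, K - k, N - K - (n - k)), 2)
    if (any(tab < 0)) next
    ft <- fisher.test(tab, alternative = "greater")
    expect_equal(fisher_tail_oracle(k, K, N, n), ft$p.value, tolerance = 1e-9)
  }
})

test_that("enrichment p-values equal the oracle over a small-N sweep", {
  for (N in c(6L, 11L, 20L)) {
    for (K in 0:N) for (n in 1:N) {
      for (k in max(0L, n - (N - K)):min(K, n)) {
        asg <- factor(rep(c("in", "out"), c(n, N - n)))
        act <- c(rep(TRUE, k), rep(FALSE, n - k),
                 rep(TRUE, K - k), rep(FALSE, (N - n) - (K - k)))
        res <- fisher_enrich(asg, act)
        expect_equal(res[cluster_id == "in", p_value],
                     fisher_tail_oracle(k, K, N, n), tolerance = 1e-12)
      }
    }
  }
})

test_that("empty clusters are kept with p = 1", {
  asg <- factor(rep("k1.1", 10), levels = c("k1.1", "k1.2"))
  res <- fisher_enrich(asg, rep(c(TRUE, FALSE), 5))
  empty <- res[cluster_id == "k1.2"]
  expect_identical(empty$n_in, 0L)
  expect_equal(empty$p_value, 1)
  expect_false(empty$significant)
})

test_that("the signed heatmap obeys the log identities and round-trips", {
  cfg <- screen_config(n_compounds = 300, n_classes = 6, dup_rate = 0,
                       seed = 33)
  lib <- generate_library(cfg)
  som <- train_som(lib$compounds$fingerprint, n_rows = 6, n_cols = 5,
                   seed = 2)
  act <- lib$compounds$compound_id %in%
    lib$truth[assay_id == "CYP1A2" & activity_type == "inhibitor", compound_id]
  res <- fisher_enrich(som$assignments, act)
  M <- enrichment_heatmap(res, som)
  expect_identical(dim(M), c(6L, 5L))
  # p identities: enriched cell value = -log10 p; p = 1 side contributes 0
  up <- res[p_value < 0.5 & k_in / pmax(n_in, 1) > mean(act)][1]
  expect_equal(M[som$grid[cluster_id == up$cluster_id, row],
                 som$grid[cluster_id == up$cluster_id, col]],
               -log10(up$p_value))
  # empty cells are exactly 0
  empt <- res[n_in == 0L, cluster_id]
  if (length(empt)) {
    rc <- som$grid[cluster_id == empt[1]]
    expect_identical(M[rc$row, rc$col], 0)
  }
  f <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(data.table::as.data.table(M), f)
  back <- as.matrix(data.table::fread(f))
  dimnames(back) <- dimnames(M)
  expect_equal(back, M, tolerance = 1e-12)
})

test_that("false enrichment is controlled on null libraries", {
  n_tests <- 0L; n_sig <- 0L
  for (seed in 1:25) {
    cfg <- screen_config(n_compounds = 400, n_classes = 10,
                         frac_enriched_classes = 0,
                         p_active_background = 0.1, dup_rate = 0,
                         p_activator = 0, seed = seed + 600)
    lib <- generate_library(cfg)
    som <- train_som(lib$compounds$fingerprint, n_rows = 10, n_cols = 8,
                     seed = seed)
    act <- lib$compounds$compound_id %in%
      lib$truth[assay_id == "CYP1A2" & activity_type == "inhibitor",
                compound_id]
    res <- fisher_enrich(som$assignments, act)
    n_tests <- n_tests + nrow(res)
    n_sig <- n_sig + sum(res$significant)
  }
  expect_gte(n_tests, 2000L)
  expect_lte(n_sig / n_tests, 0.02)
})

test_that("enriched classes surface as significant clusters", {
  hits <- 0L
  for (seed in 1:20) {
    cfg <- screen_config(n_compounds = 1000, n_classes = 10, dup_rate = 0,
                         seed = seed + 40)
    lib <- generate_library(cfg)
    som <- train_som(lib$compounds$fingerprint, n_rows = 6, n_cols = 5,
                     seed = seed)
    act <- lib$compounds$compound_id %in%
      lib$truth[assay_id == "CYP1A2" & activity_type == "inhibitor",
                compound_id]
    res <- fisher_enrich(som$assignments, act)
    ok <- vapply(unique(lib$compounds[enriched == TRUE, class_label]),
                 function(cl) {
                   members <- som$assignments[lib$compounds$class_label == cl]
                   dom <- names(which.max(table(members)))
                   res[cluster_id == dom, significant]
                 }, logical(1))
    hits <- hits + all(ok)
  }
  expect_gte(hits, 19L)
})
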