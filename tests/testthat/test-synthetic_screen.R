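library(data.table)

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_compounds = 60, n_classes = 3, n_runs = 2,
         assays = "CYP1A2", include_luciferase = FALSE, dup_rate = 0),
    list(...))
  do.call(screen_config, args)
}

test_that("configuration invariants are enforced", {
  expect_error(screen_config(n_compounds = 0), "positive integer")
  expect_error(screen_config(n_conc = 1), "n_conc")
  expect_error(screen_config(conc_min = 1e-5, conc_max = 1e-6), "conc_min")
  expect_error(screen_config(p_active_enriched = 1.2), "probability")
})

test_that("concentration series hits the endpoints with a geometric step", {
  cfg <- screen_config()
  cc <- concentration_series(cfg)
  expect_length(cc, 15L)
  expect_identical(cc[1], 0.7e-9)
  expect_identical(cc[15], 58e-6)
  ratios <- cc[-1] / cc[-15]
  expected_ratio <- (58e-6 / 0.7e-9)^(1 / 14)  # ~2.246 per step
  expect_equal(ratios, rep(expected_ratio, 14), tolerance = 1e-12)
  cc2 <- concentration_series(screen_config(n_conc = 2))
  expect_identical(cc2, c(0.7e-9, 58e-6))
})

test_that("library generation is deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 7)
  l1 <- generate_library(cfg)
  l2 <- generate_library(cfg)
  expect_identical(l1$compounds, l2$compounds)
  expect_identical(l1$truth, l2$truth)
  p1 <- simulate_screen(l1, cfg)
  p2 <- simulate_screen(l2, cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
})

test_that("degenerate activity probabilities are honored exactly", {
  cfg <- small_cfg(p_active_enriched = 1, p_active_background = 0,
                   frac_enriched_classes = 1 / 3, p_activator = 0, seed = 11)
  lib <- generate_library(cfg)
  inh <- lib$truth[activity_type == "inhibitor", unique(compound_id)]
  enr <- lib$compounds[enriched == TRUE, compound_id]
  expect_setequal(inh, enr)
})

test_that("realized per-class active fractions stay within binomial bounds", {
  cfg <- screen_config(n_compounds = 1000, n_classes = 10,
                       frac_enriched_classes = 0.3, p_active_enriched = 0.8,
                       p_active_background = 0.1, dup_rate = 0,
                       p_activator = 0, seed = 19)
  lib <- generate_library(cfg)
  inh <- lib$truth[activity_type == "inhibitor" & assay_id != "LUC",
                   unique(compound_id)]
  counts <- lib$compounds[, .(k = sum(compound_id %in% inh), n = .N),
                          by = .(class_label, enriched)]
  for (i in seq_len(nrow(counts))) {
    p <- if (counts$enriched[i]) 0.8 else 0.1
    lo <- qbinom(0.005, counts$n[i], p)
    hi <- qbinom(0.995, counts$n[i], p)
    expect_gte(counts$k[i], lo)
    expect_lte(counts$k[i], hi)
  }
})

test_that("plates have the study geometry and conserve compound placements", {
  cfg <- small_cfg(seed = 3)
  lib <- generate_library(cfg)
  plates <- simulate_screen(lib, cfg)
  per_plate <- plates[, .N, by = plate_id]
  expect_true(all(per_plate$N == 1536L))
  expect_true(all(plates[role %in% c("DMSO", "positive_control") &
                           plate_type == "compound", col] <= 4L))
  expect_true(all(plates[role == "test", col] >= 5L))
  # every compound appears exactly n_runs * n_conc times as a test well
  counts <- plates[role == "test", .N, by = compound_id]
  expect_true(all(counts$N == cfg$n_runs * cfg$n_conc))
  # and once per run x concentration
  dup <- plates[role == "test", .N, by = .(compound_id, run_id, conc_index)]
  expect_true(all(dup$N == 1L))
})

test_that("oversized libraries raise a sizing error", {
  cfg <- small_cfg(n_compounds = 3000, n_classes = 5, max_plates = 2,
                   seed = 1)
  lib <- generate_library(cfg)
  expect_error(simulate_screen(lib, cfg), "sizing error")
})

test_that("noiseless screens round-trip through normalization exactly", {
  cfg <- small_cfg(noise_cv = 0, pattern_amplitude = 0, seed = 5,
                   p_active_enriched = 0, p_active_background = 0,
                   p_activator = 0)
  lib <- generate_library(cfg)
  plates <- simulate_screen(lib, cfg)
  norm <- normalize_screen(plates)
  act <- norm[role == "test" & !is.na(compound_id), activity]
  expect_lt(max(abs(act)), 1e-9)
})

test_that("a noiseless inhibitor shows the Hill midpoint at its AC50", {
  cfg <- small_cfg(noise_cv = 0, pattern_amplitude = 0, n_runs = 1)
  conc <- concentration_series(cfg)
  truth <- truth_row("C1", "CYP1A2", "inhibitor",
                     ac50 = conc[8], eff = -100, hill = 1.3)
  lib <- manual_library(cfg, truth)
  plates <- simulate_screen(lib, cfg)
  norm <- normalize_screen(plates)
  s <- cr_series(norm[plate_type == "compound"])
  expect_equal(s[concentration_M == conc[8], activity], -50, tolerance = 1e-9)
  # asymptote never overshoots the true efficacy
  expect_true(all(s$activity > -100 - 1e-9))
})

test_that("per-plate DMSO CV estimates concentrate around the injected CV", {
  cfg <- screen_config(n_compounds = 120, n_classes = 3, noise_cv = 0.03,
                       assays = "CYP1A2", include_luciferase = FALSE,
                       dup_rate = 0, seed = 23)
  lib <- generate_library(cfg)
  plates <- simulate_screen(lib, cfg)
  cvs <- plates[plate_type == "compound" & role == "DMSO",
                .(cv = 100 * sd(rlu) / mean(rlu)), by = plate_id]
  expect_gte(nrow(cvs), 45L)
  expect_gte(mean(cvs$cv >= 2 & cvs$cv <= 4), 0.95)
})

test_that("screens serialize to text and read back unchanged", {
  cfg <- small_cfg(seed = 13, n_compounds = 30)
  lib <- generate_library(cfg)
  plates <- simulate_screen(lib, cfg)
  d <- withr::local_tempdir()
  write_screen(lib, plates, d)
  expect_true(all(file.exists(file.path(d, c("library.csv", "truth.csv",
                                             "plates.csv")))))
  back <- read_plates(file.path(d, "plates.csv"))
  expect_equal(nrow(back), nrow(plates))
  expect_equal(back$rlu, plates$rlu, tolerance = 1e-12)
})
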