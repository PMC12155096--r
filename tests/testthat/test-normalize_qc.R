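library(data.table)

# minimal plate with explicit control wells and a few test wells
toy_plate <- function(test_rlu, dmso_rlu = 10000, pos_rlu = 500) {
  ctrl <- rbind(
    data.table(plate_id = "P1", row = 1:16, col = 1L,
               role = "positive_control",
               concentration_M = exp(seq(log(0.7e-9), log(58e-6), length.out = 16)),
               rlu = pos_rlu),
    data.table(plate_id = "P1", row = 1:16, col = 3L, role = "DMSO",
               concentration_M = NA_real_, rlu = dmso_rlu))
  test <- data.table(plate_id = "P1", row = seq_along(test_rlu), col = 5L,
                     role = "test", concentration_M = 1e-6, rlu = test_rlu)
  rbind(ctrl, test)
}

test_that("the normalization formula maps its anchor points exactly", {
  p <- toy_plate(c(10000, 500, 5250))
  norm <- normalize_plate(p)
  act <- norm[role == "test", activity]
  expect_equal(act[1], 0, tolerance = 1e-9)      # V_compound = V_DMSO
  expect_equal(act[2], -100, tolerance = 1e-9)   # V_compound = V_pos
  expect_equal(act[3], -50.0, tolerance = 1e-9)  # worked mid value
  expect_equal(median(norm[role == "DMSO", activity]), 0, tolerance = 1e-12)
})

test_that("normalization is affine and monotone decreasing in the signal", {
  rlu <- seq(200, 12000, length.out = 25)
  p <- toy_plate(rlu)
  act <- normalize_plate(p)[role == "test", activity]
  expect_true(all(diff(act) > 0))  # increasing rlu -> increasing activity
  d1 <- diff(act) / diff(rlu)
  expect_equal(d1, rep(d1[1], length(d1)), tolerance = 1e-9)  # affine
})

test_that("degenerate controls raise a normalization error naming the plate", {
  p <- toy_plate(1000, dmso_rlu = 500, pos_rlu = 500)
  expect_error(normalize_plate(p), "degenerate controls.*P1")
})

test_that("QC statistics follow the closed forms and thresholds", {
  st <- structure(list(v_dmso_median = 10000, v_pos_median = 500,
                       mu_dmso = 10000, sigma_dmso = 200,
                       mu_pos = 500, sigma_pos = 50),
                  class = "control_stats")
  q <- compute_qc(st)
  expect_equal(q$s_over_b, 20)
  expect_equal(q$cv_percent, 2.0)
  expect_equal(q$z_prime, 1 - 3 * 250 / 9500, tolerance = 1e-12)
  expect_equal(round(q$z_prime, 4), 0.9211)
  expect_true(q$pass)
  # noiseless limit
  st0 <- st; st0$sigma_dmso <- 0; st0$sigma_pos <- 0
  expect_equal(compute_qc(st0)$z_prime, 1)
  # each threshold individually controls the pass flag
  bad_sb <- st; bad_sb$mu_pos <- 6000  # S/B < 2
  expect_false(compute_qc(bad_sb)$pass)
  bad_cv <- st; bad_cv$sigma_dmso <- 1100  # CV > 10
  expect_false(compute_qc(bad_cv)$pass)
  bad_z <- st; bad_z$sigma_pos <- 1500  # Z' < 0.5
  expect_false(compute_qc(bad_z)$pass)
  expect_error(compute_qc({s <- st; s$mu_pos <- 0; s}), "QC error")
})

test_that("a pattern-free screen yields a near-zero correction surface", {
  cfg <- screen_config(n_compounds = 60, n_classes = 3, n_runs = 1,
                       assays = "CYP1A2", include_luciferase = FALSE,
                       pattern_amplitude = 0, noise_cv = 0.03,
                       n_dmso_plates = 3, dup_rate = 0, seed = 31)
  lib <- generate_library(cfg)
  plates <- simulate_screen(lib, cfg)
  norm <- normalize_screen(plates)
  surf <- estimate_pattern(norm[plate_type == "dmso"])
  # smoothed marginals over ~45 wells each: bound well under raw well noise
  expect_lt(max(abs(surf)), 3 * 3.2 / sqrt(9))
})

test_that("an injected column gradient is recovered by the surface", {
  set.seed(41)
  grad <- 5 * (2 * (seq_len(48) - 24.5) / 47)  # +-5 percent linear in column
  wells <- CJ(row = 1:32, col = 3:48)
  plates <- rbindlist(lapply(1:2, function(p) {
    w <- copy(wells)
    w[, `:=`(plate_id = paste0("D", p), role = "DMSO",
             activity = grad[col] + rnorm(.N, 0, 3), plate_type = "dmso")]
    w
  }))
  surf <- estimate_pattern(plates)
  inj <- matrix(grad, 32, 48, byrow = TRUE)
  expect_gt(cor(as.vector(surf[, 3:48]), as.vector(inj[, 3:48])), 0.9)
})

test_that("pattern correction preserves plate medians and is idempotent", {
  cfg <- screen_config(n_compounds = 60, n_classes = 3, n_runs = 1,
                       assays = "CYP1A2", include_luciferase = FALSE,
                       pattern_amplitude = 0.05, noise_cv = 0.03,
                       dup_rate = 0, seed = 37)
  lib <- generate_library(cfg)
  plates <- simulate_screen(lib, cfg)
  norm <- normalize_screen(plates)
  dmso <- norm[plate_type == "dmso"]
  surf <- estimate_pattern(dmso)

  before <- dmso[, .(m = median(activity)), by = plate_id]
  once <- correct_plate(dmso, surf)
  after <- once[, .(m = median(activity)), by = plate_id]
  expect_equal(after$m, before$m, tolerance = 1e-9)
  expect_true(attr(once, "correction_applied"))

  # correcting the corrected DMSO plates again barely changes them
  surf2 <- estimate_pattern(once)
  twice <- correct_plate(once, surf2)
  expect_lt(max(abs(twice$activity - once$activity)), 1.5)
  # subtracting the surface reduces the DMSO wells' RMS activity
  expect_lt(sqrt(mean(once[role == "DMSO", activity]^2)),
            sqrt(mean(dmso[role == "DMSO", activity]^2)))
  expect_equal(median(surf), 0, tolerance = 1e-12)
})

test_that("correction shrinks spatial systematic bias at least five-fold", {
  # gradient 5% of signal, noise CV 3%; systematic spatial bias of the
  # test-well area judged against the known injected pattern
  # (plate-median-centered, since the correction preserves plate medians
  # by construction)
  ratios <- numeric(0)
  for (seed in c(17, 29, 43)) {
    cfg <- screen_config(n_compounds = 200, n_classes = 4, n_runs = 1,
                         assays = "CYP1A2", include_luciferase = FALSE,
                         pattern_amplitude = 0.05, noise_cv = 0.03,
                         p_active_enriched = 0, p_active_background = 0,
                         p_activator = 0, dup_rate = 0, seed = seed)
    lib <- generate_library(cfg)
    plates <- simulate_screen(lib, cfg)
    norm <- normalize_screen(plates)
    surf <- estimate_pattern(norm[plate_type == "dmso"])
    pat <- attr(plates, "true_pattern")[["CYP1A2|r1"]] * cfg$baseline_rlu
    span <- (cfg$baseline_rlu + median(pat[, 3:4])) -
      (cfg$background_frac * cfg$baseline_rlu + median(pat[, 1:2]))
    true_bias <- 100 * (pat - median(pat[, 3:4])) / span
    ctr <- function(M) M - median(M)
    rms <- function(M) sqrt(mean(M^2))
    tw <- 5:48  # test-well columns
    ratios <- c(ratios,
                rms(ctr(true_bias)[, tw]) / rms(ctr(true_bias - surf)[, tw]))
  }
  expect_gte(mean(ratios), 5)
  expect_true(all(ratios >= 3))
})

test_that("disabling correction without DMSO plates warns and passes through", {
  p <- toy_plate(c(9000, 9500))
  norm <- normalize_plate(p)
  expect_warning(surf <- estimate_pattern(norm[role == "empty"]), "disabled")
  expect_null(surf)
  out <- correct_plate(norm, NULL)
  expect_equal(out$activity, norm$activity)
  expect_false(attr(out, "correction_applied"))
})
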