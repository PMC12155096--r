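# End-to-end drivers: plates -> calls -> compound-level outcomes.

#' Per-run and compound-level calls for a set of corrected plates
#'
#' Pivots corrected plates into series, fits the Hill model per
#' compound x assay x run, assigns curve classes and ranks, and aggregates
#' triplicates into reproducibility calls and activity outcomes. The
#' single-point (class 3) background threshold uses the SD of normalized
#' DMSO-well activity of each assay x run. For unconverged fits the class-3
#' direction and rank bonus use the observed response at the top tested
#' concentration. The compound-level IC50 is the median fitted AC50 (uM)
#' over the runs with a converged inhibition-direction fit.
#'
#' @param plates corrected compound-plate wells ([correct_screen()]).
#' @param cfg a [class_config()].
#' @param rcfg a [repro_config()].
#' @param ... passed to [fit_hill()].
#' @return List: `runs` (per compound x assay x run: fit parameters,
#'   `curve_class`, `curve_rank`, run outcome) and `compounds` (per
#'   compound x assay: `avg_rank`, `repro_call`, `avg_score_diff`,
#'   `pct_inactive`, `outcome`, `ic50_uM`, `efficacy`).
#' @export
compound_calls <- function(plates, cfg = class_config(),
                           rcfg = repro_config(), ...) {
  series <- cr_series(plates)

  dm <- plates[role == "DMSO", .(dmso_sd = sd(activity)),
               by = .(assay_id, run_id)]
  series <- dm[series, on = c("assay_id", "run_id")]
  series[is.na(dmso_sd), dmso_sd := 3]
  data.table::setorder(series, compound_id, assay_id, run_id, concentration_M)

  fits <- series[, {
    ft <- fit_hill(concentration_M, activity, ...)
    cls <- classify_curve(ft, concentration_M, activity,
                          cfg = cfg, dmso_sd = dmso_sd[1L])
    eff_used <- if (ft$converged) ft$efficacy else activity[.N]
    rnk <- curve_rank(cls, eff_used, cfg = cfg)
    ro <- run_outcome(cls)
    list(ac50_uM = ft$ac50 * 1e6, efficacy = ft$efficacy, hill = ft$hill,
         baseline = ft$baseline, r2 = ft$r2, rss = ft$rss,
         converged = ft$converged, last_activity = activity[.N],
         dmso_sd = dmso_sd[1L], curve_class = cls, curve_rank = rnk,
         run_category = ro$category, run_direction = ro$direction)
  }, by = .(compound_id, assay_id, run_id)]

  compounds <- fits[, {
    rc <- repro_call(run_category, run_direction, cfg = rcfg)
    inh <- converged & efficacy < 0
    list(avg_rank = mean(curve_rank),
         repro_call = rc$call,
         avg_score_diff = rc$avg_score_diff,
         pct_inactive = rc$pct_inactive,
         outcome = assign_outcome(curve_rank, curve_class, rc$call),
         ic50_uM = if (any(inh)) median(ac50_uM[inh]) else NA_real_,
         efficacy = if (any(converged)) median(efficacy[converged]) else 0,
         n_runs = .N)
  }, by = .(compound_id, assay_id)]

  list(runs = fits[], compounds = compounds[])
}

#' Run the full pipeline on one configuration
#'
#' Generates the library and raw plates, normalizes, estimates and applies
#' the per-run pattern correction, computes plate QC, produces per-run and
#' compound-level calls for every channel, and assembles cross-assay
#' profiles.
#'
#' @param config a [screen_config()].
#' @param assays channels to simulate (default: all configured).
#' @param keep_plates retain the corrected well-level data in the result.
#' @param ... passed to [compound_calls()].
#' @return List: `library`, `qc` (per-plate QC table), `runs`, `compounds`,
#'   `profiles`, `surfaces`, and (optionally) `plates`.
#' @export
run_pipeline <- function(config, assays = NULL, keep_plates = FALSE, ...) {
  lib <- generate_library(config)
  raw <- simulate_screen(lib, config, assays = assays)
  qc <- qc_screen(raw[plate_type == "compound"])
  norm <- normalize_screen(raw)
  corr <- correct_screen(norm)
  calls <- compound_calls(corr$plates, ...)
  profiles <- compound_profiles(calls$compounds,
                                parent_map = lib$compounds)
  out <- list(library = lib, qc = qc, runs = calls$runs,
              compounds = calls$compounds, profiles = profiles,
              surfaces = corr$surfaces)
  if (keep_plates) out$plates <- corr$plates
  out
}
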