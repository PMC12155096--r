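# Curve classification, curve ranks and per-compound activity outcomes.

#' Thresholds for curve classification and ranking
#'
#' The published class definitions list the criteria (efficacy, points above
#' background, fit quality) but not numeric cutoffs; these defaults are
#' explicit conventions and can all be swapped.
#'
#' @param efficacy_cutoff minimum `|efficacy|` (percent) for a qualifying
#'   curve; below it the curve is class 4 (or 3 via the single-point rule).
#' @param high_efficacy `|efficacy|` (percent) separating subclass .1 from .2.
#' @param r2_good minimum r-squared for subclass .1.
#' @param plateau_tol fraction of `|efficacy|` within which the fitted
#'   response at the two highest tested concentrations must approach the top
#'   asymptote for the curve to count as complete (class 1.x).
#' @param single_point_mult multiple of the DMSO well SD that the response at
#'   the highest concentration must exceed for class 3; the same multiple
#'   defines "above background" for `min_points_above`.
#' @param min_points_above number of data points that must lie beyond the
#'   background band (relative to the fitted baseline, in the curve's
#'   direction) for a qualifying class 1.x/2.x curve.
#' @param rank_bonus_efficacy `|efficacy|` (percent) granting the +1 curve
#'   rank bonus.
#' @return List of class `class_config`.
#' @export
class_config <- function(efficacy_cutoff = 30, high_efficacy = 80,
                         r2_good = 0.9, plateau_tol = 0.1,
                         single_point_mult = 3, min_points_above = 2,
                         rank_bonus_efficacy = 90) {
  stopifnot(efficacy_cutoff > 0, efficacy_cutoff < high_efficacy)
  structure(list(efficacy_cutoff = efficacy_cutoff,
                 high_efficacy = high_efficacy, r2_good = r2_good,
                 plateau_tol = plateau_tol,
                 single_point_mult = single_point_mult,
                 min_points_above = min_points_above,
                 rank_bonus_efficacy = rank_bonus_efficacy),
            class = "class_config")
}

#' Assign a curve class to one fitted series
#'
#' Classes follow the qHTS convention: sign encodes direction (negative =
#' inhibition), magnitude encodes curve completeness and quality. A curve
#' qualifies for class 1.x/2.x when the fit converged, `|efficacy| >=
#' efficacy_cutoff`, and at least `min_points_above` data points lie beyond
#' the background band (`single_point_mult * dmso_sd`, in the curve's
#' direction, measured both from zero and from the fitted baseline) -- the
#' classification criteria are efficacy, points above background, and fit
#' quality. Class 1.x: both
#' asymptotes observed in the tested range (the fitted response at the two
#' highest concentrations is within `plateau_tol * |efficacy|` of the top
#' asymptote). Class 2.x: qualifying but partial curve. Subclass .1 needs
#' `|efficacy| >= high_efficacy` and `r2 >= r2_good`, otherwise .2. Class 3:
#' no qualifying fit but the response at the highest concentration alone
#' exceeds `single_point_mult * dmso_sd`. Class 4: inactive.
#'
#' @param fit a [fit_hill()] result.
#' @param conc,activity the fitted series.
#' @param cfg a [class_config()].
#' @param dmso_sd SD of normalized DMSO-well activity (percent) for the
#'   single-point rule.
#' @return Curve class value in
#'   `{-1.1, -1.2, -2.1, -2.2, -3, 1.1, 1.2, 2.1, 2.2, 3, 4}`.
#' @export
classify_curve <- function(fit, conc, activity, cfg = class_config(),
                           dmso_sd = 3) {
  qualifies <- isTRUE(fit$converged) && abs(fit$efficacy) >= cfg$efficacy_cutoff
  if (qualifies) {
    band <- cfg$single_point_mult * dmso_sd
    d <- sign(fit$efficacy)
    # a point counts only if it stands out from the plate background band
    # around zero AND from the curve's own fitted baseline (guards against
    # fits that park the baseline at its bound below/above all the data)
    n_above <- sum(d * (activity - fit$baseline) >= band & d * activity >= band)
    qualifies <- n_above >= cfg$min_points_above
  }
  if (!qualifies) {
    last <- activity[which.max(conc)]
    if (abs(last) >= cfg$single_point_mult * dmso_sd)
      return(sign(last) * 3)
    return(4)
  }
  dir <- sign(fit$efficacy)
  top2 <- sort(conc, decreasing = TRUE)[1:2]
  pred <- hill_response(top2, fit$baseline, fit$efficacy, fit$ac50, fit$hill)
  plateau <- all(abs(pred - (fit$baseline + fit$efficacy)) <=
                   cfg$plateau_tol * abs(fit$efficacy))
  major <- if (plateau) 1 else 2
  sub <- if (abs(fit$efficacy) >= cfg$high_efficacy && fit$r2 >= cfg$r2_good)
    0.1 else 0.2
  dir * (major + sub)
}

RANK_MAGNITUDE <- c("1.1" = 8, "2.1" = 7, "1.2" = 6, "2.2" = 4,
                    "3.0" = 2, "4.0" = 0)

#' Convert a curve class plus efficacy to a numerical curve rank
#'
#' Rank magnitude encodes evidence strength (`1.1 -> 8, 2.1 -> 7, 1.2 -> 6,
#' 2.2 -> 4, 3 -> 2, 4 -> 0`) with a +1 bonus (capped at 9) for
#' `|efficacy| >= rank_bonus_efficacy`; the sign copies the class direction.
#' A direction mismatch between class and efficacy yields rank 0.
#'
#' @param cls curve class value (see [classify_curve()]).
#' @param efficacy signed percent efficacy of the same curve (for class 3
#'   curves pass the observed top-concentration response).
#' @param cfg a [class_config()].
#' @return Integer rank in `[-9, 9]`.
#' @export
curve_rank <- function(cls, efficacy, cfg = class_config()) {
  mag <- RANK_MAGNITUDE[sprintf("%.1f", abs(cls))]
  if (is.na(mag)) stop("unknown curve class: ", cls, call. = FALSE)
  if (mag == 0) return(0L)
  s <- sign(cls)
  if (sign(efficacy) != 0 && sign(efficacy) != s) return(0L)
  if (abs(efficacy) >= cfg$rank_bonus_efficacy) mag <- min(mag + 1, 9)
  as.integer(s * mag)
}

#' Final activity outcome of a compound in one assay
#'
#' Combines the triplicate average curve rank, the reproducibility call and
#' the per-run classes: inactive when every run is class 4; inhibitor
#' (activator) when the average rank is <= -5 (>= +5) and the runs are an
#' active match; inconclusive inhibitor/activator for weaker but
#' direction-consistent evidence; inconclusive when run directions conflict
#' or the runs mismatch.
#'
#' @param ranks per-run curve ranks (length >= 2).
#' @param classes per-run curve classes.
#' @param repro reproducibility call string (see [repro_call()]).
#' @param rank_cutoff `|average rank|` needed for a definite call.
#' @return One of `"inhibitor"`, `"activator"`, `"inconclusive_inhibitor"`,
#'   `"inconclusive_activator"`, `"inconclusive"`, `"inactive"`.
#' @export
assign_outcome <- function(ranks, classes, repro, rank_cutoff = 5) {
  stopifnot(length(ranks) >= 2L, length(ranks) == length(classes))
  if (all(classes == 4)) return("inactive")
  dirs <- sign(classes[classes != 4])
  if (any(dirs > 0) && any(dirs < 0)) return("inconclusive")
  if (identical(repro, "mismatch")) return("inconclusive")
  avg <- mean(ranks)
  d <- sign(avg)
  if (d == 0) return("inconclusive")
  if (abs(avg) >= rank_cutoff && identical(repro, "active_match"))
    return(if (d < 0) "inhibitor" else "activator")
  if (d < 0) "inconclusive_inhibitor" else "inconclusive_activator"
}
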