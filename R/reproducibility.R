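# Triplicate reproducibility: per-run outcomes, scores, and the four calls.

#' Per-run activity outcome of a curve class
#'
#' Classes -1.1/-1.2/-2.1/-2.2 are active inhibition, their positive mirrors
#' active activation, class 4 is inactive, everything else (the +-3 single
#' point classes) is inconclusive with the class's direction.
#'
#' @param cls curve class value.
#' @return List: `category` (`"active"`/`"inactive"`/`"inconclusive"`) and
#'   `direction` (`"inhibition"`/`"activation"`/`"none"`).
#' @export
run_outcome <- function(cls) {
  a <- abs(cls)
  if (cls == 4) return(list(category = "inactive", direction = "none"))
  dir <- if (cls < 0) "inhibition" else "activation"
  if (a %in% c(1.1, 1.2, 2.1, 2.2))
    return(list(category = "active", direction = dir))
  list(category = "inconclusive", direction = dir)
}

#' Scores and thresholds for reproducibility calls
#'
#' The published rule states the thresholds (average score difference 1.1
#' and 2.5, inactive fractions 25% and 50%) but not the score values; the
#' defaults (+-5 active, +-2.5 inconclusive, 0 inactive, signed by
#' direction) make any active/inactive disagreement a mismatch and put
#' active/inconclusive mixtures in the inconclusive band.
#'
#' @param score_active,score_inconclusive score magnitudes (signed by
#'   direction; directionless inconclusive scores 0).
#' @param match_threshold,mismatch_threshold average pairwise score
#'   difference cutoffs.
#' @param inactive_low,inactive_high percent-inactive cutoffs for active
#'   match / inactive match.
#' @return List of class `repro_config`.
#' @export
repro_config <- function(score_active = 5, score_inconclusive = 2.5,
                         match_threshold = 1.1, mismatch_threshold = 2.5,
                         inactive_low = 25, inactive_high = 50) {
  stopifnot(match_threshold < mismatch_threshold)
  structure(list(score_active = score_active,
                 score_inconclusive = score_inconclusive,
                 match_threshold = match_threshold,
                 mismatch_threshold = mismatch_threshold,
                 inactive_low = inactive_low, inactive_high = inactive_high),
            class = "repro_config")
}

outcome_score <- function(category, direction, cfg = repro_config()) {
  s <- switch(category, active = cfg$score_active,
              inconclusive = cfg$score_inconclusive, inactive = 0,
              stop("unknown outcome category: ", category, call. = FALSE))
  d <- switch(direction, inhibition = -1, activation = 1, none = 0,
              stop("unknown direction: ", direction, call. = FALSE))
  if (category == "inactive") 0 else s * d
}

#' Reproducibility call from replicate run outcomes
#'
#' Each run outcome is scored (signed by direction), the absolute pairwise
#' score differences over all run pairs are averaged, and the fraction of
#' inactive calls is computed. The call is: active match (average difference
#' < `match_threshold` and % inactive < `inactive_low`), inactive match
#' (average difference < `match_threshold` and % inactive >
#' `inactive_high`), mismatch (average difference > `mismatch_threshold`),
#' inconclusive otherwise. Replicate sets containing no active run cannot be
#' an active match and are rerouted to inconclusive (the literal rule would
#' label e.g. three inconclusive runs an active match). The call is
#' invariant to run order.
#'
#' @param categories per-run outcome categories
#'   (`"active"`/`"inactive"`/`"inconclusive"`).
#' @param directions per-run directions
#'   (`"inhibition"`/`"activation"`/`"none"`).
#' @param cfg a [repro_config()].
#' @return List of class `repro_call`: `call` (`"active_match"`,
#'   `"inactive_match"`, `"mismatch"`, `"inconclusive"`), `avg_score_diff`,
#'   `pct_inactive`.
#' @export
repro_call <- function(categories, directions, cfg = repro_config()) {
  stopifnot(length(categories) == length(directions))
  n <- length(categories)
  if (n < 2L) {
    return(structure(list(call = "inconclusive",
                          avg_score_diff = NA_real_,
                          pct_inactive = 100 * mean(categories == "inactive")),
                     class = "repro_call"))
  }
  sc <- mapply(outcome_score, categories, directions,
               MoreArgs = list(cfg = cfg))
  prs <- combn(n, 2L)
  avg <- mean(abs(sc[prs[1L, ]] - sc[prs[2L, ]]))
  pct <- 100 * mean(categories == "inactive")
  call <- if (avg < cfg$match_threshold && pct < cfg$inactive_low) {
    if (any(categories == "active")) "active_match" else "inconclusive"
  } else if (avg < cfg$match_threshold && pct > cfg$inactive_high) {
    "inactive_match"
  } else if (avg > cfg$mismatch_threshold) {
    "mismatch"
  } else "inconclusive"
  structure(list(call = call, avg_score_diff = avg, pct_inactive = pct),
            class = "repro_call")
}
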