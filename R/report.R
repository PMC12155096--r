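# Cross-assay compound profiling: potency, selectivity, pan-activity,
# luciferase counter-screen flags.

#' Selective assay of a compound, if any
#'
#' Returns the assay in which the compound is an inhibitor with an IC50 more
#' than `fold`-fold lower than in every other assay; assays without an
#' inhibitor call count as IC50 = infinity. The comparison is against all
#' other assays (the stricter reading of ">10-fold versus other CYPs"), so
#' at most one assay can qualify.
#'
#' @param ic50 named numeric vector of IC50s (uM) per assay (NA when not an
#'   inhibitor).
#' @param outcomes named character vector of activity outcomes per assay.
#' @param fold required potency ratio.
#' @return Assay name, or `NA_character_` when none qualifies.
#' @export
selectivity <- function(ic50, outcomes, fold = 10) {
  stopifnot(length(ic50) == length(outcomes))
  if (length(ic50) < 2L) return(NA_character_)
  eff_ic50 <- ifelse(outcomes == "inhibitor" & !is.na(ic50), ic50, Inf)
  if (all(!is.finite(eff_ic50))) return(NA_character_)
  best <- which.min(eff_ic50)
  others <- eff_ic50[-best]
  if (all(others / eff_ic50[best] > fold)) names(ic50)[best] else NA_character_
}

#' Luciferase counter-screen flag
#'
#' Flags compounds whose apparent CYP inhibition may be reporter
#' interference: inhibitor outcome in the luciferase channel with IC50 at or
#' below `ic50_cutoff` uM. Luciferase-inactive or weak (IC50 > cutoff)
#' compounds are considered clean.
#'
#' @param outcome luciferase-channel activity outcome(s).
#' @param ic50 luciferase-channel IC50(s), uM.
#' @param ic50_cutoff potency cutoff in uM.
#' @return Logical flag(s); flagged compounds are kept but annotated.
#' @export
luciferase_filter <- function(outcome, ic50, ic50_cutoff = 20) {
  outcome == "inhibitor" & !is.na(ic50) & ic50 <= ic50_cutoff
}

#' Cross-assay compound profiles
#'
#' Assembles per-compound profiles from the per-assay compound-level call
#' tables: outcome and IC50 per assay, potency (IC50 < `potent_cutoff` uM in
#' any assay with an inhibitor call), selectivity, pan-inhibition (inhibitor
#' in all CYP assays), and the luciferase interference flag.
#'
#' @param calls compound-level call table (rows: compound x assay; columns
#'   `compound_id`, `assay_id`, `outcome`, `ic50_uM`) covering the CYP
#'   assays and optionally the `"LUC"` channel.
#' @param assays CYP assay names; default all non-`"LUC"` assays present.
#' @param parent_map optional data.frame (`compound_id`, `parent_id`)
#'   mapping duplicate samples to their parent compound; carried into the
#'   profile for [pan_summary()].
#' @param potent_cutoff potency definition, uM.
#' @param fold selectivity fold, see [selectivity()].
#' @return data.table, one row per sample: `outcome_<assay>`,
#'   `ic50_<assay>`, `potent`, `selective_for`, `pan_inhibitor`,
#'   `luciferase_flag`.
#' @export
compound_profiles <- function(calls, assays = NULL, parent_map = NULL,
                              potent_cutoff = 1, fold = 10) {
  calls <- data.table::as.data.table(calls)
  if (is.null(assays)) assays <- setdiff(unique(calls$assay_id), "LUC")
  wide_o <- data.table::dcast(calls, compound_id ~ assay_id,
                              value.var = c("outcome", "ic50_uM"))
  prof <- wide_o

  ocols <- paste0("outcome_", assays)
  icols <- paste0("ic50_uM_", assays)
  omat <- as.matrix(prof[, ocols, with = FALSE])
  imat <- as.matrix(prof[, icols, with = FALSE])
  inh <- omat == "inhibitor" & !is.na(omat)
  inh_ic50 <- ifelse(inh & !is.na(imat), imat, NA_real_)

  prof[, potent := apply(inh_ic50, 1L, function(v)
    any(is.finite(v) & v < potent_cutoff))]
  prof[, pan_inhibitor := rowSums(inh) == length(assays)]
  prof[, selective_for := vapply(seq_len(.N), function(i)
    selectivity(setNames(imat[i, ], assays), setNames(omat[i, ], assays),
                fold = fold), character(1L))]

  if ("outcome_LUC" %in% names(prof)) {
    prof[, luciferase_flag := luciferase_filter(outcome_LUC, ic50_uM_LUC)]
  } else prof[, luciferase_flag := FALSE]

  if (!is.null(parent_map)) {
    pm <- data.table::as.data.table(parent_map)[, .(compound_id, parent_id)]
    prof <- pm[prof, on = "compound_id"]
    prof[is.na(parent_id), parent_id := compound_id]
  } else prof[, parent_id := compound_id]
  prof[]
}

#' Screen-level pan-activity summary
#'
#' Counts unique compounds inhibiting at least one assay, all assays, and
#' each assay, after collapsing duplicate samples to their parent compound.
#' Duplicate samples merge worst-case: a parent inhibits an assay when any
#' of its samples does (matching "inhibited at least one" semantics).
#' Percentages are relative to the unique-compound count.
#'
#' @param profiles a [compound_profiles()] table.
#' @param assays CYP assay names; default inferred from outcome columns.
#' @return List: `n_unique`, `n_ge1`, `pct_ge1`, `n_all`, `pct_all`,
#'   `per_assay` (named inhibitor counts).
#' @export
pan_summary <- function(profiles, assays = NULL) {
  profiles <- data.table::as.data.table(profiles)
  if (nrow(profiles) == 0L)
    return(list(n_unique = 0L, n_ge1 = 0L, pct_ge1 = 0, n_all = 0L,
                pct_all = 0, per_assay = integer(0)))
  if (is.null(assays))
    assays <- setdiff(sub("^outcome_", "",
                          grep("^outcome_", names(profiles), value = TRUE)),
                      "LUC")
  ocols <- paste0("outcome_", assays)
  inh <- as.matrix(profiles[, ocols, with = FALSE]) == "inhibitor"
  inh[is.na(inh)] <- FALSE
  pid <- if ("parent_id" %in% names(profiles)) profiles$parent_id
         else profiles$compound_id
  merged <- rowsum(inh + 0, pid) > 0  # any sample of the parent inhibits
  n_unique <- nrow(merged)
  n_ge1 <- sum(rowSums(merged) >= 1L)
  n_all <- sum(rowSums(merged) == length(assays))
  list(n_unique = n_unique,
       n_ge1 = n_ge1, pct_ge1 = 100 * n_ge1 / n_unique,
       n_all = n_all, pct_all = 100 * n_all / n_unique,
       per_assay = setNames(as.integer(colSums(merged)), assays))
}
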