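# Plate normalization, DMSO-plate pattern correction, and plate QC.

#' Control statistics of one plate
#'
#' Medians (used by the normalization formula) and means/SDs (used by the
#' Z'-factor) of the control wells. `V_pos` is taken from the positive
#' control wells at the `top_k` highest titration concentrations only, where
#' the control is at full effect; the lower part of the titration spans
#' partial effects and would bias the anchor.
#'
#' @param plate data.table of one plate's wells (needs `role`,
#'   `concentration_M`, `rlu`).
#' @param top_k number of highest control concentrations used for `V_pos`.
#' @return List of class `control_stats`: `v_dmso_median`, `v_pos_median`,
#'   `mu_dmso`, `sigma_dmso`, `mu_pos`, `sigma_pos`, well counts.
#' @export
control_stats <- function(plate, top_k = 4L) {
  dmso <- plate[role == "DMSO", rlu]
  posw <- plate[role == "positive_control"]
  if (length(dmso) < 2L || nrow(posw) < 2L)
    stop("control stats need >= 2 wells per control role", call. = FALSE)
  topc <- sort(unique(posw$concentration_M), decreasing = TRUE)[seq_len(top_k)]
  pos <- posw[concentration_M %in% topc, rlu]
  structure(list(
    v_dmso_median = median(dmso), v_pos_median = median(pos),
    mu_dmso = mean(dmso), sigma_dmso = sd(dmso),
    mu_pos = mean(pos), sigma_pos = sd(pos),
    n_dmso = length(dmso), n_pos = length(pos)),
    class = "control_stats")
}

#' Normalize one plate to signed percent activity
#'
#' Applies `activity = 100 * (V_compound - V_DMSO) / (V_DMSO - V_pos)`:
#' DMSO wells center at 0 and wells at the positive-control level map to
#' -100, so inhibition is negative and activation positive.
#'
#' @param plate data.table of one plate's wells.
#' @param controls a [control_stats()] for this plate; computed from the
#'   plate itself when omitted.
#' @return The plate with an `activity` column (signed percent) added;
#'   attribute `correction_applied` is `FALSE`.
#' @export
normalize_plate <- function(plate, controls = control_stats(plate)) {
  span <- controls$v_dmso_median - controls$v_pos_median
  if (!is.finite(span) || span == 0)
    stop("normalization error: degenerate controls (equal medians) on plate ",
         paste(unique(plate$plate_id), collapse = ","), call. = FALSE)
  out <- data.table::copy(plate)
  out[, activity := 100 * (rlu - controls$v_dmso_median) / span]
  data.table::setattr(out, "correction_applied", FALSE)
  out[]
}

#' Normalize every plate of a screen
#'
#' Per-plate [normalize_plate()] using each plate's own control wells.
#'
#' @param plates long-format wells of one or more plates.
#' @param top_k see [control_stats()].
#' @return The wells with an `activity` column.
#' @export
normalize_screen <- function(plates, top_k = 4L) {
  out <- plates[, {
    st <- control_stats(.SD, top_k = top_k)
    span <- st$v_dmso_median - st$v_pos_median
    if (!is.finite(span) || span == 0)
      stop("normalization error: degenerate controls (equal medians) on plate ",
           plate_id[1L], call. = FALSE)
    c(.SD, list(activity = 100 * (rlu - st$v_dmso_median) / span))
  }, by = plate_id]
  data.table::setcolorder(out, names(plates))
  out[]
}

# robust row+column decomposition of a plate surface with NAs allowed;
# marginals with no data at all come back NA (to be filled by smoothing)
polish_surface <- function(M, n_iter = 4L) {
  row_eff <- rep(0, nrow(M)); col_eff <- rep(0, ncol(M))
  R <- M
  for (it in seq_len(n_iter)) {
    re <- apply(R, 1L, median, na.rm = TRUE); re[is.na(re)] <- 0
    row_eff <- row_eff + re; R <- sweep(R, 1L, re)
    ce <- apply(R, 2L, median, na.rm = TRUE); ce[is.na(ce)] <- 0
    col_eff <- col_eff + ce; R <- sweep(R, 2L, ce)
  }
  row_eff[rowSums(!is.na(M)) == 0L] <- NA_real_
  col_eff[colSums(!is.na(M)) == 0L] <- NA_real_
  list(row = row_eff, col = col_eff, residual = R)
}

# loess-smooth a marginal effect profile, predicting (and extrapolating to
# positions without data, e.g. the positive-control columns) over all
# indices. The first and last observed positions keep their raw estimates:
# plate-edge effects are real, step-like, and would be flattened by the
# smoother, while the raw marginals there already average ~45 wells.
smooth_effect <- function(eff, span = 0.6) {
  idx <- seq_along(eff)
  ok <- is.finite(eff)
  if (sum(ok) < 8L) {
    out <- ifelse(ok, eff, 0)
    return(out)
  }
  d <- data.frame(i = idx[ok], e = eff[ok])
  if (sd(d$e) < 1e-12) return(rep(d$e[1], length(eff)))
  fit <- loess(e ~ i, data = d, span = span, degree = 2,
               family = "symmetric", surface = "direct")
  out <- predict(fit, newdata = data.frame(i = idx))
  ends <- range(idx[ok])
  out[ends] <- eff[ends]
  out
}

#' Estimate the spatial background pattern from DMSO-only plates
#'
#' The per-well median normalized activity across the supplied DMSO-only
#' plates is decomposed by median polish into row and column effects, each
#' marginal profile is loess-smoothed, and the rebuilt separable surface is
#' recentered to zero plate-wide median. Positive-control columns (where no
#' DMSO signal exists) are filled by the smoothed marginals. Smoothing
#' suppresses well noise from the (few) DMSO plates so the surface captures
#' only the systematic spatial trend.
#'
#' @param dmso_plates normalized wells of one or more DMSO-only plates
#'   (rows with role `"DMSO"` are used).
#' @param span loess span for the marginal profiles.
#' @return 32 x 48 matrix of class `pattern_surface` (signed percent), zero
#'   plate-wide median. `NULL`, with a warning, when no DMSO wells are
#'   supplied (correction disabled).
#' @export
estimate_pattern <- function(dmso_plates, span = 0.6) {
  dw <- dmso_plates[role == "DMSO" & is.finite(activity)]
  if (nrow(dw) == 0L) {
    warning("no DMSO-only plates supplied; pattern correction disabled")
    return(NULL)
  }
  M <- matrix(NA_real_, PLATE_ROWS, PLATE_COLS)
  med <- dw[, .(m = median(activity)), by = .(row, col)]
  M[cbind(med$row, med$col)] <- med$m
  p <- polish_surface(M)
  surf <- outer(smooth_effect(p$row, span), rep(1, PLATE_COLS)) +
    outer(rep(1, PLATE_ROWS), smooth_effect(p$col, span))
  surf <- surf - median(surf)  # zero plate-wide median
  structure(surf, class = c("pattern_surface", "matrix"))
}

#' Apply a pattern correction surface to a normalized plate
#'
#' Subtracts the surface well-wise, then recenters the plate so its median
#' activity is exactly preserved.
#'
#' @param plate normalized wells of one plate (or several sharing the
#'   surface).
#' @param surface an [estimate_pattern()] surface; `NULL` leaves the plate
#'   untouched.
#' @return Corrected wells; attribute `correction_applied` is `TRUE` when a
#'   surface was applied.
#' @export
correct_plate <- function(plate, surface) {
  out <- data.table::copy(plate)
  if (is.null(surface)) {
    data.table::setattr(out, "correction_applied", FALSE)
    return(out[])
  }
  out[, activity := {
    m0 <- median(activity)
    a <- activity - surface[cbind(row, col)]
    a + (m0 - median(a))
  }, by = plate_id]
  data.table::setattr(out, "correction_applied", TRUE)
  out[]
}

#' Pattern-correct a whole screen run by run
#'
#' For each assay x run, estimates the background surface from that run's
#' DMSO-only plates and applies it to the run's compound plates.
#'
#' @param norm normalized wells of a whole screen ([normalize_screen()]).
#' @param span see [estimate_pattern()].
#' @return List: `plates` (corrected compound-plate wells) and `surfaces`
#'   (named list of per-run surfaces, `"<assay>|r<run>"`).
#' @export
correct_screen <- function(norm, span = 0.6) {
  surfaces <- list()
  out <- vector("list", 0L)
  for (key in split(seq_len(nrow(norm)), norm[, paste0(assay_id, "|r", run_id)])) {
    sub <- norm[key]
    tag <- paste0(sub$assay_id[1L], "|r", sub$run_id[1L])
    surf <- estimate_pattern(sub[plate_type == "dmso"], span = span)
    surfaces[[tag]] <- surf
    out[[tag]] <- correct_plate(sub[plate_type == "compound"], surf)
  }
  list(plates = data.table::rbindlist(out, use.names = TRUE),
       surfaces = surfaces)
}

#' Plate quality-control statistics
#'
#' Signal-to-background, coefficient of variation and Z'-factor from the
#' control wells: `S/B = mu_DMSO / mu_pos`, `CV = 100 * sigma_DMSO /
#' mu_DMSO`, `Z' = 1 - 3 (sigma_pos + sigma_DMSO) / |mu_DMSO - mu_pos|`.
#' A plate passes when S/B > 2, CV < 10% and Z' > 0.5.
#'
#' @param plate one plate's wells, or a [control_stats()] object.
#' @param sb_min,cv_max,zprime_min pass thresholds.
#' @return List of class `qc_metrics`: `s_over_b`, `cv_percent`, `z_prime`,
#'   `pass`.
#' @export
compute_qc <- function(plate, sb_min = 2, cv_max = 10, zprime_min = 0.5) {
  st <- if (inherits(plate, "control_stats")) plate else control_stats(plate)
  if (st$mu_pos == 0) stop("QC error: zero positive-control mean", call. = FALSE)
  sb <- st$mu_dmso / st$mu_pos
  cv <- 100 * st$sigma_dmso / st$mu_dmso
  zp <- 1 - 3 * (st$sigma_pos + st$sigma_dmso) / abs(st$mu_dmso - st$mu_pos)
  structure(list(s_over_b = sb, cv_percent = cv, z_prime = zp,
                 pass = (sb > sb_min && cv < cv_max && zp > zprime_min)),
            class = "qc_metrics")
}

#' QC report for every plate of a screen
#'
#' @param plates raw or normalized wells of one or more plates.
#' @param ... thresholds passed to [compute_qc()].
#' @return data.table, one row per plate: `plate_id`, `assay_id`, `run_id`,
#'   `s_over_b`, `cv_percent`, `z_prime`, `pass`.
#' @export
qc_screen <- function(plates, ...) {
  plates[, {
    q <- compute_qc(.SD, ...)
    list(assay_id = assay_id[1L], run_id = run_id[1L],
         s_over_b = q$s_over_b, cv_percent = q$cv_percent,
         z_prime = q$z_prime, pass = q$pass)
  }, by = plate_id]
}

#' Pivot corrected plates into concentration-response series
#'
#' @param plates normalized (ideally pattern-corrected) compound-plate wells.
#' @return data.table of test wells with a compound, ordered by
#'   compound/assay/run/concentration: `compound_id`, `assay_id`, `run_id`,
#'   `concentration_M`, `activity`.
#' @export
cr_series <- function(plates) {
  s <- plates[role == "test" & !is.na(compound_id),
              .(compound_id, assay_id, run_id, concentration_M, activity)]
  data.table::setorder(s, compound_id, assay_id, run_id, concentration_M)
  s[]
}
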