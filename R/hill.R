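# Four-parameter Hill model and multi-start least-squares fitting.

#' Four-parameter Hill response
#'
#' `baseline + efficacy / (1 + (ac50/conc)^hill)`: monotone in `conc`, with
#' asymptotes `baseline` (zero dose) and `baseline + efficacy` (saturating
#' dose). Negative efficacy describes inhibition, positive efficacy
#' activation; `ac50` is the midpoint (the IC50 for inhibition curves).
#'
#' @param conc concentration(s), molar, > 0.
#' @param baseline zero-dose asymptote (signed percent).
#' @param efficacy asymptote difference (signed percent).
#' @param ac50 midpoint concentration, molar, > 0.
#' @param hill Hill slope, > 0.
#' @return Signed percent activity, same length as `conc`.
#' @examples
#' hill_response(1e-6, 0, -100, 1e-6, 1)   # midpoint: -50
#' hill_response(1e-7, 0, -100, 1e-6, 1)   # -100/11
#' @export
hill_response <- function(conc, baseline, efficacy, ac50, hill) {
  if (any(conc <= 0) || ac50 <= 0 || hill <= 0)
    stop("hill_response: conc, ac50 and hill must be positive", call. = FALSE)
  baseline + efficacy / (1 + (ac50 / conc)^hill)
}

# constrained least squares for the linear parameters (baseline, efficacy)
# given the saturation fractions f = 1/(1+(ac50/conc)^hill); box constraints
# |baseline| <= bmax, |efficacy| <= emax.
solve_linear <- function(f, y, bmax, emax) {
  n <- length(y)
  sf <- sum(f); sff <- sum(f * f); sy <- sum(y); sfy <- sum(f * y)
  det <- n * sff - sf * sf
  cand <- list()
  if (det > 1e-12 * n * max(sff, 1)) {
    b <- (sff * sy - sf * sfy) / det
    e <- (n * sfy - sf * sy) / det
    if (abs(b) <= bmax && abs(e) <= emax) cand[[length(cand) + 1L]] <- c(b, e)
  }
  for (bfix in c(-bmax, bmax)) {  # baseline at a bound
    e <- if (sff > 0) (sfy - bfix * sf) / sff else 0
    cand[[length(cand) + 1L]] <- c(bfix, max(-emax, min(emax, e)))
  }
  for (efix in c(-emax, emax)) {  # efficacy at a bound
    b <- (sy - efix * sf) / n
    cand[[length(cand) + 1L]] <- c(max(-bmax, min(bmax, b)), efix)
  }
  b <- max(-bmax, min(bmax, sy / n))  # interior baseline, free efficacy
  e <- if (sff > 0) (sfy - b * sf) / sff else 0
  cand[[length(cand) + 1L]] <- c(b, max(-emax, min(emax, e)))
  best <- NULL; brss <- Inf
  for (p in cand) {
    r <- y - p[1] - p[2] * f
    rss <- sum(r * r)
    if (rss < brss) { brss <- rss; best <- p }
  }
  list(baseline = best[1], efficacy = best[2], rss = brss)
}

#' Fit the four-parameter Hill model to a concentration-response series
#'
#' Profiled least squares: for candidate `(log AC50, log hill)` the linear
#' parameters (baseline, efficacy) are solved in closed form under their box
#' constraints; a log-spaced AC50 x hill start grid is scanned and the best
#' starts are polished with L-BFGS-B. AC50 is confined to one decade beyond
#' the tested range, `hill` to `[0.3, 8]`, `|efficacy| <= 150`,
#' `|baseline| <= 30` (standard qHTS practice). A fit is `converged` only
#' when it improves on the best flat (constant) model; flat series come back
#' with `efficacy = 0` and `converged = FALSE`.
#'
#' @param conc concentrations (molar), strictly increasing, length >= 5.
#' @param activity signed percent activities, same length.
#' @param hill_bounds,efficacy_max,baseline_max parameter box.
#' @param ac50_bounds AC50 box (molar); default
#'   `c(min(conc)/10, max(conc)*10)`.
#' @param n_start_ac50 number of log-spaced AC50 grid starts.
#' @param start_hills hill values scanned at each AC50 start.
#' @param n_polish how many best grid starts are polished by L-BFGS-B.
#' @return List of class `hill_fit`: `ac50`, `efficacy`, `hill`, `baseline`,
#'   `r2`, `rss`, `converged`, `n`.
#' @export
fit_hill <- function(conc, activity,
                     ac50_bounds = NULL,
                     hill_bounds = c(0.3, 8),
                     efficacy_max = 150,
                     baseline_max = 30,
                     n_start_ac50 = 14L,
                     start_hills = c(0.4, 0.8, 1.5, 3, 8),
                     n_polish = 4L) {
  if (length(conc) < 5L)
    stop("fit error: need >= 5 concentration points", call. = FALSE)
  if (length(activity) != length(conc) || !all(is.finite(conc)) ||
      !all(is.finite(activity)) || any(conc <= 0))
    stop("fit error: conc/activity must be finite, conc positive", call. = FALSE)
  if (is.null(ac50_bounds)) ac50_bounds <- c(min(conc) / 10, max(conc) * 10)

  lc <- log(conc)
  la_lim <- log(ac50_bounds); lh_lim <- log(hill_bounds)

  rss_at <- function(la, lh) {
    f <- 1 / (1 + exp(exp(lh) * (la - lc)))
    solve_linear(f, activity, baseline_max, efficacy_max)
  }
  obj <- function(p) rss_at(p[1], p[2])$rss

  # flat (constant) reference model
  b0 <- max(-baseline_max, min(baseline_max, mean(activity)))
  rss_flat <- sum((activity - b0)^2)

  # start grid
  las <- seq(la_lim[1], la_lim[2], length.out = n_start_ac50)
  lhs <- log(pmin(pmax(start_hills, hill_bounds[1]), hill_bounds[2]))
  grid <- as.matrix(expand.grid(la = las, lh = lhs))
  grss <- apply(grid, 1L, function(p) rss_at(p[1], p[2])$rss)
  ord <- order(grss)[seq_len(min(n_polish, nrow(grid)))]

  best <- list(rss = Inf, la = NA_real_, lh = NA_real_)
  for (k in ord) {
    op <- tryCatch(
      optim(grid[k, ], obj, method = "L-BFGS-B",
            lower = c(la_lim[1], lh_lim[1]), upper = c(la_lim[2], lh_lim[2]),
            control = list(factr = 1e7, maxit = 200L)),
      error = function(e) NULL)
    if (!is.null(op) && op$value < best$rss)
      best <- list(rss = op$value, la = op$par[1], lh = op$par[2])
  }
  if (!is.finite(best$rss)) {  # fall back to the raw grid optimum
    k <- ord[1L]
    best <- list(rss = grss[k], la = grid[k, 1], lh = grid[k, 2])
  }

  lin <- rss_at(best$la, best$lh)
  tss <- sum((activity - mean(activity))^2)
  converged <- lin$rss < rss_flat * (1 - 1e-9) && lin$efficacy != 0
  if (!converged) {
    fit <- list(ac50 = NA_real_, efficacy = 0, hill = NA_real_,
                baseline = b0, r2 = 0, rss = rss_flat, converged = FALSE,
                n = length(conc))
  } else {
    fit <- list(ac50 = unname(exp(best$la)), efficacy = lin$efficacy,
                hill = unname(exp(best$lh)), baseline = lin$baseline,
                r2 = if (tss > 0) max(0, 1 - lin$rss / tss) else 0,
                rss = lin$rss, converged = TRUE, n = length(conc))
  }
  structure(fit, class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<hill_fit> AC50 %.3g uM, efficacy %.1f, hill %.2f, baseline %.1f, r2 %.3f\n",
                x$ac50 * 1e6, x$efficacy, x$hill, x$baseline, x$r2))
  else cat("<hill_fit> not converged (no improvement over flat model)\n")
  invisible(x)
}

#' Fit every concentration-response series of a screen
#'
#' @param series long table from [cr_series()] (`compound_id`, `assay_id`,
#'   `run_id`, `concentration_M`, `activity`).
#' @param ... passed to [fit_hill()].
#' @return data.table, one row per compound x assay x run: fitted
#'   parameters (`ac50_uM` in micromolar), `r2`, `converged`, plus
#'   `last_activity` (response at the top tested concentration, used by the
#'   curve classifier's single-point rule).
#' @export
fit_hill_series <- function(series, ...) {
  data.table::setorder(series, compound_id, assay_id, run_id, concentration_M)
  series[, {
    ft <- fit_hill(concentration_M, activity, ...)
    list(ac50_uM = ft$ac50 * 1e6, efficacy = ft$efficacy, hill = ft$hill,
         baseline = ft$baseline, r2 = ft$r2, rss = ft$rss,
         converged = ft$converged,
         last_activity = activity[.N])
  }, by = .(compound_id, assay_id, run_id)]
}
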