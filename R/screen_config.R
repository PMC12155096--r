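#' Configuration of a synthetic qHTS screen
#'
#' Collects every knob of the synthetic screen generator. The defaults are
#' the study conditions emulated throughout this package: 1536-well plates
#' (32 rows x 48 columns) with control wells in columns 1--4, test compounds
#' in columns 5--48 at 15-point titrations from 0.7 nM to 58 uM, three
#' independent runs with compounds re-randomized to different wells, a
#' class-structured compound library in which a subset of structural classes
#' is enriched for inhibitors, multiplicative plate noise, an additive smooth
#' spatial background pattern, and a luciferase counter-screen channel with
#' reporter-interfering compounds.
#'
#' @param n_compounds total number of library samples (including duplicate
#'   samples of the same parent compound, see `dup_rate`).
#' @param n_classes number of structural classes the library is partitioned
#'   into (equal-sized blocks).
#' @param frac_enriched_classes fraction of classes enriched for inhibitors.
#' @param p_active_enriched probability that a member of an enriched class is
#'   an inhibitor.
#' @param p_active_background inhibitor probability in all other classes.
#' @param conc_min,conc_max lowest/highest test concentration (molar).
#' @param n_conc number of titration points (geometric series, endpoints
#'   included).
#' @param n_runs number of independent runs (library copies).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   well noise (fraction, e.g. 0.03).
#' @param pattern_amplitude amplitude of the additive spatial background
#'   pattern, as a fraction of the DMSO signal.
#' @param luciferase_interferer_rate probability that a compound inhibits the
#'   firefly luciferase reporter itself.
#' @param seed integer seed; identical configurations give bit-identical
#'   screens.
#' @param assays character vector of assay channel names.
#' @param include_luciferase add a `"LUC"` counter-screen channel simulated
#'   with the same plate design.
#' @param p_assay_hit for an inhibitor, the independent probability that each
#'   assay channel is affected (at least one is guaranteed).
#' @param p_activator probability that a non-inhibitor shows positive
#'   cooperativity (signal increase) in one randomly chosen assay.
#' @param dup_rate fraction of samples that are duplicate preparations of an
#'   earlier compound (same parent id, fingerprint and truth).
#' @param fp_bits fingerprint length in bits (multiple of 4).
#' @param fp_density probability that an archetype fingerprint bit is set.
#' @param fp_flip per-bit flip probability of class members relative to their
#'   class archetype.
#' @param efficacy_range range (percent, negative) of true maximal inhibition.
#' @param activator_efficacy_range range (percent, positive) of true maximal
#'   activation.
#' @param hill_range range of true Hill slopes.
#' @param baseline_rlu DMSO (uninhibited) plate signal in RLU.
#' @param background_frac fully-inhibited signal as a fraction of
#'   `baseline_rlu`; sets the assay window (S/B = 1/background_frac).
#' @param n_dmso_plates DMSO-only plates emitted per run for pattern
#'   estimation.
#' @param max_plates cap on compound plates per concentration level; a
#'   library needing more raises a sizing error.
#' @param control_ac50,control_hill,control_n_conc positive-control titration
#'   parameters: Hill midpoint (molar), slope, and number of titration points
#'   in the control columns.
#'
#' @return An object of class `screen_config` (a validated list).
#' @examples
#' cfg <- screen_config(n_compounds = 200, n_classes = 5, seed = 1)
#' range(concentration_series(cfg)) * 1e6  # 7e-4 .. 58 uM
#' @export
screen_config <- function(n_compounds = 1000,
                          n_classes = 10,
                          frac_enriched_classes = 0.3,
                          p_active_enriched = 0.8,
                          p_active_background = 0.1,
                          conc_min = 0.7e-9,
                          conc_max = 58e-6,
                          n_conc = 15,
                          n_runs = 3,
                          noise_cv = 0.03,
                          pattern_amplitude = 0.05,
                          luciferase_interferer_rate = 0.09,
                          seed = 1L,
                          assays = c("CYP1A2", "CYP2C9", "CYP2C19",
                                     "CYP2D6", "CYP3A4"),
                          include_luciferase = TRUE,
                          p_assay_hit = 0.7,
                          p_activator = 0.02,
                          dup_rate = 0.05,
                          fp_bits = 256,
                          fp_density = 0.3,
                          fp_flip = 0.05,
                          efficacy_range = c(-100, -80),
                          activator_efficacy_range = c(40, 100),
                          hill_range = c(0.8, 2),
                          baseline_rlu = 1e4,
                          background_frac = 0.05,
                          n_dmso_plates = 1,
                          max_plates = 8,
                          control_ac50 = 2e-8,
                          control_hill = 2,
                          control_n_conc = 16) {
  cfg <- as.list(environment())

  counts <- c("n_compounds", "n_classes", "n_conc", "n_runs", "fp_bits",
              "n_dmso_plates", "max_plates", "control_n_conc")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != round(v))
      stop("configuration error: '", nm, "' must be a positive integer", call. = FALSE)
    cfg[[nm]] <- as.integer(v)
  }
  probs <- c("frac_enriched_classes", "p_active_enriched", "p_active_background",
             "luciferase_interferer_rate", "p_assay_hit", "p_activator",
             "dup_rate", "fp_density", "fp_flip")
  for (nm in probs) {
    v <- cfg[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("configuration error: '", nm, "' must be a probability in [0, 1]", call. = FALSE)
  }
  if (!(cfg$conc_min > 0 && cfg$conc_min < cfg$conc_max))
    stop("configuration error: need 0 < conc_min < conc_max", call. = FALSE)
  if (cfg$n_conc < 2L)
    stop("configuration error: n_conc must be >= 2", call. = FALSE)
  if (cfg$fp_bits %% 4L != 0L)
    stop("configuration error: fp_bits must be a multiple of 4", call. = FALSE)
  if (!(cfg$noise_cv >= 0 && cfg$pattern_amplitude >= 0))
    stop("configuration error: noise_cv and pattern_amplitude must be >= 0", call. = FALSE)
  if (!(cfg$background_frac > 0 && cfg$background_frac < 1))
    stop("configuration error: background_frac must be in (0, 1)", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)

  structure(cfg, class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat("<screen_config>\n")
  cat(sprintf("  %d samples, %d classes (%d enriched), %d runs\n",
              x$n_compounds, x$n_classes,
              round(x$frac_enriched_classes * x$n_classes), x$n_runs))
  cat(sprintf("  %d-point titration %.3g nM .. %.3g uM\n",
              x$n_conc, x$conc_min * 1e9, x$conc_max * 1e6))
  cat(sprintf("  assays: %s%s\n", paste(x$assays, collapse = ", "),
              if (x$include_luciferase) " + LUC" else ""))
  cat(sprintf("  noise CV %.1f%%, pattern amplitude %.1f%%, seed %d\n",
              100 * x$noise_cv, 100 * x$pattern_amplitude, x$seed))
  invisible(x)
}

#' Test concentration series
#'
#' Geometric (log-equispaced) titration from `conc_min` to `conc_max`
#' inclusive, the dosing scheme of the emulated screen (15 points from
#' 0.7 nM to 58 uM by default; step ratio about 2.246).
#'
#' @param config a [screen_config()].
#' @return Numeric vector of `n_conc` molar concentrations, increasing.
#' @export
concentration_series <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  cc <- exp(seq(log(config$conc_min), log(config$conc_max),
                length.out = config$n_conc))
  cc[1] <- config$conc_min
  cc[config$n_conc] <- config$conc_max
  cc
}

#' Positive-control titration concentrations
#'
#' The control columns carry a longer titration (16 points by default) over
#' the same concentration span as the test compounds.
#'
#' @param config a [screen_config()].
#' @return Numeric vector of `control_n_conc` molar concentrations, increasing.
#' @export
control_concentrations <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  cc <- exp(seq(log(config$conc_min), log(config$conc_max),
                length.out = config$control_n_conc))
  cc[1] <- config$conc_min
  cc[length(cc)] <- config$conc_max
  cc
}
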