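# Synthetic screen generator: compound library with ground truth, and raw
# 1536-well plates following the emulated study design.

PLATE_ROWS <- 32L
PLATE_COLS <- 48L
TEST_COLS <- 5L:48L
POS_COLS <- 1L:2L
DMSO_COLS <- 3L:4L
TEST_CAPACITY <- length(TEST_COLS) * PLATE_ROWS  # 1408 test wells per plate

#' Generate a compound library with per-assay ground truth
#'
#' Partitions `n_compounds` samples into equal-sized structural classes, each
#' with an archetype fingerprint whose members differ by independent bit
#' flips. The first `round(frac_enriched_classes * n_classes)` classes are
#' enriched: their members are inhibitors with probability
#' `p_active_enriched`, members of other classes with `p_active_background`.
#' An inhibitor affects each assay channel independently with probability
#' `p_assay_hit` (at least one guaranteed); per affected assay the true AC50
#' is log-uniform on `[3 * conc_min, conc_max / 3]`, the true efficacy is
#' negative (inhibition as fractional signal loss) and the Hill slope is
#' drawn from `hill_range`. Non-inhibitors may be activators (positive
#' efficacy, one random assay) at rate `p_activator`. Independently of CYP
#' activity, compounds interfere with the luciferase reporter at rate
#' `luciferase_interferer_rate`, giving an inhibitory response in the `"LUC"`
#' channel with its own AC50. A fraction `dup_rate` of samples are duplicate
#' preparations of earlier compounds (same `parent_id`, fingerprint and
#' truth).
#'
#' @param config a [screen_config()].
#' @return A list of class `cyp_library`:
#' \describe{
#'   \item{compounds}{data.table: `compound_id`, `parent_id`, `class_label`,
#'     `enriched`, `fingerprint` (hex).}
#'   \item{truth}{data.table, one row per sample x channel: `compound_id`,
#'     `assay_id`, `activity_type` (`inactive`/`inhibitor`/`activator`),
#'     `true_ac50` (molar, NA when inactive), `true_efficacy` (signed
#'     percent, 0 when inactive), `true_hill`.}
#'   \item{config}{the generating configuration.}
#' }
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  set.seed(config$seed)

  n_dup <- as.integer(round(config$dup_rate * config$n_compounds))
  n_uni <- config$n_compounds - n_dup
  if (n_uni < config$n_classes)
    stop("configuration error: fewer unique compounds than classes", call. = FALSE)

  n_enr <- as.integer(round(config$frac_enriched_classes * config$n_classes))
  class_labels <- sprintf("CL%02d", seq_len(config$n_classes))
  enriched_classes <- class_labels[seq_len(n_enr)]
  cls <- sort(rep_len(class_labels, n_uni))

  # archetype fingerprints and member bit flips
  arch <- matrix(rbinom(config$n_classes * config$fp_bits, 1L, config$fp_density),
                 nrow = config$n_classes,
                 dimnames = list(class_labels, NULL))
  flips <- matrix(rbinom(n_uni * config$fp_bits, 1L, config$fp_flip), nrow = n_uni)
  fp <- (arch[cls, , drop = FALSE] + flips) %% 2L

  id <- sprintf("C%05d", seq_len(n_uni))
  is_enr <- cls %in% enriched_classes
  p_act <- ifelse(is_enr, config$p_active_enriched, config$p_active_background)
  inhibitor <- runif(n_uni) < p_act

  n_assay <- length(config$assays)
  draw_ac50 <- function(n) {
    lo <- log10(3 * config$conc_min); hi <- log10(config$conc_max / 3)
    10^runif(n, lo, hi)
  }
  truth <- vector("list", n_uni)
  for (i in seq_len(n_uni)) {
    type <- rep("inactive", n_assay)
    if (inhibitor[i]) {
      hit <- runif(n_assay) < config$p_assay_hit
      if (!any(hit)) hit[sample.int(n_assay, 1L)] <- TRUE
      type[hit] <- "inhibitor"
    } else if (runif(1) < config$p_activator) {
      type[sample.int(n_assay, 1L)] <- "activator"
    }
    eff <- numeric(n_assay); a50 <- rep(NA_real_, n_assay); hl <- rep(NA_real_, n_assay)
    act <- type != "inactive"
    if (any(act)) {
      k <- sum(act)
      eff[act] <- ifelse(type[act] == "inhibitor",
                         runif(k, config$efficacy_range[1], config$efficacy_range[2]),
                         runif(k, config$activator_efficacy_range[1],
                               config$activator_efficacy_range[2]))
      a50[act] <- draw_ac50(k)
      hl[act] <- runif(k, config$hill_range[1], config$hill_range[2])
    }
    # luciferase interference channel, independent of CYP truth
    luc_type <- "inactive"; luc_eff <- 0; luc_a50 <- NA_real_; luc_hl <- NA_real_
    if (config$include_luciferase && runif(1) < config$luciferase_interferer_rate) {
      luc_type <- "inhibitor"
      luc_eff <- runif(1, config$efficacy_range[1], config$efficacy_range[2])
      luc_a50 <- draw_ac50(1L)
      luc_hl <- runif(1, config$hill_range[1], config$hill_range[2])
    }
    truth[[i]] <- data.table::data.table(
      compound_id = id[i],
      assay_id = c(config$assays, if (config$include_luciferase) "LUC"),
      activity_type = c(type, if (config$include_luciferase) luc_type),
      true_ac50 = c(a50, if (config$include_luciferase) luc_a50),
      true_efficacy = c(eff, if (config$include_luciferase) luc_eff),
      true_hill = c(hl, if (config$include_luciferase) luc_hl))
  }
  truth <- data.table::rbindlist(truth)

  compounds <- data.table::data.table(
    compound_id = id, parent_id = id, class_label = cls,
    enriched = is_enr, fingerprint = fp_pack(fp))

  if (n_dup > 0L) {
    src <- sample.int(n_uni, n_dup, replace = TRUE)
    dup_id <- sprintf("C%05d", n_uni + seq_len(n_dup))
    dup_cmp <- compounds[src]
    dup_cmp[, `:=`(compound_id = dup_id, parent_id = id[src])]
    dup_truth <- truth[data.table::data.table(compound_id = id[src]),
                       on = "compound_id", allow.cartesian = TRUE]
    # map each duplicated block to its new sample id
    dup_truth[, compound_id := rep(dup_id,
      each = n_assay + as.integer(config$include_luciferase))]
    compounds <- data.table::rbindlist(list(compounds, dup_cmp))
    truth <- data.table::rbindlist(list(truth, dup_truth))
  }
  data.table::setkey(truth, compound_id, assay_id)

  structure(list(compounds = compounds, truth = truth, config = config),
            class = "cyp_library")
}

#' @export
print.cyp_library <- function(x, ...) {
  n_act <- x$truth[activity_type == "inhibitor", data.table::uniqueN(compound_id)]
  cat(sprintf("<cyp_library> %d samples (%d unique), %d classes; %d samples inhibit >= 1 channel\n",
              nrow(x$compounds), data.table::uniqueN(x$compounds$parent_id),
              data.table::uniqueN(x$compounds$class_label), n_act))
  invisible(x)
}

# true signed-percent activity of the positive control at a concentration;
# pinned to exactly -100 once the dose saturates (>= 100x AC50) so the
# control anchors the normalization at full effect.
control_activity <- function(conc, config) {
  act <- -100 / (1 + (config$control_ac50 / conc)^config$control_hill)
  act[conc >= 100 * config$control_ac50] <- -100
  act
}

# smooth spatial background for one run: separable linear row/column
# gradients plus an optional edge ring, scaled to max |g| = 1.
make_pattern <- function() {
  a_r <- runif(1, -1, 1); a_c <- runif(1, -1, 1); a_e <- runif(1, 0, 0.5)
  u_r <- 2 * (seq_len(PLATE_ROWS) - (PLATE_ROWS + 1) / 2) / (PLATE_ROWS - 1)
  u_c <- 2 * (seq_len(PLATE_COLS) - (PLATE_COLS + 1) / 2) / (PLATE_COLS - 1)
  g <- outer(a_r * u_r, rep(1, PLATE_COLS)) + outer(rep(1, PLATE_ROWS), a_c * u_c)
  edge <- matrix(0, PLATE_ROWS, PLATE_COLS)
  edge[c(1L, PLATE_ROWS), ] <- 1; edge[, c(1L, PLATE_COLS)] <- 1
  g <- g + a_e * edge
  m <- max(abs(g))
  if (m > 0) g <- g / m
  g
}

# static control-column layout shared by every plate of a config
control_layout <- function(config) {
  cc <- control_concentrations(config)
  nrep <- ceiling(PLATE_ROWS / config$control_n_conc)
  tidx <- rep_len(rep(seq_len(config$control_n_conc), nrep), PLATE_ROWS)
  pos <- data.table::CJ(row = seq_len(PLATE_ROWS), col = POS_COLS)
  pos[, `:=`(role = "positive_control", compound_id = NA_character_,
             concentration_M = cc[tidx[row]])]
  dms <- data.table::CJ(row = seq_len(PLATE_ROWS), col = DMSO_COLS)
  dms[, `:=`(role = "DMSO", compound_id = NA_character_,
             concentration_M = NA_real_)]
  data.table::rbindlist(list(pos, dms), use.names = TRUE)
}

#' Simulate raw plates for all runs and assay channels
#'
#' Produces the raw-RLU plate stack of a synthetic screen. The true well
#' signal is `bg + (B - bg) * (1 + activity/100)` where `B` is the DMSO
#' baseline and `bg = background_frac * B` the fully-inhibited background
#' (so activity 0 gives `B` and activity -100 gives `bg`); signed activity
#' follows the compound's per-channel Hill truth. Each well's signal is
#' multiplied by lognormal noise with CV `noise_cv`, then a smooth additive
#' spatial pattern of amplitude `pattern_amplitude * B` (fixed within a run,
#' redrawn per assay x run) is added. Each run re-randomizes the compound to
#' well assignment; `n_dmso_plates` DMSO-only plates (control columns plus an
#' all-DMSO test area) are emitted per run for pattern estimation.
#'
#' @param library a [generate_library()] result.
#' @param config the matching [screen_config()]; defaults to the one stored
#'   in `library`.
#' @param assays channels to simulate; default all configured CYP channels
#'   plus `"LUC"` when enabled.
#' @return A data.table with one row per well: `assay_id`, `run_id`,
#'   `plate_id`, `plate_type` (`"compound"`/`"dmso"`), `conc_index`, `row`,
#'   `col`, `role` (`DMSO`, `positive_control`, `test`, `empty`),
#'   `compound_id`, `concentration_M`, `rlu`. The true per-run spatial
#'   patterns (fraction of `B`, 32 x 48) are attached as attribute
#'   `true_pattern`, named `"<assay>|r<run>"`.
#' @export
simulate_screen <- function(library, config = library$config, assays = NULL) {
  stopifnot(inherits(library, "cyp_library"), inherits(config, "screen_config"))
  if (nrow(library$compounds) == 0L) stop("library is empty", call. = FALSE)
  if (is.null(assays))
    assays <- c(config$assays, if (config$include_luciferase) "LUC")

  n_lib <- nrow(library$compounds)
  n_plates <- as.integer(ceiling(n_lib / TEST_CAPACITY))
  if (n_plates > config$max_plates)
    stop(sprintf("sizing error: %d compounds need %d plates per concentration (max_plates = %d)",
                 n_lib, n_plates, config$max_plates), call. = FALSE)

  set.seed(config$seed + 1L)
  conc <- concentration_series(config)
  ctrl <- control_layout(config)
  ctrl_act <- ifelse(ctrl$role == "positive_control",
                     control_activity(ctrl$concentration_M, config), 0)
  B <- config$baseline_rlu
  bg <- config$background_frac * B
  cv <- config$noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2

  noisy <- function(signal) {
    if (cv == 0) return(signal)
    signal * rlnorm(length(signal), meanlog, sdlog)
  }
  signal_of <- function(act) bg + (B - bg) * (1 + act / 100)

  patterns <- list()
  out <- vector("list", length(assays) * config$n_runs)
  oi <- 0L
  for (assay in assays) {
    truth_a <- library$truth[.(library$compounds$compound_id, assay)]
    for (run in seq_len(config$n_runs)) {
      g <- make_pattern()
      patterns[[paste0(assay, "|r", run)]] <- g * config$pattern_amplitude
      pat_rlu <- g * config$pattern_amplitude * B

      perm <- sample.int(n_lib)
      pos <- integer(n_lib); pos[perm] <- seq_len(n_lib)  # sample -> position
      plate_of <- (pos - 1L) %/% TEST_CAPACITY + 1L
      w <- (pos - 1L) %% TEST_CAPACITY
      col_of <- TEST_COLS[w %/% PLATE_ROWS + 1L]
      row_of <- w %% PLATE_ROWS + 1L

      # test wells: every sample at every concentration level
      test <- data.table::data.table(
        compound_id = rep(library$compounds$compound_id, times = config$n_conc),
        conc_index = rep(seq_len(config$n_conc), each = n_lib),
        plate = rep(plate_of, times = config$n_conc),
        row = rep(row_of, times = config$n_conc),
        col = rep(col_of, times = config$n_conc),
        role = "test")
      test[, concentration_M := conc[conc_index]]
      act <- with(truth_a[rep(seq_len(n_lib), times = config$n_conc)],
                  ifelse(activity_type == "inactive", 0,
                         true_efficacy / (1 + (true_ac50 / test$concentration_M)^true_hill)))
      test[, rlu := noisy(signal_of(act)) + pat_rlu[cbind(row, col)]]

      # unused wells in the test area of the last plate
      filler <- NULL
      n_empty <- n_plates * TEST_CAPACITY - n_lib
      if (n_empty > 0L) {
        we <- (n_lib + seq_len(n_empty)) - 1L
        wp <- we %% TEST_CAPACITY
        filler <- data.table::data.table(
          compound_id = NA_character_,
          conc_index = rep(seq_len(config$n_conc), each = n_empty),
          plate = rep(we %/% TEST_CAPACITY + 1L, times = config$n_conc),
          row = rep(wp %% PLATE_ROWS + 1L, times = config$n_conc),
          col = rep(TEST_COLS[wp %/% PLATE_ROWS + 1L], times = config$n_conc),
          role = "empty", concentration_M = NA_real_)
        filler[, rlu := noisy(rep(signal_of(0), .N)) + pat_rlu[cbind(row, col)]]
      }

      # control columns on every compound plate
      nctrl <- data.table::CJ(conc_index = seq_len(config$n_conc),
                              plate = seq_len(n_plates))
      ctl <- ctrl[rep(seq_len(nrow(ctrl)), times = nrow(nctrl))]
      ctl[, `:=`(conc_index = rep(nctrl$conc_index, each = nrow(ctrl)),
                 plate = rep(nctrl$plate, each = nrow(ctrl)))]
      ctl[, rlu := noisy(signal_of(rep(ctrl_act, times = nrow(nctrl)))) +
            pat_rlu[cbind(row, col)]]

      plates <- data.table::rbindlist(list(test, filler, ctl),
                                      use.names = TRUE, fill = TRUE)
      plates[, `:=`(
        assay_id = assay, run_id = run, plate_type = "compound",
        plate_id = sprintf("%s_r%d_c%02d_p%02d", assay, run, conc_index, plate))]

      # DMSO-only plates: control columns plus an all-DMSO test area
      dm <- data.table::CJ(row = seq_len(PLATE_ROWS), col = TEST_COLS,
                           dplate = seq_len(config$n_dmso_plates))
      dm[, `:=`(role = "DMSO", compound_id = NA_character_,
                concentration_M = NA_real_, conc_index = NA_integer_,
                plate = 0L)]
      dm[, rlu := noisy(rep(signal_of(0), .N)) + pat_rlu[cbind(row, col)]]
      dctl <- ctrl[rep(seq_len(nrow(ctrl)), times = config$n_dmso_plates)]
      dctl[, dplate := rep(seq_len(config$n_dmso_plates), each = nrow(ctrl))]
      dctl[, `:=`(conc_index = NA_integer_, plate = 0L)]
      dctl[, rlu := noisy(signal_of(rep(ctrl_act, times = config$n_dmso_plates))) +
             pat_rlu[cbind(row, col)]]
      dmso <- data.table::rbindlist(list(dm, dctl), use.names = TRUE, fill = TRUE)
      dmso[, `:=`(assay_id = assay, run_id = run, plate_type = "dmso",
                  plate_id = sprintf("%s_r%d_dmso%02d", assay, run, dplate))]
      dmso[, dplate := NULL]

      oi <- oi + 1L
      out[[oi]] <- data.table::rbindlist(list(plates[, -"plate"], dmso),
                                         use.names = TRUE, fill = TRUE)
    }
  }
  res <- data.table::rbindlist(out, use.names = TRUE)
  data.table::setcolorder(res, c("assay_id", "run_id", "plate_id", "plate_type",
                                 "conc_index", "row", "col", "role",
                                 "compound_id", "concentration_M", "rlu"))
  data.table::setattr(res, "true_pattern", patterns)
  res[]
}

#' Write a synthetic screen to plain-text files
#'
#' Writes `library.csv` (compound table with hex fingerprints),
#' `truth.csv` (per-channel ground truth), `plates.csv` (long-format wells)
#' and `config.json` (configuration echo) into `dir`.
#'
#' @param library a [generate_library()] result.
#' @param plates a [simulate_screen()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_screen <- function(library, plates, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(library$compounds, file.path(dir, "library.csv"))
  data.table::fwrite(library$truth, file.path(dir, "truth.csv"))
  data.table::fwrite(plates, file.path(dir, "plates.csv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cfg <- unclass(library$config)
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a plate file written by [write_screen()]
#'
#' @param path path to a `plates.csv`.
#' @return data.table in the [simulate_screen()] layout.
#' @export
read_plates <- function(path) {
  data.table::fread(path, colClasses = list(
    character = c("assay_id", "plate_id", "plate_type", "role", "compound_id")))
}
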