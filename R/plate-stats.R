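# Per-plate control statistics, QC gates and normalized well scores.

#' Per-plate quality-control statistics
#'
#' For every plate, computes the control-well summary statistics and the two
#' standard quality gates of high-density screening:
#' `Z' = 1 - 3 (sd_high + sd_low) / |mu_high - mu_low|` and the
#' signal-to-background ratio `S/B = mu_high / mu_low`. A plate passes when
#' `Z' >= z_prime_min` and `S/B >= s_over_b_min`. Degenerate plates
#' (`mu_high == mu_low`, undefined Z') are flagged and fail QC rather than
#' raising an error.
#'
#' @param plates Tibble of well signals as produced by
#'   [generate_plate_signals()] (columns `plate_id`, `role`, `signal`).
#' @param z_prime_min,s_over_b_min QC gates (defaults 0.6 and 3).
#' @return Tibble with one row per plate: `plate_id`, `mu_high`, `sd_high`,
#'   `mu_low`, `sd_low`, `z_prime`, `s_over_b`, `cv_high`, `cv_low`,
#'   `degenerate`, `passed`.
#' @export
plate_qc <- function(plates, z_prime_min = 0.6, s_over_b_min = 3) {
  stopifnot(all(c("plate_id", "role", "signal") %in% names(plates)))
  qc <- plates %>%
    filter(.data$role %in% c("control_high", "control_low")) %>%
    group_by(.data$plate_id) %>%
    summarise(
      n_high = sum(.data$role == "control_high"),
      n_low = sum(.data$role == "control_low"),
      mu_high = mean(.data$signal[.data$role == "control_high"]),
      sd_high = sd(.data$signal[.data$role == "control_high"]),
      mu_low = mean(.data$signal[.data$role == "control_low"]),
      sd_low = sd(.data$signal[.data$role == "control_low"]),
      .groups = "drop"
    )
  if (any(qc$n_high < 8 | qc$n_low < 8)) {
    abort("each plate needs at least 8 wells per control role.")
  }
  qc %>%
    mutate(
      degenerate = .data$mu_high == .data$mu_low,
      z_prime = ifelse(.data$degenerate, NA_real_,
                       1 - 3 * (.data$sd_high + .data$sd_low) /
                         abs(.data$mu_high - .data$mu_low)),
      s_over_b = .data$mu_high / .data$mu_low,
      cv_high = 100 * .data$sd_high / .data$mu_high,
      cv_low = 100 * .data$sd_low / .data$mu_low,
      passed = !.data$degenerate &
        .data$z_prime >= z_prime_min & .data$s_over_b >= s_over_b_min
    ) %>%
    select(-"n_high", -"n_low")
}

#' Percent inhibition of a raw signal
#'
#' Scales a raw well signal between the plate's high-control mean (enzyme plus
#' vehicle, 0% inhibition) and low-control mean (no enzyme, 100% inhibition):
#' `100 (mu_high - signal) / (mu_high - mu_low)`. Genuine inhibitors are
#' positive; signal-enhancing artifacts (e.g. chromophores in an absorbance
#' readout) come out negative, and values may exceed 100 for strong quenchers.
#' The score is invariant under rescaling all signals by a positive constant.
#'
#' @param signal Raw signal(s).
#' @param mu_high,mu_low Control means of the same plate.
#' @return Percent inhibition (numeric, unbounded).
#' @examples
#' percent_inhibition(550, 1000, 100)
#' @export
percent_inhibition <- function(signal, mu_high, mu_low) {
  if (any(mu_high == mu_low)) abort("undefined %inhibition: mu_high == mu_low.")
  100 * (mu_high - signal) / (mu_high - mu_low)
}

#' Robust per-plate Z-scores of compound wells
#'
#' Standardizes each compound-well signal against the plate's own compound-well
#' population using robust estimators:
#' `z = (signal - median) / (1.4826 * MAD)`. Compound wells (including vehicle
#' backfill wells on sparse plates) form the null population, so the score is
#' tolerant of the minority of true actives and of smooth plate gradients.
#' A zero MAD falls back to the sample SD; if that is also zero every z is 0.
#' Inhibitors, which lower the signal, score strongly negative.
#'
#' @param plates Well-signal tibble (columns `plate_id`, `role`,
#'   `compound_id`, `signal`); needs >= 16 compound wells per plate.
#' @return Tibble `plate_id`, `compound_id`, `signal`, `z_score` for wells
#'   that carry a compound.
#' @export
robust_zscore <- function(plates) {
  comp <- filter(plates, .data$role == "compound")
  sizes <- dplyr::count(comp, .data$plate_id)
  if (any(sizes$n < 16)) abort("robust Z-scores need >= 16 compound wells per plate.")
  comp %>%
    group_by(.data$plate_id) %>%
    mutate(z_score = {
      m <- median(.data$signal)
      s <- 1.4826 * mad(.data$signal, constant = 1)
      if (!is.na(s) && s == 0) s <- sd(.data$signal)
      if (is.na(s) || s == 0) rep(0, length(.data$signal))
      else (.data$signal - m) / s
    }) %>%
    ungroup() %>%
    filter(!is.na(.data$compound_id)) %>%
    select("plate_id", "compound_id", "signal", "z_score")
}

#' Normalized activity scores for all compound wells
#'
#' Joins plate QC onto the well table and returns, per compound well, the raw
#' signal, percent inhibition relative to that plate's controls, and the
#' robust Z-score from [robust_zscore()]. Wells on plates that failed QC are
#' excluded (flagged for retest upstream).
#'
#' @param plates Well-signal tibble.
#' @param qc Output of [plate_qc()]; computed on the fly if missing.
#' @param keep_failed Keep wells from QC-failed plates (default FALSE).
#' @return Tibble `plate_id`, `compound_id`, `signal`, `pct_inhibition`,
#'   `z_score`.
#' @export
score_wells <- function(plates, qc = NULL, keep_failed = FALSE) {
  if (is.null(qc)) qc <- plate_qc(plates)
  if (!keep_failed) {
    plates <- filter(plates, .data$plate_id %in% qc$plate_id[qc$passed])
  }
  z <- robust_zscore(plates)
  z %>%
    left_join(select(qc, "plate_id", "mu_high", "mu_low"), by = "plate_id") %>%
    mutate(pct_inhibition = percent_inhibition(.data$signal, .data$mu_high, .data$mu_low)) %>%
    select("plate_id", "compound_id", "signal", "pct_inhibition", "z_score")
}
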