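# Threshold and rescue rules that drive the staged triage cascade.
# All printed thresholds are inclusive (z <= -4, %effect >= 30 / 50 / 80).

#' Call primary actives from Z-scores
#'
#' Selects compounds whose robust Z-score is at or below the activity
#' threshold (inhibition is negative under the package's sign convention).
#'
#' @param scores Tibble with `compound_id` and `z_score`.
#' @param threshold Inclusive Z-score cut-off, default -4.
#' @return Character vector of compound ids, sorted.
#' @examples
#' call_primary_actives(tibble::tibble(
#'   compound_id = c("a", "b", "c"), z_score = c(-4, -3.99, -7)))
#' @export
call_primary_actives <- function(scores, threshold = -4) {
  ids <- scores$compound_id[scores$z_score <= threshold]
  sort(ids)
}

#' Confirmation-stage calls
#'
#' Applies the confirmation predicate to a fresh read of the progressed
#' compounds: `confirmed` are those with Z-score at or below `z_threshold`;
#' `confirmed_30` is the subset that additionally shows at least
#' `pct_threshold` percent effect in the same read.
#'
#' @param scores Tibble with `compound_id`, `z_score`, `pct_inhibition`.
#' @param z_threshold Inclusive Z cut-off (default -4).
#' @param pct_threshold Inclusive %effect cut-off (default 30).
#' @return List with sorted id vectors `confirmed` and `confirmed_30`.
#' @export
confirm_actives <- function(scores, z_threshold = -4, pct_threshold = 30) {
  confirmed <- sort(scores$compound_id[scores$z_score <= z_threshold])
  confirmed_30 <- sort(scores$compound_id[
    scores$z_score <= z_threshold & scores$pct_inhibition >= pct_threshold])
  list(confirmed = confirmed, confirmed_30 = confirmed_30)
}

#' Orthogonal-assay gate with rescue rules
#'
#' The orthogonal (different-readout) assay is run on every compound showing
#' at least `pct_tested` percent effect in the primary or confirmation read.
#' Progressed to potency testing are: compounds confirming in the orthogonal
#' assay (`ortho_pct >= pct_ortho`), plus two rescue routes guarding against
#' readout-specific false negatives -- a strong confirmation effect
#' (`confirm_pct >= pct_rescue_confirm`) or a very strong primary effect
#' (`primary_pct >= pct_rescue_primary`).
#'
#' @param effects Tibble with `compound_id`, `primary_pct`, `confirm_pct` and
#'   `ortho_pct` (NA where the compound was not orthogonally tested).
#' @param pct_tested Inclusive threshold defining the orthogonally tested set
#'   (default 30, on primary or confirmation effect).
#' @param pct_ortho Inclusive orthogonal confirmation threshold (default 30).
#' @param pct_rescue_confirm,pct_rescue_primary Inclusive rescue thresholds
#'   (defaults 50 and 80).
#' @return List of sorted id vectors: `tested`, `ortho_confirmed`, `rescued`,
#'   `progressed` (the union, without double counting).
#' @export
orthogonal_and_rescue <- function(effects, pct_tested = 30, pct_ortho = 30,
                                  pct_rescue_confirm = 50,
                                  pct_rescue_primary = 80) {
  tested <- effects$primary_pct >= pct_tested | effects$confirm_pct >= pct_tested
  ortho_ok <- tested & !is.na(effects$ortho_pct) & effects$ortho_pct >= pct_ortho
  rescue <- (effects$confirm_pct >= pct_rescue_confirm) |
    (effects$primary_pct >= pct_rescue_primary)
  list(
    tested = sort(effects$compound_id[tested]),
    ortho_confirmed = sort(effects$compound_id[ortho_ok]),
    rescued = sort(effects$compound_id[rescue & !ortho_ok]),
    progressed = sort(effects$compound_id[ortho_ok | rescue])
  )
}

#' Flag inhibitors in a robustness-set profiling run
#'
#' The robustness set is a small library of known assay-interference compounds
#' plus clean compounds, profiled before the campaign to gauge the assay's
#' susceptibility to nuisance mechanisms. This applies the same Z-score
#' predicate as the primary screen and reports each flagged compound together
#' with its annotated interference class.
#'
#' @param scores Tibble with `compound_id`, `z_score`.
#' @param classes Tibble with `compound_id` and `class` annotation.
#' @param threshold Inclusive Z cut-off (default -4).
#' @return Tibble of flagged compounds with their class labels, ordered by id.
#' @export
flag_robustness_set <- function(scores, classes, threshold = -4) {
  flagged <- tibble(compound_id = call_primary_actives(scores, threshold))
  left_join(flagged, classes, by = "compound_id")
}
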