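# End-to-end triage funnel: primary screen -> active calling -> Bayesian
# augmentation -> confirmation -> orthogonal + rescue -> availability ->
# dose-response + thermal shift -> zinc deselection -> gating -> analog
# expansion -> ranking -> LCMS attrition -> capped qualified hit list.

#' Funnel configuration
#'
#' All thresholds of the triage cascade in one place. Defaults follow
#' standard ultra-HTS practice for this assay family: inclusive Z-score cut
#' at -4, 30% effect for confirmation/orthogonal testing, 50%/80% rescue
#' effects, potency gate pIC50 >= 4.7 (a resolvable curve below the 20 uM
#' top concentration), 3 x SD thermal-shift significance, top-500 Bayesian
#' augmentation, a 50-compound cap on the qualified hit list with 100
#' compounds LCMS-checked, and a per-cluster diversity cap of 6.
#'
#' @param z_cut Inclusive primary/confirmation Z-score threshold.
#' @param pct_confirm Effect threshold defining orthogonally tested actives.
#' @param pct_rescue_confirm,pct_rescue_primary Rescue thresholds.
#' @param pic50_gate Potency gate on the fluorescence dose-response.
#' @param tsa_sd_mult Thermal-shift significance multiple.
#' @param bayes_top_n Size of the Bayesian augmentation list.
#' @param qhl_cap Maximum size of the qualified hit list.
#' @param lcms_checked_n Number of top-ranked compounds subjected to LCMS.
#' @param qed_promising QED level regarded as promising (reporting only).
#' @param per_cluster_cap Diversity cap per chemotype cluster in the ranking.
#' @param screen_conc Single-concentration screening concentration (molar).
#' @param tsa_conc Thermal-shift test concentration (molar).
#' @param dilution Dose-response dilution series.
#' @param seed Seed offset for the funnel's simulated stage reads.
#' @return Object of class `funnel_config`.
#' @export
funnel_config <- function(z_cut = -4, pct_confirm = 30,
                          pct_rescue_confirm = 50, pct_rescue_primary = 80,
                          pic50_gate = 4.7, tsa_sd_mult = 3,
                          bayes_top_n = 500, qhl_cap = 50,
                          lcms_checked_n = 100, qed_promising = 0.65,
                          per_cluster_cap = 6,
                          screen_conc = 10e-6, tsa_conc = 30e-6,
                          dilution = build_dilution(), seed = 0L) {
  structure(
    list(z_cut = z_cut, pct_confirm = pct_confirm,
         pct_rescue_confirm = pct_rescue_confirm,
         pct_rescue_primary = pct_rescue_primary,
         pic50_gate = pic50_gate, tsa_sd_mult = tsa_sd_mult,
         bayes_top_n = bayes_top_n, qhl_cap = qhl_cap,
         lcms_checked_n = lcms_checked_n, qed_promising = qed_promising,
         per_cluster_cap = per_cluster_cap, screen_conc = screen_conc,
         tsa_conc = tsa_conc, dilution = dilution, seed = as.integer(seed)),
    class = "funnel_config"
  )
}

#' Rank qualified-hit candidates
#'
#' Lexicographic priority: compounds with a positive thermal-shift call
#' first, then descending fluorescence pIC50 (censored last), then
#' descending QED, then compound id. A greedy diversity pass then walks the
#' ranking and defers compounds whose chemotype cluster already holds
#' `per_cluster_cap` selections; deferred compounds are back-filled at the
#' end, still in rank order, so tightening or widening the downstream cap
#' never reorders the list.
#'
#' @param entries Tibble with at least `compound_id`, `cluster_id`,
#'   `tsa_call`, `pic50_fluor`, `qed`.
#' @param per_cluster_cap Maximum picks per cluster before deferral.
#' @return `entries` reordered, with a `rank` column.
#' @export
rank_candidates <- function(entries, per_cluster_cap = 6) {
  pic <- ifelse(is.na(entries$pic50_fluor), -Inf, entries$pic50_fluor)
  ord <- order(-(entries$tsa_call == "positive"), -pic, -entries$qed,
               entries$compound_id)
  e <- entries[ord, ]
  sel <- logical(nrow(e))
  cl_count <- list()
  for (i in seq_len(nrow(e))) {
    cl <- e$cluster_id[i]
    k <- cl_count[[cl]] %||% 0L
    if (k < per_cluster_cap) {
      sel[i] <- TRUE
      cl_count[[cl]] <- k + 1L
    }
  }
  e <- bind_rows(e[sel, ], e[!sel, ])
  e$rank <- seq_len(nrow(e))
  e
}

#' Run the complete triage funnel on a synthetic campaign
#'
#' Executes every stage of the cascade against simulated stage reads of the
#' campaign, recording each stage's input/output sets so the whole funnel is
#' auditable:
#' primary screen (plate QC with retest, robust Z-scores) -> Z-score cut ->
#' naive-Bayes augmentation of the active list -> confirmation read ->
#' orthogonal read with rescue rules -> out-of-stock attrition ->
#' dose-response in the fluorescence, absorbance and zinc-supplemented
#' assays plus the thermal-shift run -> zinc deselection -> potency gate
#' OR significant thermal shift -> same-cluster analog expansion ->
#' diversity-aware ranking -> LCMS attrition of the checked top ->
#' qualified hit list capped at `qhl_cap`.
#'
#' @param campaign A [generate_library()] campaign.
#' @param config A [funnel_config()].
#' @return Object of class `funnel_report`: list with `stages` (counts and
#'   rules), `sets` (per-stage id vectors), `qhl` (the final hit table),
#'   `candidates` (all ranked candidates), `drc` (all dose-response fits),
#'   `tsa` (thermal-shift calls), `qc` (primary plate QC), `scores`
#'   (primary scores), `zinc` (deselection table), `config`.
#' @export
run_funnel <- function(campaign, config = funnel_config()) {
  lib <- campaign$library
  seed0 <- derive_seed(campaign$seed, 1L + config$seed)
  stages <- list()
  sets <- list()
  note <- function(stage, rule, in_ids, out_ids) {
    stages[[length(stages) + 1L]] <<- tibble(
      stage = stage, rule = rule,
      n_in = length(in_ids), n_out = length(out_ids))
    sets[[stage]] <<- sort(out_ids)
  }

  # -- 1. primary screen ----------------------------------------------------
  fl <- assay_config("fluorescence", plate_effect_amplitude = 0.02)
  primary <- simulate_screen_read(campaign, fl, config$screen_conc,
                                  seed = derive_seed(seed0, 11L), label = "PS")
  note("primary_screen", "plates passing QC, one read per compound",
       lib$compound_id, primary$scores$compound_id)

  # -- 2. primary actives ---------------------------------------------------
  actives <- call_primary_actives(primary$scores, config$z_cut)
  note("primary_actives", sprintf("z <= %g", config$z_cut),
       primary$scores$compound_id, actives)

  # -- 3. Bayesian augmentation --------------------------------------------
  if (length(actives) > 0 && length(actives) < nrow(lib)) {
    model <- bayes_fit(lib[, c("compound_id", "fp_bits")], actives)
    bscore <- bayes_score(lib[, c("compound_id", "fp_bits")], model)
    aug <- augment_actives(bscore, actives, config$bayes_top_n)
  } else {
    model <- NULL
    aug <- list(augmented = sort(actives), top_ids = character(0), n_added = 0L)
  }
  note("bayes_augmented",
       sprintf("actives + top-%d Bayes (added %d)", config$bayes_top_n, aug$n_added),
       actives, aug$augmented)

  # -- 4. confirmation read -------------------------------------------------
  confirm <- simulate_screen_read(campaign, fl, config$screen_conc,
                                  seed = derive_seed(seed0, 23L),
                                  ids = aug$augmented, label = "CF")
  conf_call <- confirm_actives(confirm$scores, config$z_cut, config$pct_confirm)
  note("confirmed", sprintf("z <= %g on confirmation read", config$z_cut),
       aug$augmented, conf_call$confirmed)
  note("confirmed_30",
       sprintf("confirmed and >= %g%% effect", config$pct_confirm),
       conf_call$confirmed, conf_call$confirmed_30)

  # -- 5. orthogonal + rescue ----------------------------------------------
  prim_pct <- setNames(primary$scores$pct_inhibition, primary$scores$compound_id)
  conf_pct <- setNames(confirm$scores$pct_inhibition, confirm$scores$compound_id)
  effects <- tibble(
    compound_id = aug$augmented,
    primary_pct = dplyr::coalesce(unname(prim_pct[aug$augmented]), -Inf),
    confirm_pct = dplyr::coalesce(unname(conf_pct[aug$augmented]), -Inf)
  )
  tested_ids <- effects$compound_id[
    effects$primary_pct >= config$pct_confirm |
      effects$confirm_pct >= config$pct_confirm]
  ab <- assay_config("absorbance")
  ortho <- simulate_screen_read(campaign, ab, config$screen_conc,
                                seed = derive_seed(seed0, 31L),
                                ids = tested_ids, label = "OR")
  ortho_pct <- setNames(ortho$scores$pct_inhibition, ortho$scores$compound_id)
  effects$ortho_pct <- unname(ortho_pct[effects$compound_id])
  gate <- orthogonal_and_rescue(effects, config$pct_confirm, config$pct_confirm,
                                config$pct_rescue_confirm,
                                config$pct_rescue_primary)
  note("orthogonal_progressed",
       sprintf("ortho >= %g%% or confirm >= %g%% or primary >= %g%%",
               config$pct_confirm, config$pct_rescue_confirm,
               config$pct_rescue_primary),
       gate$tested, gate$progressed)

  # -- 6. availability ------------------------------------------------------
  avail <- setNames(lib$available, lib$compound_id)
  drc_ids <- gate$progressed[avail[gate$progressed]]
  note("available", "compound in stock for cherry-pick", gate$progressed, drc_ids)

  # -- 7. dose-response in three assays + thermal shift ---------------------
  zn <- assay_config("fluorescence_zinc")
  drc <- bind_rows(
    fit_drc(simulate_drc(campaign, drc_ids, fl, config$dilution,
                         seed = derive_seed(seed0, 41L))),
    fit_drc(simulate_drc(campaign, drc_ids, ab, config$dilution,
                         seed = derive_seed(seed0, 43L))),
    fit_drc(simulate_drc(campaign, drc_ids, zn, config$dilution,
                         seed = derive_seed(seed0, 47L)))
  )
  tsa <- simulate_tsa(campaign, drc_ids, config$tsa_conc,
                      seed = derive_seed(seed0, 53L),
                      sd_mult = config$tsa_sd_mult)

  if (nrow(drc) > 0) {
    pic <- drc %>%
      select("compound_id", "assay", "pic50") %>%
      tidyr::pivot_wider(names_from = "assay", values_from = "pic50",
                         names_prefix = "pic50_") %>%
      rename(pic50_fluor = "pic50_fluorescence",
             pic50_abs = "pic50_absorbance",
             pic50_zinc = "pic50_fluorescence_zinc")
  } else {
    pic <- tibble(compound_id = character(0), pic50_fluor = numeric(0),
                  pic50_abs = numeric(0), pic50_zinc = numeric(0))
  }

  zinc_tab <- zinc_deselect(pic$pic50_fluor, pic$pic50_zinc, config$pic50_gate)
  zinc_lost <- pic$compound_id[zinc_tab$status == "lost"]
  gate_pass <- pic$compound_id[!is.na(pic$pic50_fluor) &
                                 pic$pic50_fluor >= config$pic50_gate]
  note("pic50_gate", sprintf("fluorescence pIC50 >= %g", config$pic50_gate),
       drc_ids, gate_pass)
  gate_kept <- setdiff(gate_pass, zinc_lost)
  note("zinc_deselected", "activity not lost with zinc present",
       gate_pass, gate_kept)
  tsa_sig <- tsa$calls$compound_id[tsa$calls$call != "none"]
  note("tsa_significant",
       sprintf("|dTm| > %g x vehicle SD in both replicates", config$tsa_sd_mult),
       drc_ids, tsa_sig)

  # -- 8. qualifying set + analog expansion ---------------------------------
  qualifying <- sort(union(gate_kept, tsa_sig))
  cl <- setNames(lib$cluster_id, lib$compound_id)
  analog_pool <- drc_ids[cl[drc_ids] %in% unique(cl[qualifying])]
  prelim <- sort(union(qualifying, analog_pool))
  note("preliminary_hit_list",
       "pIC50 gate (zinc-retained) or significant TSA, plus same-cluster analogs",
       drc_ids, prelim)

  # -- 9. ranking, LCMS attrition, cap --------------------------------------
  lib_cols <- lib[match(prelim, lib$compound_id),
                  c("compound_id", "cluster_id", "mech_class", "qed", "alogp",
                    "lcms_pass")]
  cand <- lib_cols %>%
    left_join(pic, by = "compound_id") %>%
    left_join(tsa$calls, by = "compound_id") %>%
    mutate(
      tsa_call = ifelse(is.na(.data$call), "none", .data$call),
      lipe = lipe(.data$pic50_fluor, .data$alogp),
      gate_pass = .data$compound_id %in% gate_kept,
      tsa_only = !(.data$compound_id %in% gate_kept) &
        (.data$compound_id %in% tsa_sig)
    ) %>%
    select(-"call")
  ranked <- rank_candidates(cand, config$per_cluster_cap)
  checked <- utils::head(ranked, config$lcms_checked_n)
  survivors <- checked[checked$lcms_pass, ]
  note("lcms_pass",
       sprintf("LCMS pass among the %d checked", nrow(checked)),
       checked$compound_id, survivors$compound_id)
  qhl <- utils::head(survivors, config$qhl_cap)
  qhl$qhl_rank <- seq_len(nrow(qhl))
  note("qualified_hit_list", sprintf("top %d after attrition", config$qhl_cap),
       survivors$compound_id, qhl$compound_id)

  structure(
    list(stages = bind_rows(stages), sets = sets, qhl = qhl,
         candidates = ranked, drc = drc, tsa = tsa$calls,
         tsa_vehicle_sd = tsa$vehicle_sd,
         qc = primary$qc, scores = primary$scores,
         zinc = tibble(compound_id = pic$compound_id, zinc_tab),
         effects = effects, bayes_model = model, config = config),
    class = "funnel_report"
  )
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  print(as.data.frame(x$stages), row.names = FALSE)
  invisible(x)
}

#' Stage-count summary of a funnel run
#'
#' @param report A [run_funnel()] report.
#' @return Tibble with `stage`, `rule`, `n_in`, `n_out`.
#' @export
stage_count_summary <- function(report) {
  report$stages
}

#' @rdname run_funnel
#' @param x A `funnel_report`.
#' @param ... Unused.
#' @method tidy funnel_report
#' @export
tidy.funnel_report <- function(x, ...) x$stages

#' @rdname run_funnel
#' @method glance funnel_report
#' @export
glance.funnel_report <- function(x, ...) {
  tibble(n_library = x$stages$n_in[1],
         n_primary_actives = length(x$sets$primary_actives),
         n_confirmed = length(x$sets$confirmed),
         n_progressed = length(x$sets$orthogonal_progressed),
         n_gate = length(x$sets$pic50_gate),
         n_tsa = length(x$sets$tsa_significant),
         n_qhl = nrow(x$qhl))
}

#' @rdname run_funnel
#' @param object A `funnel_report`.
#' @method autoplot funnel_report
#' @export
autoplot.funnel_report <- function(object, ...) {
  d <- object$stages
  d$stage <- factor(d$stage, levels = rev(d$stage))
  ggplot2::ggplot(d, ggplot2::aes(.data$n_out, .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), hjust = -0.15, size = 3) +
    ggplot2::scale_x_log10(expand = ggplot2::expansion(mult = c(0, 0.15))) +
    ggplot2::labs(x = "compounds out (log scale)", y = NULL,
                  title = "Triage funnel stage counts")
}

#' Persist a funnel report as plain-text artifacts
#'
#' Writes the stage-count summary (JSON), per-stage id sets (CSV), the full
#' candidate ranking and the qualified hit list (CSV) into a directory.
#'
#' @param report A [run_funnel()] report.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_funnel_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    list(stages = report$stages),
    file.path(dir, "stage_summary.json"), dataframe = "rows", auto_unbox = TRUE)
  sets <- map_dfr(names(report$sets), function(s) {
    tibble(stage = s, compound_id = report$sets[[s]])
  })
  readr::write_csv(sets, file.path(dir, "stage_sets.csv"))
  readr::write_csv(select(report$candidates, -dplyr::any_of("fp_bits")),
                   file.path(dir, "candidates.csv"))
  readr::write_csv(select(report$qhl, -dplyr::any_of("fp_bits")),
                   file.path(dir, "qualified_hit_list.csv"))
  readr::write_csv(report$drc, file.path(dir, "drc_fits.csv"))
  invisible(dir)
}
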