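# Funnel orchestration: stage-by-stage recomposition from the recorded
# score tables, auditability, ranking semantics and serialization.

test_that("every funnel stage equals its predicate applied independently", {
  camp <- test_campaign()
  rep <- test_funnel_report()
  cfg <- rep$config
  lib <- tidy(camp)

  # primary actives from the recorded primary scores
  expect_identical(rep$sets$primary_actives,
                   sort(rep$scores$compound_id[rep$scores$z_score <= cfg$z_cut]))

  # augmentation: union of actives and the top-scoring set
  bs <- bayes_score(lib[, c("compound_id", "fp_bits")], rep$bayes_model)
  aug <- augment_actives(bs, rep$sets$primary_actives, cfg$bayes_top_n)
  expect_identical(rep$sets$bayes_augmented, aug$augmented)
  expect_true(all(rep$sets$primary_actives %in% rep$sets$bayes_augmented))

  # orthogonal progression from the recorded effect table
  gate <- orthogonal_and_rescue(rep$effects, cfg$pct_confirm, cfg$pct_confirm,
                                cfg$pct_rescue_confirm, cfg$pct_rescue_primary)
  expect_identical(rep$sets$orthogonal_progressed, gate$progressed)

  # potency gate from the recorded dose-response fits
  fl <- rep$drc[rep$drc$assay == "fluorescence", ]
  gate_ids <- sort(fl$compound_id[!fl$censored & fl$pic50 >= cfg$pic50_gate])
  expect_identical(rep$sets$pic50_gate, gate_ids)

  # confirmed sets nest, the QHL respects its cap, stage counts match sets
  expect_true(all(rep$sets$confirmed_30 %in% rep$sets$confirmed))
  expect_true(all(rep$sets$confirmed %in% rep$sets$bayes_augmented))
  expect_lte(nrow(rep$qhl), cfg$qhl_cap)
  counts <- stage_count_summary(rep)
  expect_identical(counts$n_out,
                   vapply(counts$stage, function(s) length(rep$sets[[s]]),
                          integer(1), USE.NAMES = FALSE))
})

test_that("biochemical stage counts never increase after augmentation", {
  counts <- stage_count_summary(test_funnel_report())
  chain <- counts$n_out[match(c("bayes_augmented", "confirmed",
                                "orthogonal_progressed", "available"),
                              counts$stage)]
  expect_true(all(diff(chain) <= 0))
})

test_that("an impossible activity threshold empties the funnel", {
  camp <- generate_library(600, seed = 3)
  rep <- run_funnel(camp, funnel_config(z_cut = -Inf))
  expect_identical(nrow(rep$qhl), 0L)
  expect_identical(length(rep$sets$primary_actives), 0L)
})

test_that("funnel runs are deterministic", {
  camp <- generate_library(1500, seed = 19)
  r1 <- run_funnel(camp)
  r2 <- run_funnel(camp)
  expect_identical(stage_count_summary(r1), stage_count_summary(r2))
  expect_identical(r1$qhl$compound_id, r2$qhl$compound_id)
  expect_identical(r1$sets, r2$sets)
})

test_that("candidate ranking honours TSA, potency, QED and the cluster cap", {
  entries <- tibble::tibble(
    compound_id = c("a", "b", "c", "d", "e", "f"),
    cluster_id = c("K", "K", "K", "L", "L", "M"),
    tsa_call = c("positive", "positive", "positive", "positive", "none", "none"),
    pic50_fluor = c(6.5, 6.4, 6.3, 6.2, 7.0, NA),
    qed = c(0.5, 0.5, 0.5, 0.5, 0.9, 0.3))
  r <- rank_candidates(entries, per_cluster_cap = 2)
  # third member of cluster K deferred behind every other cluster's picks
  expect_identical(r$compound_id, c("a", "b", "d", "e", "f", "c"))
  # TSA positives precede a more potent non-engager
  expect_lt(which(r$compound_id == "d"), which(r$compound_id == "e"))
  # censored potency ranks last within its stratum
  expect_gt(which(r$compound_id == "f"), which(r$compound_id == "e"))

  # QED breaks ties between otherwise identical entries
  pair <- tibble::tibble(compound_id = c("x", "y"), cluster_id = c("P", "Q"),
                         tsa_call = "positive", pic50_fluor = 6.0,
                         qed = c(0.50, 0.70))
  expect_identical(rank_candidates(pair)$compound_id[1], "y")

  # widening the downstream cap preserves the selection prefix
  r10 <- utils::head(r$compound_id, 3)
  expect_identical(utils::head(rank_candidates(entries, 2)$compound_id, 3), r10)
})

test_that("funnel artifacts survive a serialization round trip", {
  camp <- generate_library(300, seed = 23)
  dir <- withr::local_tempdir()
  write_campaign(camp, file.path(dir, "camp"))
  back <- read_campaign(file.path(dir, "camp"))
  expect_equal(tidy(back)$fp_bits, tidy(camp)$fp_bits)
  expect_equal(tidy(back)$true_pKi, tidy(camp)$true_pKi)
  expect_identical(back$seed, camp$seed)

  rep <- test_funnel_report()
  write_funnel_report(rep, file.path(dir, "funnel"))
  sets <- readr::read_csv(file.path(dir, "funnel", "stage_sets.csv"),
                          show_col_types = FALSE)
  for (s in names(rep$sets)) {
    expect_identical(sets$compound_id[sets$stage == s], rep$sets[[s]])
  }
  qhl <- readr::read_csv(file.path(dir, "funnel", "qualified_hit_list.csv"),
                         show_col_types = FALSE)
  expect_identical(qhl$compound_id, rep$qhl$compound_id)

  plate <- generate_plate_signals(tidy(camp)[1:20, ], 1e-5, assay_config(),
                                  seed = 2)
  write_plate_csv(plate, file.path(dir, "p.csv"))
  expect_equal(as.data.frame(read_plate_csv(file.path(dir, "p.csv"))),
               as.data.frame(plate))
})

test_that("plates failing QC are re-queued once with a fresh seed", {
  camp <- generate_library(100, c(inactive = 1), seed = 5)
  noisy <- assay_config(well_cv = 0.5)   # hopeless assay: every plate fails
  res <- simulate_screen_read(camp, noisy, 1e-5, seed = 1)
  expect_gt(length(res$retested), 0)
  ok <- assay_config(well_cv = 0.02)
  res2 <- simulate_screen_read(camp, ok, 1e-5, seed = 1)
  expect_identical(res2$retested, character(0))
})
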