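# Synthetic screening library with latent ground truth.

MECH_CLASSES <- c("inactive", "competitive", "noncompetitive", "zinc_chelator",
                  "quencher", "chromophore", "aggregator")
GENUINE_CLASSES <- c("competitive", "noncompetitive", "zinc_chelator")

#' Default mechanism-class composition of the synthetic library
#'
#' Genuine inhibitors (competitive, non-competitive, zinc chelators) total
#' 0.8% of the library, the primary-active rate observed in large diverse
#' collections screened against this target class. The optical/colloidal
#' nuisance classes (quenchers, chromophores, aggregators) are present at a
#' few tenths of a percent each so every artifact-removal stage of the triage
#' has something to remove.
#'
#' @return Named numeric vector over the seven mechanism classes, summing to 1.
#' @export
default_class_fractions <- function() {
  c(inactive = 0.985,
    competitive = 0.005,
    noncompetitive = 0.002,
    zinc_chelator = 0.001,
    quencher = 0.003,
    chromophore = 0.002,
    aggregator = 0.002)
}

#' Generate a synthetic compound library with known ground truth
#'
#' Builds a seeded in-silico screening library. Class counts are allocated by
#' exact largest-remainder rounding of `n * fraction` (not sampled), so the
#' number of genuine actives is reproducible to the compound. Genuine
#' inhibitors receive a true pKi drawn from a truncated normal; nuisance
#' classes receive the artifact parameters that drive their apparent activity
#' in the plate signal model (attenuation for quenchers, absorbance offsets
#' for chromophores, steep-slope apparent potency for aggregators).
#'
#' Compounds are organised into chemotype clusters. Genuine actives are
#' grouped into clusters whose members share a 20-bit fingerprint signature
#' (each signature bit carried with probability `bit_prob`), and each active
#' cluster also contains inactive structural analogs; this is the structure
#' the naive-Bayes enrichment stage exploits. All remaining compounds sit in
#' background clusters with their own signatures, plus per-compound random
#' background bits.
#'
#' @param n Library size (>= 1).
#' @param class_fractions Named fractions over the mechanism classes; must sum
#'   to 1. See [default_class_fractions()].
#' @param potency_mean_sd Length-2 numeric: mean and SD of the true pKi
#'   (-log10 Ki in molar) of genuine inhibitors, truncated to
#'   `potency_bounds`. Default `c(6, 0.7)`.
#' @param seed Integer seed; the same seed reproduces the library bit for bit.
#' @param potency_bounds Truncation interval for pKi, default `c(4.5, 8)`.
#' @param cluster_size Target chemotype cluster size.
#' @param analog_inactive_frac Fraction of extra inactive analogs appended to
#'   each genuine-active cluster (relative to its active member count).
#' @param lcms_fail_rate Fraction of the library failing purity/identity
#'   control when eventually checked by LCMS.
#' @param out_of_stock_rate Fraction of compounds unavailable for cherry-pick
#'   follow-up.
#' @param n_bits Fingerprint length (number of possible binary features).
#' @param bits_per_cluster Signature bits per cluster.
#' @param bit_prob Probability that a compound carries each signature bit of
#'   its own cluster.
#' @param background_bits Random extra bits per compound.
#' @return An object of class `campaign_truth`: a list with `library`
#'   (a tibble of compound records), `class_fractions`, `seed`, and the
#'   generator parameters. `tidy()` returns the library tibble.
#' @examples
#' camp <- generate_library(500, seed = 1)
#' dplyr::count(tidy(camp), mech_class)
#' @export
generate_library <- function(n,
                             class_fractions = default_class_fractions(),
                             potency_mean_sd = c(6, 0.7),
                             seed = 1L,
                             potency_bounds = c(4.5, 8),
                             cluster_size = 6,
                             analog_inactive_frac = 0.3,
                             lcms_fail_rate = 0.18,
                             out_of_stock_rate = 0.01,
                             n_bits = 2048L,
                             bits_per_cluster = 20L,
                             bit_prob = 0.8,
                             background_bits = 15L) {
  if (!is_scalar_number(n) || n < 1) abort("`n` must be a positive integer.")
  n <- as.integer(n)
  missing_cls <- setdiff(names(class_fractions), MECH_CLASSES)
  if (length(missing_cls) > 0) {
    abort(paste0("unknown mechanism class: ", paste(missing_cls, collapse = ", ")))
  }
  fr <- setNames(numeric(length(MECH_CLASSES)), MECH_CLASSES)
  fr[names(class_fractions)] <- class_fractions
  counts <- largest_remainder(n, fr)

  with_seed(seed, {
    mech <- factor(rep(names(counts), counts), levels = MECH_CLASSES)
    mech <- mech[sample.int(n)]
    id <- sprintf("C%06d", seq_len(n))

    lib <- tibble(
      compound_id = id,
      mech_class = mech,
      true_pKi = NA_real_,
      hill = 1,
      quencher_atten = NA_real_,
      chromo_atten = NA_real_,
      abs_offset_frac = NA_real_,
      agg_pIC50 = NA_real_,
      dtm_max = 0
    )

    genuine <- lib$mech_class %in% GENUINE_CLASSES
    lib$true_pKi[genuine] <- rnorm_trunc(sum(genuine), potency_mean_sd[1],
                                         potency_mean_sd[2],
                                         potency_bounds[1], potency_bounds[2])
    # saturable stabilisation amplitude of genuine binders in the thermal
    # shift assay, degrees C at saturation
    lib$dtm_max[genuine] <- runif(sum(genuine), 1, 8)

    nq <- sum(lib$mech_class == "quencher")
    # attenuation capped at 0.7 so every quencher shows >= 30% apparent
    # inhibition in the fluorescent readout
    lib$quencher_atten[lib$mech_class == "quencher"] <- runif(nq, 0.2, 0.7)
    lib$abs_offset_frac[lib$mech_class == "quencher"] <- runif(nq, 0.1, 0.5)
    nc <- sum(lib$mech_class == "chromophore")
    lib$chromo_atten[lib$mech_class == "chromophore"] <- runif(nc, 0.3, 0.8)
    lib$abs_offset_frac[lib$mech_class == "chromophore"] <- runif(nc, 0.1, 0.5)
    na_ <- sum(lib$mech_class == "aggregator")
    lib$hill[lib$mech_class == "aggregator"] <- runif(na_, 3, 6)
    lib$agg_pIC50[lib$mech_class == "aggregator"] <- rnorm(na_, 5.5, 0.4)

    # ---- clusters: genuine actives share clusters, padded with inactive
    # analogs; everything else goes to background clusters -----------------
    cluster <- character(n)
    act_idx <- which(genuine)
    n_act_cl <- max(1L, ceiling(length(act_idx) / cluster_size))
    if (length(act_idx) > 0) {
      cl_of_active <- rep(seq_len(n_act_cl), length.out = length(act_idx))
      cluster[act_idx] <- sprintf("A%04d", sort(cl_of_active))
      # append inactive analogs to active clusters
      inact_idx <- which(lib$mech_class == "inactive")
      n_analog <- min(length(inact_idx),
                      round(analog_inactive_frac * length(act_idx)))
      if (n_analog > 0) {
        analog_idx <- sample(inact_idx, n_analog)
        cluster[analog_idx] <- sprintf("A%04d",
                                       sample.int(n_act_cl, n_analog, replace = TRUE))
      }
    }
    rest <- which(cluster == "")
    n_bg_cl <- max(1L, ceiling(length(rest) / cluster_size))
    cluster[rest] <- sprintf("B%05d", rep(seq_len(n_bg_cl), length.out = length(rest)))
    lib$cluster_id <- cluster

    # ---- fingerprints ----------------------------------------------------
    cl_levels <- unique(cluster)
    signatures <- lapply(seq_along(cl_levels), function(i) {
      sample.int(n_bits, bits_per_cluster)
    })
    names(signatures) <- cl_levels
    cl_idx <- match(cluster, cl_levels)
    lib$fp_bits <- lapply(seq_len(n), function(i) {
      sig <- signatures[[cl_idx[i]]]
      keep <- sig[runif(length(sig)) < bit_prob]
      sort(unique(c(keep, sample.int(n_bits, background_bits))))
    })

    lib$lcms_pass <- runif(n) >= lcms_fail_rate
    lib$available <- runif(n) >= out_of_stock_rate

    # drug-likeness inputs: plausible lead-like property profiles used by the
    # prioritisation stage (the synthetic library has no real structures)
    lib$mw <- pmin(pmax(rnorm(n, 380, 60), 150), 650)
    lib$alogp <- rnorm(n, 2.5, 1.2)
    lib$hba <- rpois(n, 5)
    lib$hbd <- rpois(n, 1.5)
    lib$psa <- pmax(rnorm(n, 85, 25), 3)
    lib$rotb <- rpois(n, 5)
    lib$arom <- rpois(n, 2)
    lib$alerts <- rbinom(n, 2, 0.15)
    lib$qed <- qed(lib$mw, lib$alogp, lib$hba, lib$hbd, lib$psa,
                   lib$rotb, lib$arom, lib$alerts)
    lib$smiles <- NA_character_

    lib <- select(lib, "compound_id", "cluster_id", "mech_class", "true_pKi",
                  "hill", dplyr::everything())

    structure(
      list(
        library = lib,
        class_fractions = fr,
        seed = as.integer(seed),
        params = list(
          n = n, potency_mean_sd = potency_mean_sd,
          potency_bounds = potency_bounds, cluster_size = cluster_size,
          analog_inactive_frac = analog_inactive_frac,
          lcms_fail_rate = lcms_fail_rate,
          out_of_stock_rate = out_of_stock_rate,
          n_bits = as.integer(n_bits), bits_per_cluster = bits_per_cluster,
          bit_prob = bit_prob, background_bits = background_bits
        )
      ),
      class = "campaign_truth"
    )
  })
}

#' @export
print.campaign_truth <- function(x, ...) {
  cat("<campaign_truth> ", nrow(x$library), " compounds, seed ", x$seed, "\n", sep = "")
  print(table(x$library$mech_class))
  invisible(x)
}

#' @rdname generate_library
#' @param x A `campaign_truth` object.
#' @param ... Unused.
#' @method tidy campaign_truth
#' @export
tidy.campaign_truth <- function(x, ...) x$library

#' Fractional enzyme inhibition of a compound at one concentration
#'
#' True (artifact-free) fractional inhibition under the competitive-inhibition
#' model. For competitive inhibitors and zinc chelators the half-inhibitory
#' concentration follows the Cheng-Prusoff relation
#' `IC50 = Ki * (1 + [S]/Km)`, so their measured potency depends on the
#' assay's substrate load; non-competitive inhibitors have `IC50 = Ki`
#' regardless of substrate. Inhibition is `c^h / (IC50^h + c^h)`. In the
#' zinc-supplemented readout a chelator's inhibition is multiplied by the
#' assay's `zinc_suppression` factor (0 by default: fully suppressed).
#' Optical and colloidal artifact classes (quencher, chromophore, aggregator)
#' and inactives return 0 here -- their apparent activity is a property of
#' the signal generation, not of the enzyme.
#'
#' @param compounds Data frame of compound records (rows from a
#'   [generate_library()] library).
#' @param conc Compound concentration in molar (scalar or one per row).
#' @param assay An [assay_config()].
#' @return Numeric vector of inhibition fractions in \[0, 1\].
#' @examples
#' camp <- generate_library(10, c(competitive = 1), seed = 1)
#' fractional_inhibition(tidy(camp)[1, ], 1e-5, assay_config())
#' @export
fractional_inhibition <- function(compounds, conc, assay = assay_config()) {
  if (any(conc < 0)) abort("`conc` must be non-negative.")
  stopifnot(inherits(assay, "assay_config"))
  ki <- 10^(-compounds$true_pKi)
  ic50 <- dplyr::case_when(
    compounds$mech_class %in% c("competitive", "zinc_chelator") ~
      ki * (1 + assay$substrate_over_km),
    compounds$mech_class == "noncompetitive" ~ ki,
    TRUE ~ NA_real_
  )
  h <- compounds$hill
  inh <- ifelse(is.na(ic50) | conc == 0, 0,
                conc^h / (ic50^h + conc^h))
  if (assay$readout == "fluorescence_zinc") {
    chel <- compounds$mech_class == "zinc_chelator"
    inh[chel] <- inh[chel] * assay$zinc_suppression
  }
  inh
}
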