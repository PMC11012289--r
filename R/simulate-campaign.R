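# Stage-level simulated reads of a synthetic campaign: single-concentration
# screens on 1536-well plates, dose-response reads, and thermal-shift runs.

#' Simulate a single-concentration screening read
#'
#' Distributes the requested compounds across as many 1536-well plates as
#' needed (unused compound wells are backfilled with vehicle, as on sparse
#' cherry-pick plates), simulates raw signals, applies plate QC, re-queues
#' failed plates once with a fresh seed (the "retest" policy), and scores
#' all compound wells.
#'
#' @param campaign A [generate_library()] campaign.
#' @param assay An [assay_config()].
#' @param conc Screening concentration (molar).
#' @param seed Integer seed.
#' @param ids Compound ids to screen (default: whole library).
#' @param layout Plate layout.
#' @param label Prefix for plate ids.
#' @return List with `plates` (well signals), `qc` (one row per plate,
#'   including retests), `scores` (per-compound `pct_inhibition`, `z_score`),
#'   `retested` (plate ids that failed QC).
#' @export
simulate_screen_read <- function(campaign, assay = assay_config(),
                                 conc = 10e-6, seed = 1L,
                                 ids = NULL, layout = plate_layout(),
                                 label = "P") {
  lib <- campaign$library
  if (!is.null(ids)) lib <- lib[match(ids, lib$compound_id), ]
  n_wells <- sum(layout$role == "compound")
  n_plates <- max(1L, ceiling(nrow(lib) / n_wells))
  chunks <- if (nrow(lib) == 0) list(integer(0)) else
    split(seq_len(nrow(lib)), ceiling(seq_len(nrow(lib)) / n_wells))

  run_plate <- function(i, seed_off) {
    generate_plate_signals(lib[chunks[[i]], ], conc, assay, layout,
                           seed = derive_seed(seed, i + seed_off),
                           plate_id = sprintf("%s%03d", label, i))
  }
  plates <- map_dfr(seq_len(n_plates), run_plate, seed_off = 0)
  qc <- plate_qc(plates)
  retested <- qc$plate_id[!qc$passed]
  if (length(retested) > 0) {
    redo <- map_dfr(which(qc$plate_id %in% retested), run_plate,
                    seed_off = 1000L)
    plates <- bind_rows(filter(plates, !.data$plate_id %in% retested), redo)
    qc <- bind_rows(filter(qc, .data$passed), plate_qc(redo))
  }
  scores <- score_wells(plates, qc)
  list(plates = plates, qc = qc, scores = scores, retested = retested)
}

#' Simulate dose-response reads for a compound set
#'
#' Generates percent-inhibition responses for every compound at each
#' concentration of the dilution series under the given assay, using the
#' class-conditional signal model of [expected_compound_signal()] plus
#' multiplicative well noise at the assay's `well_cv`.
#'
#' @param campaign A [generate_library()] campaign.
#' @param ids Compound ids to test.
#' @param assay An [assay_config()].
#' @param dilution A [build_dilution()] series.
#' @param seed Integer seed.
#' @return Tibble with `compound_id`, `assay`, `conc_M`, `pct_inhibition`.
#' @export
simulate_drc <- function(campaign, ids, assay = assay_config(),
                         dilution = build_dilution(), seed = 1L) {
  lib <- campaign$library[match(ids, campaign$library$compound_id), ]
  hi <- assay$control_high_mean
  lo <- assay$control_low_mean
  with_seed(seed, {
    map_dfr(seq_len(nrow(dilution)), function(i) {
      s <- expected_compound_signal(lib, dilution$conc_M[i], assay)
      if (assay$well_cv > 0) s <- s * (1 + assay$well_cv * rnorm(length(s)))
      tibble(compound_id = lib$compound_id,
             assay = assay$readout,
             conc_M = dilution$conc_M[i],
             pct_inhibition = percent_inhibition(s, hi, lo))
    })
  })
}

#' Simulate a thermal-shift screening run
#'
#' Each genuine binder stabilises the protein saturably: its injected shift
#' at concentration `conc` is `dtm_max * conc / (conc + Ki)`; every other
#' class injects no shift. Each sample is melted in `n_replicates`
#' independent runs alongside `n_vehicle` vehicle wells; melting
#' temperatures are extracted with [compute_tm()] and shifts are classified
#' with [classify_shift()] against the vehicle distribution.
#'
#' @param campaign A [generate_library()] campaign.
#' @param ids Compound ids to test.
#' @param conc Test concentration (molar), default 30 uM.
#' @param seed Integer seed.
#' @param vehicle_tm Vehicle melting temperature (deg C).
#' @param n_vehicle Number of vehicle wells (>= 8).
#' @param n_replicates Independent replicates per compound.
#' @param noise_frac Curve noise SD as a fraction of the fluorescence window.
#' @param sd_mult Significance multiple for [classify_shift()].
#' @param transition_slope,temps Melt-curve shape parameters.
#' @return List with `shifts` (per compound and replicate), `calls`
#'   (per-compound classification), `vehicle_tms`, `vehicle_sd`.
#' @export
simulate_tsa <- function(campaign, ids, conc = 30e-6, seed = 1L,
                         vehicle_tm = 64.87, n_vehicle = 16,
                         n_replicates = 2, noise_frac = 0.01,
                         sd_mult = 3, transition_slope = 1.5,
                         temps = seq(25, 99, by = 0.5)) {
  lib <- campaign$library[match(ids, campaign$library$compound_id), ]
  if (nrow(lib) == 0) {
    return(list(
      shifts = tibble(compound_id = character(0), replicate = integer(0),
                      delta_tm = numeric(0), injected = numeric(0)),
      calls = tibble(compound_id = character(0), mean_delta_tm = numeric(0),
                     call = character(0)),
      vehicle_tms = numeric(0), vehicle_sd = NA_real_))
  }
  ki <- 10^(-lib$true_pKi)
  inj <- ifelse(lib$mech_class %in% GENUINE_CLASSES,
                lib$dtm_max * conc / (conc + ki), 0)
  window <- 900
  noise_sd <- noise_frac * window
  base <- list(low_intercept = 100, low_slope = 0,
               high_intercept = 1000, high_slope = 0)

  melt_tm <- function(tm_true, sd_seed) {
    curve <- generate_melt_curve(tm_true, transition_slope, base, temps,
                                 noise_sd = noise_sd, seed = sd_seed)
    compute_tm(curve)$tm
  }
  vehicle_tms <- vapply(seq_len(n_vehicle), function(i) {
    melt_tm(vehicle_tm, derive_seed(seed, i))
  }, numeric(1))
  veh_mean <- mean(vehicle_tms)
  vehicle_deltas <- vehicle_tms - veh_mean

  shifts <- map_dfr(seq_len(nrow(lib)), function(i) {
    d <- vapply(seq_len(n_replicates), function(r) {
      tm <- melt_tm(vehicle_tm + inj[i], derive_seed(seed, 10000L + i * 7L + r))
      delta_tm(tm, vehicle_tms)
    }, numeric(1))
    tibble(compound_id = lib$compound_id[i], replicate = seq_len(n_replicates),
           delta_tm = d, injected = inj[i])
  })
  calls <- shifts %>%
    group_by(.data$compound_id) %>%
    summarise(
      mean_delta_tm = mean(.data$delta_tm),
      call = classify_shift(.data$delta_tm, vehicle_deltas, sd_mult)$call,
      .groups = "drop"
    )
  list(shifts = shifts, calls = calls, vehicle_tms = vehicle_tms,
       vehicle_sd = sd(vehicle_deltas))
}
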