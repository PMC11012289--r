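# 1536-well plate layouts and raw signal generation.

#' Define a high-density plate layout
#'
#' Default geometry is the 1536-well plate (32 rows x 48 columns) with the two
#' left-most columns as high controls (enzyme + vehicle, 0% inhibition), the
#' two right-most as low controls (no enzyme, 100% inhibition), and the 1408
#' wells in between as compound wells.
#'
#' @param n_rows,n_cols Plate geometry.
#' @param high_cols,low_cols Column indices holding the high / low controls.
#' @return Tibble with `well`, `row`, `col`, `role`.
#' @export
plate_layout <- function(n_rows = 32, n_cols = 48,
                         high_cols = c(1, 2), low_cols = c(47, 48)) {
  grid <- tidyr::expand_grid(row = seq_len(n_rows), col = seq_len(n_cols))
  grid$role <- "compound"
  grid$role[grid$col %in% high_cols] <- "control_high"
  grid$role[grid$col %in% low_cols] <- "control_low"
  grid$well <- sprintf("R%02dC%02d", grid$row, grid$col)
  as_tibble(grid[, c("well", "row", "col", "role")])
}

# Noise-free expected signal of compound wells under one readout, including
# artifact behaviour. Quenchers and chromophores attenuate the fluorescent
# readout multiplicatively (they absorb at the excitation wavelength) and ADD
# to the absorbance readout (apparent signal enhancement, i.e. negative
# %inhibition). Aggregators inhibit with a steep Hill slope in every
# biochemical readout.
expected_compound_signal <- function(compounds, conc, assay) {
  hi <- assay$control_high_mean
  lo <- assay$control_low_mean
  window <- hi - lo
  inh <- fractional_inhibition(compounds, conc, assay)
  agg <- compounds$mech_class == "aggregator"
  if (any(agg)) {
    ic <- 10^(-compounds$agg_pIC50[agg])
    h <- compounds$hill[agg]
    inh[agg] <- ifelse(conc == 0, 0, conc^h / (ic^h + conc^h))
  }
  s <- lo + window * (1 - inh)
  if (assay$readout %in% c("fluorescence", "fluorescence_zinc")) {
    # optical attenuation acts on the enzyme-generated signal above the
    # no-enzyme background, so a quencher with attenuation a reads as
    # exactly (1 - a) * 100 percent inhibition downstream
    qn <- compounds$mech_class == "quencher"
    s[qn] <- lo + (s[qn] - lo) * compounds$quencher_atten[qn]
    ch <- compounds$mech_class == "chromophore"
    s[ch] <- lo + (s[ch] - lo) * compounds$chromo_atten[ch]
  } else {
    opt <- compounds$mech_class %in% c("quencher", "chromophore")
    s[opt] <- s[opt] + window * compounds$abs_offset_frac[opt]
  }
  s
}

#' Generate raw well signals for one screening plate
#'
#' Lays the given compounds onto the compound wells of `layout` (row-major
#' order), fills any remaining compound wells with vehicle (they behave as
#' uninhibited wells and serve as the null population on sparse cherry-pick
#' plates), and simulates the raw readout: control means per role, the
#' class-conditional compound-well model of [expected_compound_signal()],
#' an optional smooth row/column polynomial gradient, and multiplicative
#' Gaussian well noise at the assay's `well_cv`.
#'
#' @param compounds Data frame of compound records; at most as many rows as
#'   compound wells in the layout.
#' @param conc Screening concentration (molar).
#' @param assay An [assay_config()].
#' @param layout A [plate_layout()] tibble.
#' @param seed Integer seed (deterministic plate).
#' @param plate_id Plate label.
#' @return Tibble with `plate_id`, `well`, `row`, `col`, `role`,
#'   `compound_id`, `signal`.
#' @export
generate_plate_signals <- function(compounds, conc, assay = assay_config(),
                                   layout = plate_layout(), seed = 1L,
                                   plate_id = "P001") {
  cw <- which(layout$role == "compound")
  if (nrow(compounds) > length(cw)) {
    abort(sprintf("%d compounds do not fit the %d compound wells of the layout.",
                  nrow(compounds), length(cw)))
  }
  with_seed(seed, {
    hi <- assay$control_high_mean
    lo <- assay$control_low_mean
    plate <- layout
    plate$compound_id <- NA_character_
    plate$compound_id[cw[seq_len(nrow(compounds))]] <- compounds$compound_id
    signal <- rep(NA_real_, nrow(plate))
    signal[plate$role == "control_high"] <- hi
    signal[plate$role == "control_low"] <- lo
    signal[plate$role == "compound"] <- hi  # vehicle backfill
    if (nrow(compounds) > 0) {
      signal[cw[seq_len(nrow(compounds))]] <-
        expected_compound_signal(compounds, conc, assay)
    }
    if (assay$plate_effect_amplitude > 0) {
      a <- runif(3, -1, 1)
      r <- plate$row / max(plate$row) - 0.5
      c2 <- plate$col / max(plate$col) - 0.5
      g <- a[1] * r + a[2] * c2 + a[3] * r * c2
      g <- g / max(abs(g))
      signal <- signal + assay$plate_effect_amplitude * hi * g
    }
    if (assay$well_cv > 0) {
      signal <- signal * (1 + assay$well_cv * rnorm(nrow(plate)))
    }
    plate$signal <- signal
    plate$plate_id <- plate_id
    plate[, c("plate_id", "well", "row", "col", "role", "compound_id", "signal")]
  })
}
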