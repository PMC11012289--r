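#' Biochemical assay configuration
#'
#' Describes one plate-based enzymatic readout used by the signal generators
#' and dose-response simulators. The two label-based readouts differ in the
#' substrate concentration relative to the Michaelis constant: the fluorogenic
#' assay runs at `[S] = Km` while the chromogenic (absorbance) assay needs
#' `[S] = 2.6 Km` for an adequate signal window. That ratio is what shifts the
#' measured IC50 of purely competitive inhibitors between the two readouts
#' (see [cheng_prusoff_shift()]). The zinc-supplemented readout is the
#' fluorescence assay with excess Zn2+ in the buffer, which suppresses
#' inhibition by pure metal chelators.
#'
#' @param readout One of `"fluorescence"`, `"absorbance"`,
#'   `"fluorescence_zinc"`.
#' @param substrate_over_km Substrate concentration as a multiple of Km.
#'   Defaults: 1 (fluorescence and fluorescence_zinc), 2.6 (absorbance).
#' @param control_high_mean,control_low_mean Expected signal of the
#'   enzyme-plus-vehicle (high, 0% inhibition) and no-enzyme (low, 100%
#'   inhibition) control wells, in instrument units.
#' @param well_cv Fractional multiplicative well-to-well noise (coefficient of
#'   variation). 0 gives noise-free plates.
#' @param plate_effect_amplitude Amplitude of the optional smooth row/column
#'   plate gradient, as a fraction of the high-control signal. 0 disables it.
#' @param zinc_suppression Residual fraction of a pure zinc chelator's
#'   inhibition that survives the zinc-supplemented buffer (0 = fully
#'   suppressed). Only used when `readout = "fluorescence_zinc"`.
#' @return An object of class `assay_config`.
#' @examples
#' assay_config("absorbance")
#' @export
assay_config <- function(readout = c("fluorescence", "absorbance", "fluorescence_zinc"),
                         substrate_over_km = NULL,
                         control_high_mean = 1000,
                         control_low_mean = 1000 / 30,
                         well_cv = 0.03,
                         plate_effect_amplitude = 0,
                         zinc_suppression = 0) {
  readout <- match.arg(readout)
  if (is.null(substrate_over_km)) {
    substrate_over_km <- if (readout == "absorbance") 2.6 else 1
  }
  if (!is_scalar_number(substrate_over_km) || substrate_over_km <= 0) {
    abort("`substrate_over_km` must be a positive number.")
  }
  if (!is_scalar_number(well_cv) || well_cv < 0 || well_cv >= 1) {
    abort("`well_cv` must lie in [0, 1).")
  }
  if (control_high_mean <= 0 || control_low_mean <= 0) {
    abort("control means must be positive.")
  }
  structure(
    list(
      readout = readout,
      substrate_over_km = substrate_over_km,
      control_high_mean = control_high_mean,
      control_low_mean = control_low_mean,
      well_cv = well_cv,
      plate_effect_amplitude = plate_effect_amplitude,
      zinc_suppression = zinc_suppression
    ),
    class = "assay_config"
  )
}

#' @export
print.assay_config <- function(x, ...) {
  cat("<assay_config> ", x$readout,
      "  [S]/Km = ", x$substrate_over_km,
      "  S/B = ", signif(x$control_high_mean / x$control_low_mean, 3),
      "  well CV = ", x$well_cv, "\n", sep = "")
  invisible(x)
}
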