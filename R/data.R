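#' Published qualified-hit-list reference properties
#'
#' The printed summary table of the most potent qualified hits of the
#' reference campaign (fluorescence IC50 below 3.5 uM plus same-cluster
#' additions): per-compound potencies in the three biochemical assays
#' (censored entries as the literal `"<4.70"`), thermal shift, molecular
#' weight, Lipinski counts, TPSA, LogD, LipE and QED. Used as an input for
#' consistency checks (e.g. `LipE = pIC50_fluorescence - LogD` for every
#' row) and as the column template for the package's own hit tables.
#'
#' @return Tibble with one row per published hit.
#' @export
qhl_reference <- function() {
  path <- system.file("extdata", "qhl_reference_properties.csv",
                      package = "screentriage", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    qhl = "i", cluster = "c", ic50_um = "d",
                    pic50_fluor = "d", pic50_abs = "c", pic50_zinc = "d",
                    tsa_delta_c = "d", mw = "d", hba = "i", hbd = "i",
                    tpsa = "d", logd = "d", lipe = "d", qed = "d"))
}
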