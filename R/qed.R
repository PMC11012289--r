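# Quantitative estimate of drug-likeness: the geometric mean of eight
# asymmetric-double-sigmoid desirability functions fitted to the property
# distributions of approved oral drugs.

# Parameters (a, b, c, d, e, f, dmax) of the asymmetric double sigmoid
# d(x) = [a + b / (1 + exp(-(x - c + d/2)/e)) * (1 - 1/(1 + exp(-(x - c - d/2)/f)))] / dmax
# for the eight properties, in the published parameterisation.
QED_ADS_PARAMS <- list(
  mw     = c(a = 2.817065973, b = 392.5754953, c = 290.7489764, d = 2.419764353,
             e = 49.22325677, f = 65.37051707, dmax = 104.9805561),
  alogp  = c(a = 3.172690585, b = 137.8624751, c = 2.534937431, d = 4.581497897,
             e = 0.822739154, f = 0.576295591, dmax = 131.3186604),
  hba    = c(a = 2.948620388, b = 160.4605972, c = 3.615294657, d = 4.435986202,
             e = 0.290141953, f = 1.300669958, dmax = 148.7763046),
  hbd    = c(a = 1.618662227, b = 1010.051101, c = 0.985094388, d = 1e-09,
             e = 0.713820843, f = 0.920922555, dmax = 258.1632616),
  psa    = c(a = 1.876861559, b = 125.2232657, c = 62.90773554, d = 87.83366614,
             e = 12.01999824, f = 28.51324732, dmax = 104.5686167),
  rotb   = c(a = 0.01, b = 272.4121427, c = 2.55837997, d = 1.565547684,
             e = 1.271567166, f = 2.758063707, dmax = 105.4420403),
  arom   = c(a = 3.21778897, b = 957.7374108, c = 2.274627939, d = 1e-09,
             e = 1.317690384, f = 0.375760881, dmax = 312.337261),
  alerts = c(a = 0.01, b = 1199.094025, c = -0.09002883, d = 1e-09,
             e = 0.185904477, f = 0.875193782, dmax = 417.725314)
)

# Weights of the "mean-information-content" weighted variant.
QED_MEAN_WEIGHTS <- c(mw = 0.66, alogp = 0.46, hba = 0.05, hbd = 0.61,
                      psa = 0.06, rotb = 0.65, arom = 0.48, alerts = 0.95)

qed_ads <- function(x, p) {
  v <- p["a"] + p["b"] / (1 + exp(-(x - p["c"] + p["d"] / 2) / p["e"])) *
    (1 - 1 / (1 + exp(-(x - p["c"] - p["d"] / 2) / p["f"])))
  unname(v / p["dmax"])
}

#' Desirability functions of the eight QED properties
#'
#' @param mw Molecular weight (g/mol).
#' @param alogp Calculated octanol-water partition coefficient.
#' @param hba,hbd Hydrogen-bond acceptor / donor counts.
#' @param psa Polar surface area (square Angstrom).
#' @param rotb Rotatable bond count.
#' @param arom Aromatic ring count.
#' @param alerts Structural alert count.
#' @return Tibble of the eight desirabilities, each in (0, 1\].
#' @export
qed_desirabilities <- function(mw, alogp, hba, hbd, psa, rotb, arom, alerts) {
  tibble(
    mw = qed_ads(mw, QED_ADS_PARAMS$mw),
    alogp = qed_ads(alogp, QED_ADS_PARAMS$alogp),
    hba = qed_ads(hba, QED_ADS_PARAMS$hba),
    hbd = qed_ads(hbd, QED_ADS_PARAMS$hbd),
    psa = qed_ads(psa, QED_ADS_PARAMS$psa),
    rotb = qed_ads(rotb, QED_ADS_PARAMS$rotb),
    arom = qed_ads(arom, QED_ADS_PARAMS$arom),
    alerts = qed_ads(alerts, QED_ADS_PARAMS$alerts)
  )
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Combines the eight property desirabilities into a single score in
#' \[0, 1\] (0 = unfavourable, 1 = favourable): the unweighted variant is
#' the plain geometric mean `exp(mean(ln d_i))`; the `"mean"` variant uses
#' the published mean-information-content weights. Desirabilities are
#' floored at 1e-6 before taking logs, so a single vanishing desirability
#' drives the score toward 0 without producing -Inf.
#'
#' @inheritParams qed_desirabilities
#' @param weights `"unweighted"` (default) or `"mean"`.
#' @return QED scores in \[0, 1\].
#' @examples
#' qed(mw = 346.4, alogp = 1.48, hba = 4, hbd = 2, psa = 86.7,
#'     rotb = 4, arom = 2, alerts = 2)
#' @export
qed <- function(mw, alogp, hba, hbd, psa, rotb, arom, alerts,
                weights = c("unweighted", "mean")) {
  weights <- match.arg(weights)
  d <- qed_desirabilities(mw, alogp, hba, hbd, psa, rotb, arom, alerts)
  logd <- log(pmax(as.matrix(d), 1e-6))
  if (weights == "unweighted") {
    out <- exp(rowMeans(logd))
  } else {
    w <- QED_MEAN_WEIGHTS[colnames(logd)]
    out <- exp(as.vector(logd %*% w) / sum(w))
  }
  pmin(pmax(out, 0), 1)
}
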