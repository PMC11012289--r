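# Formula masses, adduct m/z, SMILES descriptors, QED and LipE.
# Expected descriptor values were frozen from an independent cheminformatics
# toolkit (RDKit) for both TPSA conventions and the QED variants.

qhl1 <- "ONC(=O)Cc1ccccc1S(=O)(=O)N1CCc2ccccc2C1"

test_that("molecular formulas parse order-agnostically with implicit counts", {
  f <- parse_formula("C17H18N2O4S")
  expect_identical(f[c("C", "H", "N", "O", "S")],
                   c(C = 17L, H = 18L, N = 2L, O = 4L, S = 1L))
  expect_identical(parse_formula("H2O"), c(H = 2L, O = 1L))
  expect_identical(parse_formula("OH2"), c(H = 2L, O = 1L))  # order-free
  expect_identical(parse_formula("CH3CH3")[["C"]], 2L)       # repeats summed
  expect_error(parse_formula("Xx3"), "unknown element")
  expect_error(parse_formula(""), "non-empty")
})

test_that("average molecular weights match the standard-weight table", {
  expect_equal(average_mw("C17H18N2O4S"), 346.40)
  expect_equal(average_mw("H2O"), 18.02)
  expect_equal(average_mw("C"), 12.01)
  # additivity over formula union
  expect_equal(monoisotopic_mass("C2H6O"),
               monoisotopic_mass("C2H4") + monoisotopic_mass("H2O"),
               tolerance = 1e-9)
})

test_that("adduct m/z uses neutral-atom monoisotopic masses", {
  expect_equal(adduct_mz("C17H18N2O4S", "M+Na"), 369.0885)
  expect_equal(adduct_mz("C17H18N2O4S", "M+H"), 347.1066)
  # the sodium-proton spacing is formula-independent
  for (f in c("C17H18N2O4S", "H2O", "C6H6")) {
    expect_equal(adduct_mz(f, "M+Na") - adduct_mz(f, "M+H"), 21.9819,
                 tolerance = 1e-4)
  }
})

test_that("Lipinski counts are N+O acceptors and N/O-attached hydrogens", {
  lc <- lipinski_counts(c(qhl1, "C", "O"))
  expect_identical(lc$hba, c(6L, 0L, 1L))
  expect_identical(lc$hbd, c(2L, 0L, 2L))
})

test_that("TPSA reproduces both sulfur conventions", {
  expect_equal(tpsa(qhl1), 95.09)
  expect_equal(tpsa(qhl1, include_sulfur_phosphorus = FALSE), 86.71)
  expect_equal(tpsa("C"), 0)
  # panel frozen from the independent toolkit: S/P-inclusive, then N/O-only
  panel <- c("CCO", "c1ccsc1", "CS(=O)C", "CSC", "CC(=O)Nc1ccc(O)cc1",
             "CN1C=NC2=C1C(=O)N(C)C(=O)N2C", "CCOP(=O)(OCC)OCC",
             "NS(=O)(=O)c1ccccc1", "O=S(=O)(O)O", "c1ccoc1", "C1CCNCC1")
  sp <- c(20.23, 28.24, 36.28, 25.30, 49.33, 61.82, 54.57, 68.54, 82.98,
          13.14, 12.03)
  nosp <- c(20.23, 0.00, 17.07, 0.00, 49.33, 61.82, 44.76, 60.16, 74.60,
            13.14, 12.03)
  expect_equal(tpsa(panel), sp)
  expect_equal(tpsa(panel, include_sulfur_phosphorus = FALSE), nosp)
})

test_that("QED reproduces frozen oracle values for both weighting variants", {
  mw <- c(346.408, 180.16, 500.0); alogp <- c(1.4815, 1.31, 5.2)
  hba <- c(4, 4, 10); hbd <- c(2, 1, 5); psa <- c(86.71, 63.6, 140.0)
  rotb <- c(4, 3, 12); arom <- c(2, 1, 4); alerts <- c(2, 0, 3)
  expect_equal(qed(mw, alogp, hba, hbd, psa, rotb, arom, alerts),
               c(0.7484862, 0.8003236, 0.1097092), tolerance = 1e-6)
  expect_equal(qed(mw, alogp, hba, hbd, psa, rotb, arom, alerts,
                   weights = "mean"),
               c(0.6484760, 0.7611665, 0.1002367), tolerance = 1e-6)
})

test_that("QED behaves as a bounded geometric mean of desirabilities", {
  d <- qed_desirabilities(300, 2.5, 4, 1, 80, 4, 2, 0)
  expect_true(all(as.numeric(d) > 0 & as.numeric(d) <= 1))
  # QED is exactly the geometric mean of the floored desirabilities
  expect_equal(qed(300, 2.5, 4, 1, 80, 4, 2, 0),
               exp(mean(log(pmax(as.numeric(d), 1e-6)))))
  # a catastrophic single property collapses the score
  lo <- qed(300, 2.5, 4, 1, 80, 200, 2, 0)  # absurd rotatable-bond count
  hi <- qed(300, 2.5, 4, 1, 80, 4, 2, 0)
  expect_lt(lo, 0.35)
  expect_gt(hi, 0.6)
  # monotone non-decreasing in any single desirability, others held fixed:
  # moving MW toward the optimum never lowers the score
  q1 <- qed(450, 2.5, 4, 1, 80, 4, 2, 0)
  q2 <- qed(390, 2.5, 4, 1, 80, 4, 2, 0)
  q3 <- qed(310, 2.5, 4, 1, 80, 4, 2, 0)
  expect_true(q1 <= q2 && q2 <= q3)
  expect_true(all(qed(c(100, 3000), 2.5, 4, 1, 80, 4, 2, 0) >= 0))
})

test_that("structure property bundles assemble per molecule", {
  props <- mol_properties(qhl1)
  expect_identical(props$formula, "C17H18N2O4S")
  expect_equal(props$mw, 346.40)
  expect_identical(props$hba, 6L)
  expect_identical(props$hbd, 2L)
  expect_equal(props$tpsa, 95.09)
  expect_identical(props$logp_source, "openbabel_logp")
})

test_that("LipE is the potency-lipophilicity difference", {
  expect_equal(lipe(6.50, 1.65), 4.85)
  expect_equal(lipe(5.33, 0.95), 4.38)
  expect_equal(lipe(5.2, 0), 5.2)
})

test_that("every published hit row satisfies LipE = pIC50 - LogD", {
  ref <- qhl_reference()
  expect_equal(lipe(ref$pic50_fluor, ref$logd), ref$lipe, tolerance = 0.011)
  # the published table is ordered by non-increasing fluorescence potency
  expect_true(all(diff(ref$pic50_fluor) <= 0))
})
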