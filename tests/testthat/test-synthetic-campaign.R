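# Synthetic campaign generator: quota allocation, determinism, the
# class-conditional signal model, progress curves and melt curves.

test_that("class counts follow exact largest-remainder quotas", {
  fr <- default_class_fractions()
  camp <- generate_library(40000, fr, seed = 7)
  counts <- table(tidy(camp)$mech_class)
  genuine <- sum(counts[genuine_classes])
  expect_identical(as.integer(genuine), 320L)
  expect_identical(unname(largest_remainder(40000, fr)),
                   as.integer(counts[names(fr)]))

  # degenerate single-class library
  one <- tidy(generate_library(10, c(inactive = 1), seed = 1))
  expect_identical(nrow(one), 10L)
  expect_true(all(one$mech_class == "inactive"))
  expect_true(all(is.na(one$true_pKi)))
})

test_that("library generation is deterministic under a seed", {
  a <- generate_library(800, seed = 42)
  b <- generate_library(800, seed = 42)
  expect_identical(tidy(a), tidy(b))
  c <- generate_library(800, seed = 43)
  expect_false(identical(tidy(a)$fp_bits, tidy(c)$fp_bits))
})

test_that("invalid library arguments error", {
  expect_error(generate_library(0), "positive")
  expect_error(generate_library(10, c(inactive = 1.2, competitive = -0.2)),
               "non-negative")
  expect_error(generate_library(10, c(inactive = 0.5)), "sum to 1")
  expect_error(generate_library(10, c(bogus_class = 1)), "unknown mechanism")
})

test_that("fractional inhibition follows the competitive-shift model", {
  comp <- tibble::tibble(
    mech_class = factor("competitive", levels = screentriage:::MECH_CLASSES),
    true_pKi = 6, hill = 1)  # Ki = 1 uM
  # at [S]=Km the IC50 is 2 uM, so 2 uM gives half-inhibition
  expect_equal(fractional_inhibition(comp, 2e-6, assay_config("fluorescence")), 0.5)
  expect_equal(fractional_inhibition(comp, 0, assay_config()), 0)
  expect_error(fractional_inhibition(comp, -1e-9, assay_config()), "non-negative")

  # IC50 ratio between the two substrate loads is 3.6/2 = 1.8,
  # i.e. a pIC50 shift of 0.2553 that prints as 0.26
  ic50_fluor <- 1e-6 * (1 + 1)
  ic50_abs <- 1e-6 * (1 + 2.6)
  expect_equal(ic50_abs / ic50_fluor, 1.8)
  shift <- log10(ic50_abs / ic50_fluor)
  expect_equal(shift, 0.2553, tolerance = 1e-3)
  expect_identical(sprintf("%.2f", shift), "0.26")

  # full chelator suppression under the zinc-supplemented readout
  chel <- tibble::tibble(
    mech_class = factor("zinc_chelator", levels = screentriage:::MECH_CLASSES),
    true_pKi = 6, hill = 1)
  expect_gt(fractional_inhibition(chel, 1e-5, assay_config("fluorescence")), 0.5)
  expect_equal(fractional_inhibition(chel, 1e-5, assay_config("fluorescence_zinc")), 0)
})

test_that("plate signal model reproduces the stated class phenotypes", {
  quiet <- assay_config("fluorescence", well_cv = 0)
  quiet_abs <- assay_config("absorbance", well_cv = 0)
  hi <- quiet$control_high_mean; lo <- quiet$control_low_mean

  # noise-free null plate: every compound well equals the high-control mean
  camp <- generate_library(100, c(inactive = 1), seed = 3)
  plate <- generate_plate_signals(tidy(camp), 1e-5, quiet, seed = 1)
  cw <- plate$signal[plate$role == "compound"]
  expect_true(all(cw == hi))

  # quencher with attenuation 0.4: 60% apparent inhibition in fluorescence,
  # negative in absorbance
  qn <- tidy(generate_library(1, c(quencher = 1), seed = 5))
  qn$quencher_atten <- 0.4
  s_fl <- screentriage:::expected_compound_signal(qn, 1e-5, quiet)
  expect_equal(percent_inhibition(s_fl, hi, lo), 60, tolerance = 1e-9)
  s_ab <- screentriage:::expected_compound_signal(qn, 1e-5, quiet_abs)
  expect_lt(percent_inhibition(s_ab, quiet_abs$control_high_mean,
                               quiet_abs$control_low_mean), 0)

  # competitive compound at its IC50: well signal is the control midpoint
  cmp <- tidy(generate_library(1, c(competitive = 1), seed = 5))
  cmp$true_pKi <- -log10(1e-5 / 2)  # IC50 = 10 uM at [S]=Km
  s_mid <- screentriage:::expected_compound_signal(cmp, 1e-5, quiet)
  expect_equal(s_mid, (hi + lo) / 2, tolerance = 1e-9)

  # layout overflow errors
  small_layout <- plate_layout(n_rows = 2, n_cols = 6,
                               high_cols = 1, low_cols = 6)
  big <- tidy(generate_library(20, c(inactive = 1), seed = 1))
  expect_error(generate_plate_signals(big, 1e-5, quiet, small_layout), "fit")

  # determinism
  p1 <- generate_plate_signals(big[1:5, ], 1e-5, assay_config(), seed = 9)
  p2 <- generate_plate_signals(big[1:5, ], 1e-5, assay_config(), seed = 9)
  expect_identical(p1, p2)
})

test_that("optical artifact classes separate by readout, chelators by zinc", {
  fr <- c(quencher = 0.25, chromophore = 0.25, zinc_chelator = 0.25,
          inactive = 0.25)
  camp <- generate_library(200, fr, seed = 13)
  lib <- tidy(camp)
  quiet <- assay_config("fluorescence", well_cv = 0)
  quiet_abs <- assay_config("absorbance", well_cv = 0)
  quiet_zn <- assay_config("fluorescence_zinc", well_cv = 0)
  hi <- quiet$control_high_mean; lo <- quiet$control_low_mean

  qn <- lib[lib$mech_class == "quencher", ]
  pct_fl <- percent_inhibition(
    screentriage:::expected_compound_signal(qn, 1e-5, quiet), hi, lo)
  pct_ab <- percent_inhibition(
    screentriage:::expected_compound_signal(qn, 1e-5, quiet_abs), hi, lo)
  expect_true(all(pct_fl >= 30))   # attenuation <= 0.7 guarantees >= 30
  expect_true(all(pct_ab <= 0))

  chel <- lib[lib$mech_class == "zinc_chelator", ]
  inh_zn <- fractional_inhibition(chel, 1e-5, quiet_zn)
  expect_true(all(inh_zn == 0))
})

test_that("progress curves obey Michaelis-Menten limits and conservation", {
  km <- 36.6e-6; vmax <- 1e-6
  # saturating substrate: early slope equals Vmax
  sat <- generate_progress_curve(km, vmax, 1000 * km, seq(1, 10, 1))
  early <- (sat$product[2] - sat$product[1]) / 1
  expect_equal(early, vmax, tolerance = 0.002)

  # s0 = Km: initial slope is Vmax / 2
  half <- generate_progress_curve(km, vmax, km, c(0.05, 0.1))
  expect_equal(half$product[1] / 0.05, vmax / 2, tolerance = 0.01)

  # conservation: product approaches s0
  s0 <- 5e-6
  long <- generate_progress_curve(km, vmax, s0, c(1, 5000))
  expect_equal(long$product[2], s0, tolerance = 1e-3 * s0)
  expect_true(all(diff(long$product) >= 0))

  expect_error(generate_progress_curve(-1, vmax, s0, 1:3), "positive")
  expect_error(generate_progress_curve(km, vmax, s0, c(2, 1)), "ascending")
})

test_that("integrated progress curve matches the Lambert-W closed form", {
  km <- 2e-5; vmax <- 3e-6; s0 <- 6e-5
  times <- seq(2, 60, by = 2)
  got <- generate_progress_curve(km, vmax, s0, times)$product
  w_arg <- (s0 / km) * exp((s0 - vmax * times) / km)
  s_exact <- km * pracma::lambertWp(w_arg)
  expect_equal(got, s0 - s_exact, tolerance = 1e-6)
})

test_that("melt curve places its steepest ascent at the midpoint", {
  mc <- generate_melt_curve(64.87)
  d <- diff(mc$fluorescence) / diff(mc$temp_C)
  t_mid <- mc$temp_C[which.max(d)]
  expect_equal(t_mid, 64.87, tolerance = 0.5)

  # near-step transition still peaks at the midpoint
  steep <- generate_melt_curve(70, transition_slope = 0.05)
  d2 <- diff(steep$fluorescence) / diff(steep$temp_C)
  expect_equal(steep$temp_C[which.max(d2)], 70, tolerance = 0.5)

  expect_error(generate_melt_curve(110), "span")
  expect_error(generate_melt_curve(64, temps = c(60, 59, 70)), "ascending")

  # seeded determinism of the noisy curve
  n1 <- generate_melt_curve(64.87, noise_sd = 5, seed = 4)
  n2 <- generate_melt_curve(64.87, noise_sd = 5, seed = 4)
  expect_identical(n1, n2)
})
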