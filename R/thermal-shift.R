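# Melting-temperature extraction from dye-reported melt curves and the
# two-replicate thermal-shift classification.

#' Melting temperature from a melt curve's derivative peak
#'
#' Smooths the fluorescence trace with a local polynomial
#' (Savitzky-Golay) filter (window 9 points, order 2), takes centred finite
#' differences dF/dT, and locates the derivative maximum restricted to the
#' ascending transition (up to the global fluorescence maximum, which
#' excludes the post-peak dye-dissociation decay). The peak position is
#' refined by quadratic interpolation through the peak and its two
#' neighbours. The result is invariant to affine transforms of the
#' fluorescence axis. `single_peak` is FALSE when a second local derivative
#' maximum reaches at least half the main peak (multi-transition curve).
#'
#' @param curve Tibble with `temp_C` (strictly ascending) and `fluorescence`.
#' @param sg_window,sg_order Savitzky-Golay window (odd) and polynomial
#'   order.
#' @return Object of class `tm_result`: list with `tm`, `peak_height`
#'   (signal per deg C) and `single_peak`.
#' @examples
#' compute_tm(generate_melt_curve(64.87))
#' @export
compute_tm <- function(curve, sg_window = 9, sg_order = 2) {
  stopifnot(all(c("temp_C", "fluorescence") %in% names(curve)))
  tt <- curve$temp_C
  if (is.unsorted(tt, strictly = TRUE)) {
    abort("`temp_C` must be strictly ascending.")
  }
  if (length(tt) < sg_window + 2) abort("melt curve has too few points.")
  y <- signal::sgolayfilt(curve$fluorescence, p = sg_order, n = sg_window)
  n <- length(y)
  d <- c(NA, (y[3:n] - y[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)]), NA)
  # second smoothing pass on the derivative itself: halves the variance of
  # the peak location without visibly biasing the symmetric transition peak
  d[2:(n - 1)] <- signal::sgolayfilt(d[2:(n - 1)], p = sg_order, n = sg_window)
  ascent_end <- which.max(y)
  win <- seq(2, max(ascent_end, 3) - 1)
  dw <- d[win]
  if (all(!is.finite(dw)) || max(dw, na.rm = TRUE) <= 0 ||
      diff(range(y)) < 1e-8 * max(abs(y), 1)) {
    abort("no melting transition found (flat or monotone-decreasing curve).")
  }
  peak <- win[which.max(dw)]
  # quadratic refinement: least-squares parabola through the derivative peak
  # and its neighbours (up to +/- 3 grid points, symmetric), vertex = Tm
  half_w <- min(4, peak - 2, n - 1 - peak)
  tm <- tt[peak]; ph <- d[peak]
  if (half_w >= 1) {
    idx <- (peak - half_w):(peak + half_w)
    idx <- idx[is.finite(d[idx])]
    if (length(idx) >= 3) {
      x <- tt[idx] - tt[peak]
      fit <- lm(yy ~ x + I(x^2), data = list(yy = d[idx], x = x))
      cf <- coef(fit)
      if (is.finite(cf[3]) && cf[3] < 0) {
        vertex <- -cf[2] / (2 * cf[3])
        grid_step <- median(diff(tt[idx]))
        if (abs(vertex) <= 2 * grid_step) {
          tm <- unname(tt[peak] + vertex)
          ph <- unname(cf[1] - cf[2]^2 / (4 * cf[3]))
        }
      }
    }
  }
  # secondary transitions: local maxima of the derivative at >= 50% of the
  # main peak, at least 3 grid points away
  dmax <- d[peak]
  others <- which(vapply(win, function(i) {
    is.finite(d[i]) && d[i] >= 0.5 * dmax && abs(i - peak) > 3 &&
      i > 2 && i < n - 1 && d[i] >= d[i - 1] && d[i] >= d[i + 1]
  }, logical(1)))
  structure(list(tm = tm, peak_height = ph, single_peak = length(others) == 0),
            class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat("<tm_result> Tm =", sprintf("%.2f", x$tm), "degC",
      if (!x$single_peak) "(multiple transitions)" else "", "\n")
  invisible(x)
}

#' @rdname compute_tm
#' @param x A `tm_result`.
#' @param ... Unused.
#' @method tidy tm_result
#' @export
tidy.tm_result <- function(x, ...) {
  tibble(tm = x$tm, peak_height = x$peak_height, single_peak = x$single_peak)
}

#' Thermal shift relative to the plate-matched vehicle
#'
#' `delta_tm = sample_tm - mean(vehicle_tms)`. The vehicle reference is the
#' mean Tm of the DMSO wells of the same run.
#'
#' @param sample_tm Sample melting temperature (deg C).
#' @param vehicle_tms Vehicle melting temperatures (>= 1).
#' @return Thermal shift in deg C.
#' @examples
#' delta_tm(74.2, 64.87)
#' @export
delta_tm <- function(sample_tm, vehicle_tms) {
  if (length(vehicle_tms) < 1) abort("at least one vehicle Tm is required.")
  sample_tm - mean(vehicle_tms)
}

#' Classify a thermal shift from two replicates
#'
#' A compound is a significant stabiliser ("positive") when its thermal shift
#' exceeds `+sd_mult` vehicle SD in **both** replicates, a significant
#' destabiliser ("negative") when both replicates fall below `-sd_mult` SD,
#' and "none" otherwise.
#'
#' @param delta_tms Thermal shifts of the replicates (deg C), length >= 2.
#' @param vehicle_deltas Vehicle thermal-shift distribution (>= 8 values)
#'   from the same run, used to estimate the null SD.
#' @param sd_mult Significance multiple (default 3).
#' @return Object of class `shift_call`: list with `call`, `delta_tms`,
#'   `vehicle_sd`.
#' @export
classify_shift <- function(delta_tms, vehicle_deltas, sd_mult = 3) {
  if (length(vehicle_deltas) < 8) {
    abort("at least 8 vehicle wells are required to estimate the null SD.")
  }
  s <- sd(vehicle_deltas)
  call <- if (all(delta_tms > sd_mult * s)) "positive"
          else if (all(delta_tms < -sd_mult * s)) "negative"
          else "none"
  structure(list(call = call, delta_tms = delta_tms, vehicle_sd = s),
            class = "shift_call")
}

#' @export
print.shift_call <- function(x, ...) {
  cat("<shift_call>", x$call, " dTm =", paste(sprintf("%.2f", x$delta_tms), collapse = ", "),
      " vehicle SD =", sprintf("%.3f", x$vehicle_sd), "\n")
  invisible(x)
}

#' Saturable thermal-shift dose-response
#'
#' Least-squares fit of the single-site saturation model
#' `dTm(c) = dTm_max * c / (c + K)` to a concentration series, as used to
#' show dose-dependent and saturable stabilisation by reference ligands.
#'
#' @param data Tibble with `conc_M` and `delta_tm`.
#' @return Tibble with `dtm_max`, `k` (apparent dissociation constant,
#'   molar), `converged`.
#' @export
tm_dose_response <- function(data) {
  stopifnot(all(c("conc_M", "delta_tm") %in% names(data)))
  if (all(abs(data$delta_tm) < 1e-12)) {
    return(tibble(dtm_max = 0, k = NA_real_, converged = TRUE))
  }
  if (sd(data$delta_tm) < 1e-9) {
    # fully saturated series: the amplitude is the plateau, K unresolvable
    return(tibble(dtm_max = mean(data$delta_tm), k = NA_real_,
                  converged = TRUE))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      delta_tm ~ dmax * conc_M / (conc_M + k), data = data,
      start = list(dmax = max(data$delta_tm), k = median(data$conc_M)),
      lower = c(dmax = -50, k = .Machine$double.xmin),
      control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(tibble(dtm_max = NA_real_, k = NA_real_, converged = FALSE))
  p <- coef(fit)
  tibble(dtm_max = unname(p["dmax"]), k = unname(p["k"]), converged = TRUE)
}
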