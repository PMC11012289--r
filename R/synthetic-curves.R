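# Enzyme progress curves and protein melt curves.

#' Simulate a Michaelis-Menten progress curve
#'
#' Integrates the product-formation ODE `dP/dt = Vmax (S0 - P) / (Km + S0 - P)`
#' from `P(0) = 0` with a maximum integrator step of 0.1 min, evaluated at the
#' requested time points, then applies optional multiplicative noise. The
#' noise-free curve is monotone non-decreasing and bounded by `s0`.
#'
#' @param km Michaelis constant (molar), > 0.
#' @param vmax Maximal velocity (molar/min), > 0.
#' @param s0 Initial substrate concentration (molar), > 0.
#' @param times Ascending sampling times in minutes (may start at 0).
#' @param noise_cv Fractional multiplicative noise on the product readings.
#' @param seed Integer seed (used only when `noise_cv > 0`).
#' @return Tibble with `time` (min) and `product` (molar).
#' @examples
#' pc <- generate_progress_curve(36.6e-6, 1e-6, 36.6e-6, seq(0, 120, 5))
#' @export
generate_progress_curve <- function(km, vmax, s0, times,
                                    noise_cv = 0, seed = 1L) {
  if (!is_scalar_number(km) || km <= 0) abort("`km` must be positive.")
  if (!is_scalar_number(vmax) || vmax <= 0) abort("`vmax` must be positive.")
  if (!is_scalar_number(s0) || s0 <= 0) abort("`s0` must be positive.")
  if (is.unsorted(times, strictly = TRUE)) abort("`times` must be strictly ascending.")
  t_ode <- unique(c(0, times))
  sol <- deSolve::ode(
    y = c(P = 0),
    times = t_ode,
    func = function(t, y, parms) {
      s <- max(s0 - y[1], 0)
      list(vmax * s / (km + s))
    },
    parms = NULL, method = "lsoda", hmax = 0.1, maxsteps = 1e6
  )
  p <- approx(sol[, "time"], sol[, "P"], xout = times)$y
  p <- pmin(pmax(p, 0), s0)
  if (noise_cv > 0) {
    p <- with_seed(seed, p * (1 + noise_cv * rnorm(length(p))))
  }
  tibble(time = times, product = p)
}

# Closed-form Michaelis-Menten progress curve via the Lambert W function;
# kept internal as an independent cross-check of the integrator.
# S(t) = Km * W( (S0/Km) exp((S0 - Vmax t)/Km) ), P = S0 - S.

#' Simulate a thermal-melt fluorescence curve
#'
#' Two-state melt model read out by an environment-sensitive dye:
#' `F(T) = low(T) (1 - theta) + high(T) theta` with
#' `theta = logistic((T - tm)/transition_slope)`. The low baseline is the
#' folded-state signal, the high baseline the unfolded state; both may carry
#' linear slopes (a negative `high_slope` mimics post-transition dye
#' dissociation). On the noise-free curve with flat baselines the steepest
#' ascent sits exactly at `tm`.
#'
#' @param tm Melting temperature (deg C); must lie inside `temps`.
#' @param transition_slope Transition width parameter (deg C), > 0.
#' @param baselines List with `low_intercept`, `low_slope`, `high_intercept`,
#'   `high_slope` (slopes per deg C, relative to `tm` for the high baseline).
#' @param temps Strictly ascending temperature grid spanning `tm`.
#' @param noise_sd Additive Gaussian noise SD in signal units.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return Tibble with `temp_C` and `fluorescence`.
#' @examples
#' mc <- generate_melt_curve(64.87)
#' @export
generate_melt_curve <- function(tm, transition_slope = 1.5,
                                baselines = list(low_intercept = 100, low_slope = 0,
                                                 high_intercept = 1000, high_slope = 0),
                                temps = seq(25, 99, by = 0.5),
                                noise_sd = 0, seed = 1L) {
  if (is.unsorted(temps, strictly = TRUE)) abort("`temps` must be strictly ascending.")
  if (tm <= min(temps) || tm >= max(temps)) abort("`temps` must span `tm`.")
  if (transition_slope <= 0) abort("`transition_slope` must be positive.")
  theta <- plogis((temps - tm) / transition_slope)
  low <- baselines$low_intercept + baselines$low_slope * (temps - min(temps))
  high <- baselines$high_intercept + baselines$high_slope * (temps - tm)
  f <- low * (1 - theta) + high * theta
  if (noise_sd > 0) {
    f <- with_seed(seed, f + noise_sd * rnorm(length(f)))
  }
  tibble(temp_C = temps, fluorescence = f)
}
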