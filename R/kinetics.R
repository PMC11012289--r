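# Steady-state velocities from progress curves and Michaelis-Menten fits.

#' Steady-state (initial) velocity of a progress curve
#'
#' Fits a least-squares line through the points of the linear, early phase of
#' the reaction, defined as product below `max_depletion` of the initial
#' substrate (10% depletion by default, the standard initial-rate criterion).
#' If fewer than `min_points` points fall inside the window the first
#' `min_points` points are used instead and the result is flagged.
#'
#' @param curve Tibble with `time` (min) and `product` (same units as
#'   `substrate_conc`).
#' @param substrate_conc Initial substrate concentration.
#' @param max_depletion Fraction of substrate allowed to be consumed within
#'   the velocity window (default 0.1).
#' @param min_points Minimum number of points for the slope (default 4).
#' @return Object of class `ss_velocity`: list with `velocity`, `n_points`,
#'   `window_end` (last time used), `fallback`.
#' @export
steady_state_velocity <- function(curve, substrate_conc, max_depletion = 0.1,
                                  min_points = 4) {
  stopifnot(all(c("time", "product") %in% names(curve)))
  keep <- curve$product < max_depletion * substrate_conc
  fallback <- FALSE
  if (sum(keep) < min_points) {
    warn("fewer than `min_points` points inside the depletion window; using the earliest points.")
    keep <- seq_len(nrow(curve)) <= min_points
    fallback <- TRUE
  }
  pts <- curve[keep, ]
  v <- if (length(unique(pts$time)) < 2) 0 else unname(coef(lm(product ~ time, data = pts))[2])
  structure(
    list(velocity = v, n_points = nrow(pts), window_end = max(pts$time),
         fallback = fallback),
    class = "ss_velocity"
  )
}

#' @export
print.ss_velocity <- function(x, ...) {
  cat("steady-state velocity:", signif(x$velocity, 4),
      "per min over", x$n_points, "points",
      if (x$fallback) "(fallback window)" else "", "\n")
  invisible(x)
}

#' Fit the Michaelis-Menten model to velocity data
#'
#' Nonlinear least squares of `v = Vmax S / (Km + S)` (unweighted), with
#' starting values `Km0 = median(S)`, `Vmax0 = max(v)` and a relative
#' convergence tolerance of 1e-8. Warns when the tested concentrations do not
#' bracket the fitted Km, since the estimate is then poorly constrained.
#'
#' @param substrate_concs Substrate concentrations (molar), all positive,
#'   at least 4 distinct values.
#' @param velocities Matching reaction velocities.
#' @return Object of class `mm_fit` with `km`, `vmax`, `r_squared`,
#'   `converged` and the data. `tidy()` gives the parameters, `glance()` the
#'   fit summary, `autoplot()` the curve.
#' @examples
#' s <- 36.6e-6 * 2^((-3):4)
#' v <- 2 * s / (36.6e-6 + s)
#' fit_km(s, v)
#' @export
fit_km <- function(substrate_concs, velocities) {
  if (any(substrate_concs <= 0)) abort("substrate concentrations must be positive.")
  if (length(unique(substrate_concs)) < 4) {
    abort("at least 4 distinct substrate concentrations are required.")
  }
  dat <- tibble(s = substrate_concs, v = velocities)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ vmax * s / (km + s), data = dat,
      start = list(km = median(dat$s), vmax = max(dat$v)),
      lower = c(km = .Machine$double.xmin, vmax = .Machine$double.xmin),
      control = minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8, maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out <- list(km = NA_real_, vmax = NA_real_, r_squared = NA_real_,
                converged = FALSE, data = dat)
  } else {
    p <- coef(fit)
    ss_res <- sum(resid(fit)^2)
    ss_tot <- sum((dat$v - mean(dat$v))^2)
    out <- list(km = unname(p["km"]), vmax = unname(p["vmax"]),
                r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                converged = TRUE, data = dat)
    if (out$km < min(dat$s) || out$km > max(dat$s)) {
      warn("fitted Km lies outside the tested concentration range.")
    }
  }
  structure(out, class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit> Km =", signif(x$km, 4), "M, Vmax =", signif(x$vmax, 4),
      " R^2 =", signif(x$r_squared, 4), "\n")
  invisible(x)
}

#' @rdname fit_km
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(term = c("km", "vmax"), estimate = c(x$km, x$vmax))
}

#' @rdname fit_km
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(km = x$km, vmax = x$vmax, r_squared = x$r_squared,
         converged = x$converged, n = nrow(x$data))
}

#' @rdname fit_km
#' @param object An `mm_fit`.
#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble(s = exp(seq(log(min(object$data$s)), log(max(object$data$s)),
                             length.out = 100)))
  grid$v <- object$vmax * grid$s / (object$km + grid$s)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$s, .data$v)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[S] (M)", y = "velocity",
                  title = sprintf("Michaelis-Menten fit: Km = %.3g M", object$km))
}
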