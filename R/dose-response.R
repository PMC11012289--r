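# 4-parameter logistic concentration-response analysis with censoring,
# zinc-chelator deselection and Cheng-Prusoff utilities.

#' Build a geometric dilution series
#'
#' The default design is the 7-point, 3-fold series from a 20 uM top
#' concentration, whose bottom is 20 uM / 3^6 = 27.4 nM.
#'
#' @param top Top concentration (molar).
#' @param points Number of concentrations (>= 1).
#' @param fold Dilution factor between neighbours (> 1 unless `points` is 1).
#' @return Tibble with `point` (1 = top) and `conc_M`, descending.
#' @examples
#' build_dilution()
#' @export
build_dilution <- function(top = 20e-6, points = 7, fold = 3) {
  if (!is_scalar_number(top) || top <= 0) abort("`top` must be positive.")
  if (points < 1) abort("`points` must be >= 1.")
  tibble(point = seq_len(points), conc_M = top / fold^(seq_len(points) - 1))
}

#' Nominal assay concentration after an acoustic transfer
#'
#' `transfer_vol * stock / assay_vol`, with `assay_vol` the nominal final
#' assay volume (the nanolitre compound volume is not added). 40 nL of a
#' 2.00 mM stock into 4 uL gives a 20 uM top concentration.
#'
#' @param transfer_vol Transferred compound volume (litres).
#' @param stock Stock concentration (molar).
#' @param assay_vol Final assay volume (litres).
#' @return Concentration in molar.
#' @examples
#' nominal_conc(40e-9, 2e-3, 4e-6)
#' @export
nominal_conc <- function(transfer_vol, stock, assay_vol) {
  if (any(transfer_vol < 0) || any(stock < 0) || any(assay_vol <= 0)) {
    abort("volumes must be non-negative and `assay_vol` positive.")
  }
  transfer_vol * stock / assay_vol
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Fits `y = bottom + (top - bottom) / (1 + 10^((log10 IC50 - log10 c) h))`
#' to percent-inhibition data in log-concentration space, with soft plateau
#' bounds (bottom in \[-20, 20\]%, top in \[0, 120\]%, Hill slope in
#' \[0.3, 5\]) that stabilise sparse 7-point fits. The reported potency is
#' `pIC50 = -log10(IC50)`, rounded to 2 decimals.
#'
#' A fit is censored -- reported as below the lowest resolvable potency, e.g.
#' `"<4.70"` for a 20 uM top concentration -- when the fitted IC50 exceeds
#' the top tested concentration, when the maximal observed effect stays below
#' `min_max_effect`, or when the fit fails. Response series whose dynamic
#' range is smaller than `min_span` percentage points (flat curves, e.g.
#' concentration-independent optical artifacts) are unidentifiable and are
#' censored with `converged = FALSE`.
#'
#' @param data Tibble with `conc_M` (molar) and `response` (percent
#'   inhibition); at least 5 points.
#' @param min_max_effect Minimum maximal effect (percent) for a resolvable
#'   curve (default 50).
#' @param min_span Minimum response range (percentage points) for an
#'   identifiable fit (default 15).
#' @param weighting `"relative"` (default) weights residuals by
#'   `1 / max(response, 2)^2`, matching the constant-CV error structure of
#'   replicate percent-inhibition readouts; `"equal"` is ordinary least
#'   squares. Noise-free fits are identical under either choice.
#' @param bounds List overriding the plateau/slope bounds.
#' @return Object of class `fit4pl` with `pic50`, `pic50_label`, `censored`,
#'   `hill`, `top_plateau`, `bottom_plateau`, `max_effect`, `converged`.
#'   `tidy()` returns a one-row tibble; `autoplot()` draws the curve.
#' @export
fit_4pl <- function(data, min_max_effect = 50, min_span = 15,
                    weighting = c("relative", "equal"),
                    bounds = list(bottom = c(-20, 20), top = c(0, 120),
                                  hill = c(0.3, 5))) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("conc_M", "response") %in% names(data)))
  data <- data[order(data$conc_M), ]
  if (nrow(data) < 5) abort("at least 5 (conc, response) pairs are required.")
  if (any(data$conc_M <= 0)) abort("concentrations must be positive.")
  top_conc <- max(data$conc_M)
  censor_label <- sprintf("<%.2f", round(-log10(top_conc), 2))
  max_effect <- max(data$response)

  out <- list(pic50 = NA_real_, log_ic50 = NA_real_, pic50_label = censor_label,
              censored = TRUE,
              hill = NA_real_, top_plateau = NA_real_, bottom_plateau = NA_real_,
              max_effect = max_effect, converged = FALSE, data = data,
              top_conc = top_conc)
  class(out) <- "fit4pl"

  span <- diff(range(data$response))
  if (span < min_span) return(out)

  lx <- log10(data$conc_M)
  half <- (max(data$response) + min(data$response)) / 2
  start_l50 <- lx[which.min(abs(data$response - half))]
  # a start parameter sitting exactly at 0 can yield a singular numeric
  # Jacobian in the bounded Levenberg-Marquardt routine, so every candidate
  # start keeps parameters off 0 and we fall through a short start list
  top0 <- min(max(max(data$response), 20), bounds$top[2] - 1)
  starts <- list(
    list(bottom = 0.5, top = top0, l50 = start_l50, h = 1),
    list(bottom = 0.5, top = top0, l50 = start_l50 + 0.4, h = 1.3),
    list(bottom = -0.5, top = min(top0 + 10, bounds$top[2] - 1),
         l50 = start_l50 - 0.4, h = 0.7)
  )
  model_resp <- function(p) {
    p[1] + (p[2] - p[1]) / (1 + 10^((p[3] - lx) * p[4]))
  }
  lower <- c(bounds$bottom[1], bounds$top[1], min(lx) - 1, bounds$hill[1])
  upper <- c(bounds$bottom[2], bounds$top[2], max(lx) + 1, bounds$hill[2])
  run_lm <- function(st, w) {
    sw <- sqrt(w)
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = unlist(st), lower = lower, upper = upper,
        fn = function(p) sw * (data$response - model_resp(p)),
        control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                             maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(res) && !(res$info %in% c(1, 2, 3, 4))) res <- NULL
    res
  }
  # stage 1: ordinary least squares, walking a short start list; stage 2:
  # weighted refinement seeded at the OLS solution (for noise-free data the
  # zero-residual optimum is shared, so refinement is a no-op there)
  fit <- NULL
  for (st in starts) {
    cand <- run_lm(st, rep(1, nrow(data)))
    if (!is.null(cand) && (is.null(fit) || cand$deviance < fit$deviance)) {
      fit <- cand
    }
  }
  if (is.null(fit)) return(out)
  if (weighting == "relative") {
    w <- 1 / pmax(data$response, 2)^2
    refit <- run_lm(as.list(fit$par), w)
    if (!is.null(refit)) fit <- refit
  }

  p <- setNames(fit$par, c("bottom", "top", "l50", "h"))
  ic50 <- 10^unname(p["l50"])
  out$converged <- TRUE
  out$log_ic50 <- unname(p["l50"])
  out$hill <- unname(p["h"])
  out$top_plateau <- unname(p["top"])
  out$bottom_plateau <- unname(p["bottom"])
  out$censored <- ic50 > top_conc || max_effect < min_max_effect
  if (!out$censored) {
    out$pic50 <- round(-log10(ic50), 2)
    out$pic50_label <- sprintf("%.2f", out$pic50)
  }
  out
}

#' @export
print.fit4pl <- function(x, ...) {
  cat("<fit4pl> pIC50 ", x$pic50_label,
      if (!x$censored) sprintf(" (hill %.2f, max effect %.0f%%)", x$hill, x$max_effect)
      else " (censored)", "\n", sep = "")
  invisible(x)
}

#' @rdname fit_4pl
#' @param x A `fit4pl`.
#' @param ... Unused.
#' @method tidy fit4pl
#' @export
tidy.fit4pl <- function(x, ...) {
  tibble(pic50 = x$pic50, log_ic50 = x$log_ic50,
         pic50_label = x$pic50_label, censored = x$censored,
         hill = x$hill, top_plateau = x$top_plateau,
         bottom_plateau = x$bottom_plateau, max_effect = x$max_effect,
         converged = x$converged)
}

#' @rdname fit_4pl
#' @param object A `fit4pl`.
#' @method autoplot fit4pl
#' @export
autoplot.fit4pl <- function(object, ...) {
  d <- object$data
  pl <- ggplot2::ggplot(d, ggplot2::aes(.data$conc_M, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (M)", y = "% inhibition",
                  title = paste("pIC50", object$pic50_label))
  if (object$converged && !object$censored) {
    grid <- tibble(conc_M = 10^seq(log10(min(d$conc_M)), log10(max(d$conc_M)),
                                   length.out = 120))
    grid$response <- object$bottom_plateau +
      (object$top_plateau - object$bottom_plateau) /
      (1 + 10^((-object$pic50 - log10(grid$conc_M)) * object$hill))
    pl <- pl + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  pl
}

#' Fit concentration-response curves for a table of reads
#'
#' Convenience wrapper running [fit_4pl()] per compound and assay.
#'
#' @param reads Tibble with `compound_id`, `assay`, `conc_M`,
#'   `pct_inhibition`.
#' @param ... Passed to [fit_4pl()].
#' @return Tibble with one row per compound x assay and the [tidy.fit4pl()]
#'   columns.
#' @export
fit_drc <- function(reads, ...) {
  if (nrow(reads) == 0) {
    return(tibble(compound_id = character(0), assay = character(0),
                  pic50 = numeric(0), log_ic50 = numeric(0),
                  pic50_label = character(0), censored = logical(0),
                  hill = numeric(0), top_plateau = numeric(0),
                  bottom_plateau = numeric(0), max_effect = numeric(0),
                  converged = logical(0)))
  }
  reads %>%
    rename(response = "pct_inhibition") %>%
    group_by(.data$compound_id, .data$assay) %>%
    dplyr::group_modify(function(d, key) tidy(fit_4pl(d, ...))) %>%
    ungroup()
}

#' Zinc-chelation deselection call
#'
#' A compound's activity is "lost" in the zinc-supplemented counter-screen
#' when it passed the potency gate in the plain fluorescence assay but is
#' censored (unresolvable potency) with zinc present -- the signature of
#' inhibition purely through metal chelation. Compounds that never passed the
#' gate are "retained" (nothing to lose). A resolved-but-weakened zinc curve
#' (potency drop of at least `drop_flag` log units) is flagged as advisory
#' without changing the call.
#'
#' @param pic50_fluor,pic50_zinc Numeric pIC50 values, NA where censored.
#' @param gate Potency gate (default 4.7).
#' @param drop_flag Advisory potency-drop threshold in log units.
#' @return Tibble with `status` ("retained"/"lost") and `drop_flagged`.
#' @examples
#' zinc_deselect(c(6.5, 5.9, NA), c(6.5, NA, NA))
#' @export
zinc_deselect <- function(pic50_fluor, pic50_zinc, gate = 4.7, drop_flag = 0.5) {
  gated_in <- !is.na(pic50_fluor) & pic50_fluor >= gate
  lost <- gated_in & is.na(pic50_zinc)
  drop <- gated_in & !is.na(pic50_zinc) &
    (pic50_fluor - pic50_zinc >= drop_flag)
  tibble(status = ifelse(lost, "lost", "retained"), drop_flagged = drop)
}

#' Theoretical inter-assay pIC50 shift for competitive inhibitors
#'
#' Under the Cheng-Prusoff relation `IC50 = Ki (1 + [S]/Km)`, running the
#' same competitive inhibitor in two assays with different substrate loads
#' shifts its measured pIC50 by
#' `log10((1 + [S]_b/Km) / (1 + [S]_a/Km))` -- the potency excess of assay
#' `a` over assay `b`. For the standard pairing of a fluorescence assay at
#' `[S] = Km` and an absorbance assay at `[S] = 2.6 Km` the shift is 0.2553,
#' printed as 0.26. Non-competitive inhibitors show no shift.
#'
#' @param s_over_km_a,s_over_km_b Substrate-to-Km ratios of the two assays.
#' @return The pIC50 difference (assay a minus assay b) in log10 units.
#' @examples
#' cheng_prusoff_shift(1, 2.6)
#' @export
cheng_prusoff_shift <- function(s_over_km_a, s_over_km_b) {
  if (any(s_over_km_a < 0) || any(s_over_km_b < 0)) {
    abort("substrate ratios must be non-negative.")
  }
  log10((1 + s_over_km_b) / (1 + s_over_km_a))
}

#' Convert pIC50 to IC50
#'
#' @param pic50 Potency as -log10(IC50 in molar).
#' @param unit Output unit: `"M"`, `"uM"` or `"nM"`.
#' @return IC50 in the requested unit.
#' @examples
#' pic50_to_ic50(6.5, "uM")
#' @export
pic50_to_ic50 <- function(pic50, unit = c("M", "uM", "nM")) {
  unit <- match.arg(unit)
  10^(-pic50) / switch(unit, M = 1, uM = 1e-6, nM = 1e-9)
}
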