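# Weighted Henderson-Hasselbalch fitting of the I-state fraction versus
# pH, and two-state spectral unmixing.

#' Henderson-Hasselbalch fraction
#'
#' Fraction of the deprotonated (I) species at a given pH for a single
#' protonation site: `1 / (1 + 10^(pka - ph))`. Monotone increasing in
#' pH, equals 0.5 at `ph == pka`.
#'
#' @param ph pH value(s).
#' @param pka Acid dissociation midpoint.
#' @return Fraction(s) in (0, 1).
#' @export
hh_fraction <- function(ph, pka) {
  1 / (1 + 10^(pka - ph))
}

validate_titration <- function(data) {
  stopifnot(is.data.frame(data), all(c("ph", "fraction") %in% names(data)))
  if (any(data$ph < 2 | data$ph > 12)) {
    stop("pH outside the physically sensible range [2, 12]")
  }
  if (any(data$fraction < 0 | data$fraction > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  if ("sd" %in% names(data) && any(!is.na(data$sd) & data$sd <= 0)) {
    stop("per-point sd must be positive where given")
  }
  invisible(data)
}

#' Read a titration table from CSV
#'
#' Expects columns `ph`, `fraction` and optionally `sd` (per-point
#' standard deviation of the fraction) and `replicate`.
#'
#' @param path CSV file path.
#' @return Validated data.frame.
#' @export
read_titration_csv <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_titration(data)
}

#' Fit the pKa of a titration by weighted least squares
#'
#' Minimizes `sum(w * (fraction - hh_fraction(ph, pka))^2)` over the
#' single parameter pKa (Hill coefficient fixed at 1, i.e. one
#' protonation site). Weights are `1/sd^2` where per-point standard
#' deviations are given, 1 otherwise. The pKa uncertainty comes from the
#' curvature of the objective at the optimum: with the analytic
#' sensitivity `d f / d pKa = -ln(10) f (1 - f)`, the 1-sigma error is
#' `sqrt(s2 / sum(w g^2))` with `s2` the weighted residual variance.
#'
#' @param data data.frame with `ph`, `fraction` and optional `sd`.
#' @return Object of class `titration_fit`: `pka`, `pka_sd`,
#'   `residual_sum` (weighted), `n`, `fitted_curve` (function pH ->
#'   fraction) and the input `data`.
#' @export
fit_pka <- function(data) {
  validate_titration(data)
  ph <- data$ph
  f <- data$fraction
  if (length(unique(ph)) < 3) {
    stop("need at least 3 distinct pH values spanning the transition")
  }
  w <- if ("sd" %in% names(data) && all(!is.na(data$sd)) && all(data$sd > 0)) {
    1 / data$sd^2
  } else {
    rep(1, length(f))
  }
  if (max(f) <= 0.1 || min(f) >= 0.9) {
    stop("non-identifiable titration: the sampled pH range does not span ",
         "the transition (all fractions near 0 or near 1)")
  }
  objective <- function(pka) sum(w * (f - hh_fraction(ph, pka))^2)
  opt <- stats::optimize(objective, interval = c(min(ph) - 3, max(ph) + 3),
                         tol = 1e-10)
  pka <- opt$minimum
  fitted <- hh_fraction(ph, pka)
  g <- -log(10) * fitted * (1 - fitted)
  s2 <- opt$objective / max(length(f) - 1, 1)
  pka_sd <- sqrt(s2 / sum(w * g^2))
  structure(
    list(pka = pka, pka_sd = pka_sd, residual_sum = opt$objective,
         n = length(f),
         fitted_curve = function(ph) hh_fraction(ph, pka),
         data = data),
    class = "titration_fit"
  )
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("<titration_fit> pKa =", sprintf("%.3f +/- %.3f", x$pka, x$pka_sd),
      sprintf("(n = %d, weighted RSS = %.4g)\n", x$n, x$residual_sum))
  invisible(x)
}

#' Two-state fraction from peak absorbances
#'
#' Linear unmixing of a two-state spectrum from the A-band and I-band
#' peak absorbances: `fraction = (A_I / r) / (A_I / r + A_A)` where
#' `r = eps_I / eps_A` is the ratio of the two states' extinction
#' coefficients at their peaks (default 1, configurable).
#'
#' @param abs_a_peak Absorbance at the A-state peak (~395 nm), >= 0.
#' @param abs_i_peak Absorbance at the I-state peak (~499 nm), >= 0.
#' @param eps_ratio Extinction-coefficient ratio eps_I / eps_A.
#' @return I-state fraction in \[0, 1\].
#' @export
fraction_from_spectra <- function(abs_a_peak, abs_i_peak, eps_ratio = 1) {
  stopifnot(all(abs_a_peak >= 0), all(abs_i_peak >= 0), eps_ratio > 0)
  if (any(abs_a_peak == 0 & abs_i_peak == 0)) {
    stop("undefined fraction: both peak absorbances are zero")
  }
  reduced_i <- abs_i_peak / eps_ratio
  reduced_i / (reduced_i + abs_a_peak)
}
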