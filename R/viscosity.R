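#' Power-law fit of a rate constant versus viscosity
#'
#' Fits `k = A * eta^(-delta)` to a series of (viscosity, rate) points by
#' nonlinear least squares in natural space, warm-started from the exact
#' log-log linear solution.  A positive `delta` near 1 is the signature of
#' a diffusion-limited step; `delta > 1` indicates an overdamped
#' (stronger-than-diffusion) viscosity effect.
#'
#' @param eta viscosities, cP (positive), or a data frame with columns
#'   `eta` (or `eta_cP`) and `k` (or `k_value`).
#' @param k rate-constant (or empirical-parameter) values, positive; omit
#'   when `eta` is a data frame.
#' @return Class `"powerlaw_fit"`: list with `A`, `delta`, `se_A`,
#'   `se_delta`, `r_squared`, `n`, `eta`, `k`, `fitted`.
#' @examples
#' eta <- seq(1, 6, length.out = 24)
#' fit_power_law(eta, 2 * eta^-1)        # A = 2, delta = 1
#' @export
fit_power_law <- function(eta, k = NULL) {
  if (is.data.frame(eta)) {
    df <- eta
    nm <- names(df)
    ec <- intersect(c("eta", "eta_cP"), nm)[1]
    kc <- intersect(c("k", "k_value"), nm)[1]
    if (is.na(ec) || is.na(kc))
      stop_lux("data frame must have columns eta/eta_cP and k/k_value")
    eta <- df[[ec]]; k <- df[[kc]]
  }
  eta <- as.numeric(eta); k <- as.numeric(k)
  if (length(eta) != length(k)) stop_lux("eta and k must have equal length")
  if (length(eta) < 3L)
    stop_lux("at least 3 points are needed for a power-law fit")
  if (any(eta <= 0) || any(k <= 0))
    stop_lux("eta and k must be positive")

  # exact solution on log-log axes as warm start
  wf <- lm(log(k) ~ log(eta))
  A0 <- exp(unname(coef(wf)[1])); d0 <- -unname(coef(wf)[2])

  df <- data.frame(eta = eta, k = k)
  fit <- tryCatch(
    minpack.lm::nlsLM(k ~ A * eta^(-delta), data = df,
                      start = list(A = A0, delta = d0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) ||
      sum((k - predict(fit))^2) > sum((k - A0 * eta^(-d0))^2)) {
    # warm start already (near-)exact: keep it, with log-space errors
    sw <- suppressWarnings(summary(wf))$coefficients
    cf <- c(A = A0, delta = d0)
    se <- c(A = A0 * sw[1, 2], delta = sw[2, 2])
    yhat <- A0 * eta^(-d0)
  } else {
    cf <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit))),
                   error = function(e) c(A = NA, delta = NA))
    yhat <- predict(fit)
  }
  tss <- sum((k - mean(k))^2)
  structure(list(A = unname(cf[["A"]]), delta = unname(cf[["delta"]]),
                 se_A = unname(se[["A"]]), se_delta = unname(se[["delta"]]),
                 r_squared = if (tss > 0) 1 - sum((k - yhat)^2) / tss else NA,
                 n = length(k), eta = eta, k = k, fitted = as.numeric(yhat)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power-law fit  k = A * eta^(-delta),  n = %d\n", x$n))
  cat(sprintf("  A     = %.5g (se %.3g)\n", x$A, x$se_A))
  cat(sprintf("  delta = %.4f (se %.3g),  R^2 = %.4f\n",
              x$delta, x$se_delta, x$r_squared))
  cat(sprintf("  regime: %s\n", classify_diffusion_control(x)))
  invisible(x)
}

#' @export
plot.powerlaw_fit <- function(x, ..., log = "xy") {
  plot(x$eta, x$k, log = log, xlab = "viscosity (cP)", ylab = "k", ...)
  o <- order(x$eta)
  lines(x$eta[o], x$fitted[o], col = 2, lwd = 2)
  invisible(x)
}

#' Classify the viscosity dependence of a rate constant
#'
#' Given a fitted exponent `delta` of `k = A * eta^(-delta)`:
#' `delta < tol` means the step is viscosity-independent; exponents up to
#' `1 + tol` indicate diffusion limitation (power-law decay with
#' `delta ~ 1`); larger exponents indicate an overdamped effect, stronger
#' than diffusion control.
#'
#' @param fit a [fit_power_law()] result, or a bare numeric `delta`.
#' @param tol classification half-width (default 0.25).
#' @return One of `"viscosity_independent"`, `"diffusion_limited"`,
#'   `"overdamped"`.
#' @examples
#' classify_diffusion_control(1.0)   # diffusion_limited
#' classify_diffusion_control(1.8)   # overdamped
#' @export
classify_diffusion_control <- function(fit, tol = 0.25) {
  delta <- if (inherits(fit, "powerlaw_fit")) fit$delta else as.numeric(fit)
  if (delta < tol) "viscosity_independent"
  else if (delta <= 1 + tol) "diffusion_limited"
  else "overdamped"
}

#' Mole fractions of a binary water-cosolvent mixture
#'
#' @param wt_percent cosolvent mass fraction, percent (0-100).
#' @param molar_mass cosolvent molar mass, g/mol.
#' @return Named vector `c(x_w, x_s)` of water and cosolvent mole
#'   fractions (water molar mass 18.015 g/mol).
#' @examples
#' mole_fractions(30, 342.3)   # 30 wt % sucrose
#' @export
mole_fractions <- function(wt_percent, molar_mass) {
  if (molar_mass <= 0) stop_lux("molar_mass must be positive")
  if (wt_percent < 0 || wt_percent > 100)
    stop_lux("wt_percent must be in [0, 100]")
  ns <- wt_percent / molar_mass
  nw <- (100 - wt_percent) / 18.015
  c(x_w = nw / (nw + ns), x_s = ns / (nw + ns))
}

#' Norrish water activity of a cosolvent solution
#'
#' The Norrish model corrects Raoult's law for non-ideal mixing:
#' `a_w = x_w * exp(kN * x_s^2)`, where `x_w` and `x_s` are the mole
#' fractions of water and cosolvent and `kN` is the empirical Norrish
#' constant of the cosolvent (negative `kN` depresses water activity below
#' the ideal mole-fraction value, positive `kN` raises it).
#'
#' @param kN Norrish constant, dimensionless.
#' @param x_s cosolvent mole fraction; either give `x_s` directly or
#'   `wt_percent` + `molar_mass`.
#' @param wt_percent,molar_mass alternative mass-based specification.
#' @return Water activity `a_w` (single number in `[0, ~1]`).
#' @examples
#' norrish_water_activity(kN = -2.0, x_s = 0.1)     # 0.9 * exp(-0.02)
#' norrish_water_activity(kN = -6.47, wt_percent = 30, molar_mass = 342.3)
#' @export
norrish_water_activity <- function(kN, x_s = NULL, wt_percent = NULL,
                                   molar_mass = NULL) {
  if (is.null(x_s)) {
    if (is.null(wt_percent) || is.null(molar_mass))
      stop_lux("give either x_s or both wt_percent and molar_mass")
    x_s <- mole_fractions(wt_percent, molar_mass)[["x_s"]]
  }
  if (x_s < 0 || x_s > 1) stop_lux("x_s must be in [0, 1]")
  (1 - x_s) * exp(kN * x_s^2)
}

#' Pearson correlation between a rate constant and a cosolvent property
#'
#' Thin, validated wrapper around the product-moment correlation used for
#' relating the catalytic constant to cosolvent-water interaction
#' parameters (Norrish constants, van der Waals energies per molecule).
#'
#' @param x,y equal-length numeric series, `n >= 3`.
#' @param labels optional character pair naming the series.
#' @return Class `"correlation_result"`: list with `r`, `n`, `labels`.
#' @examples
#' correlate(1:5, 2 * (1:5) + 1)$r   # 1
#' @export
correlate <- function(x, y, labels = c("x", "y")) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_lux("x and y must have equal length")
  if (length(x) < 3L) stop_lux("at least 3 paired points are needed")
  if (sd(x) == 0 || sd(y) == 0)
    stop_lux("correlation undefined: zero variance in one of the series")
  structure(list(r = cor(x, y), n = length(x), labels = labels),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r(%s, %s) = %.4f  (n = %d)\n",
              x$labels[1], x$labels[2], x$r, x$n))
  invisible(x)
}
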