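#' Elementary rate constants of the single-turnover scheme
#'
#' Bundles the seven elementary rate constants of the bacterial-luciferase
#' reaction scheme together with the intensity scale factor that converts
#' the photon emission rate `k4 * [Intermediate IIA]` into instrument units.
#'
#' @param k1 flavin (FMNH2) binding rate, 1/(M s); Intermediate I formation.
#' @param k2 pseudo-first-order oxygen binding rate, 1/s (air-equilibrated
#'   dissolved oxygen is in excess and folded into the constant);
#'   Intermediate II (peroxyflavin) formation.
#' @param k3 aldehyde (decanal) binding rate, 1/(M s); Intermediate IIA
#'   formation.
#' @param k_minus3 aldehyde dissociation rate from Intermediate IIA, 1/s.
#' @param k4 catalytic constant, 1/s: formation and decay of the excited
#'   emitter (Intermediate III is not resolved as a separate state).
#' @param kd apparent autoxidation rate of free FMNH2, 1/s.
#' @param kdd dark-decay rate of the peroxyflavin Intermediate II, 1/s.
#' @param scale nonnegative intensity scale factor, a.u. s / M, absorbing
#'   quantum yield and instrument gain.
#'
#' @return A named numeric vector of class `"lux_rates"`.
#' @seealso [michaelis_constants()], [lux_simulate()], [luxfit()]
#' @examples
#' r <- lux_rates(k1 = 1e6, k2 = 1.5, k3 = 1e5, k_minus3 = 2.4,
#'                k4 = 0.6, kd = 0.3, kdd = 0.05, scale = 1e9)
#' michaelis_constants(r)
#' @export
lux_rates <- function(k1, k2, k3, k_minus3, k4, kd, kdd, scale = 1) {
  r <- c(k1 = k1, k2 = k2, k3 = k3, k_minus3 = k_minus3, k4 = k4,
         kd = kd, kdd = kdd, scale = scale)
  if (!is.numeric(r) || length(r) != 8L || anyNA(r) || any(!is.finite(r)))
    stop_lux("all rate constants must be finite numbers")
  if (any(r < 0))
    stop_lux("rate constants and scale must be nonnegative; got negative ",
             paste(names(r)[r < 0], collapse = ", "))
  structure(r, class = "lux_rates")
}

#' Default ground-truth rate constants for synthetic studies
#'
#' A fixed, realistic parameter set used by the synthetic-data generators.
#' The values give flash-like 15 s curves under the standard post-mix
#' concentrations (luciferase 1 uM, FMNH2 15 uM, decanal 10-50 uM), with
#' Michaelis constants KM_F = k2/k1 = 1.5 uM and
#' KM_a = (k_minus3 + k4)/k3 = 30 uM, inside the windows reported for the
#' enzyme in buffer (1-2 uM and 25-50 uM).
#'
#' @return A `"lux_rates"` object.
#' @examples
#' lux_default_rates()
#' @export
lux_default_rates <- function() {
  lux_rates(k1 = 1e6, k2 = 1.5, k3 = 1e5, k_minus3 = 2.4, k4 = 0.6,
            kd = 0.30, kdd = 0.05, scale = 1e9)
}

#' @export
print.lux_rates <- function(x, ...) {
  cat("Elementary rate constants of the luciferase single-turnover scheme\n")
  u <- c(k1 = "1/(M s)", k2 = "1/s", k3 = "1/(M s)", k_minus3 = "1/s",
         k4 = "1/s", kd = "1/s", kdd = "1/s", scale = "a.u. s/M")
  for (nm in names(u))
    cat(sprintf("  %-9s %12.5g  %s\n", nm, unclass(x)[[nm]], u[[nm]]))
  invisible(x)
}

#' Initial (post-mixing) concentrations for a single-turnover run
#'
#' Concentrations after stopped-flow mixing; all reaction intermediates and
#' the oxidized-flavin / product sinks start at zero.
#'
#' @param L0 free luciferase.
#' @param F0 free reduced flavin (FMNH2).
#' @param A0 free decanal.
#' @param units `"uM"` (default, the usual experimental unit) or `"M"`.
#'   Values are stored internally in M.
#' @return A named numeric vector (`L0`, `F0`, `A0`, in M) of class
#'   `"lux_init"`.
#' @examples
#' lux_init()                    # 1, 15, 50 uM: the standard assay
#' lux_init(1, 15, 20)           # lower decanal
#' @export
lux_init <- function(L0 = 1, F0 = 15, A0 = 50, units = c("uM", "M")) {
  units <- match.arg(units)
  x <- c(L0 = L0, F0 = F0, A0 = A0)
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0))
    stop_lux("initial concentrations must be finite and nonnegative")
  if (units == "uM") x <- x * 1e-6
  structure(x, class = "lux_init")
}

#' @export
print.lux_init <- function(x, ...) {
  cat("Post-mix initial concentrations (uM):\n")
  print(round(unclass(x) * 1e6, 6))
  invisible(x)
}

#' Michaelis constants from elementary rate constants
#'
#' The Michaelis constant of luciferase for reduced flavin is
#' `KM_F = k2 / k1` and for the aldehyde `KM_a = (k_minus3 + k4) / k3`.
#' With `k2` a pseudo-first-order constant (1/s) both values are molar.
#'
#' @param rates a [lux_rates()] object (or named vector with the same fields).
#' @return Named numeric vector `c(KM_F, KM_a)` in M.
#' @examples
#' michaelis_constants(lux_default_rates()) * 1e6   # in uM
#' @export
michaelis_constants <- function(rates) {
  r <- unclass(rates)
  if (r[["k1"]] <= 0 || r[["k3"]] <= 0)
    stop_lux("k1 and k3 must be positive to form Michaelis constants")
  c(KM_F = r[["k2"]] / r[["k1"]],
    KM_a = (r[["k_minus3"]] + r[["k4"]]) / r[["k3"]])
}
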