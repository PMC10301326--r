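#' Mass-action right-hand side of the single-turnover scheme
#'
#' Time derivatives of the eight-species state of the bacterial-luciferase
#' reaction: free luciferase `L` binds FMNH2 `F` (rate `k1`) to give
#' Intermediate I `I1`, which binds dissolved oxygen (pseudo-first-order
#' `k2`) to give the peroxyflavin Intermediate II `I2`.  `I2` either decays
#' in the dark (`kdd`) or binds decanal `A` (`k3`, reversible with
#' `k_minus3`) to give Intermediate IIA `I2A`, which emits through the
#' catalytic step `k4`.  Free FMNH2 is autoxidized with `kd` into the
#' oxidized-flavin sink `Fox`; `P` is the product sink.  Luciferase is
#' recycled after both the dark decay and the emission step.
#'
#' This pure-R form documents the equations and backs the compiled version
#' used by [lux_simulate()].
#'
#' @param state named numeric vector with elements
#'   `L, F, I1, I2, I2A, A, Fox, P` (concentrations, M).
#' @param rates a [lux_rates()] object.
#' @return Named numeric vector of derivatives, M/s, in the same order.
#' @examples
#' st <- c(L = 1e-6, F = 1.5e-5, I1 = 0, I2 = 0, I2A = 0, A = 5e-5,
#'         Fox = 0, P = 0)
#' lux_ode_rhs(st, lux_default_rates())
#' @export
lux_ode_rhs <- function(state, rates) {
  if (anyNA(state) || any(!is.finite(state)))
    stop_lux("state must be finite")
  if (any(state < 0))
    stop_lux("state concentrations must be nonnegative")
  r <- unclass(lux_rates_check(rates))
  s <- state[lux_species]
  bindLF <- r[["k1"]] * s[["L"]] * s[["F"]]
  bindA  <- r[["k3"]] * s[["I2"]] * s[["A"]]
  c(L   = -bindLF + r[["kdd"]] * s[["I2"]] + r[["k4"]] * s[["I2A"]],
    F   = -bindLF - r[["kd"]] * s[["F"]],
    I1  =  bindLF - r[["k2"]] * s[["I1"]],
    I2  =  r[["k2"]] * s[["I1"]] - bindA + r[["k_minus3"]] * s[["I2A"]] -
           r[["kdd"]] * s[["I2"]],
    I2A =  bindA - (r[["k_minus3"]] + r[["k4"]]) * s[["I2A"]],
    A   = -bindA + r[["k_minus3"]] * s[["I2A"]],
    Fox =  r[["kd"]] * s[["F"]] + r[["kdd"]] * s[["I2"]],
    P   =  r[["k4"]] * s[["I2A"]])
}

lux_species <- c("L", "F", "I1", "I2", "I2A", "A", "Fox", "P")

lux_rates_check <- function(rates) {
  if (inherits(rates, "lux_rates")) return(rates)
  r <- unlist(rates)
  do.call(lux_rates, as.list(r[c("k1", "k2", "k3", "k_minus3", "k4",
                                 "kd", "kdd",
                                 if ("scale" %in% names(r)) "scale")]))
}

#' Integrate the full reaction trajectory
#'
#' Solves the single-turnover ODE system with deSolve's stiff-capable
#' `lsoda` integrator (compiled right-hand side), returning all species.
#'
#' @param rates a [lux_rates()] object.
#' @param init a [lux_init()] object (or named vector `L0`, `F0`, `A0`, M).
#' @param t time grid, s; strictly increasing from 0.
#' @param rtol,atol solver tolerances; `atol` defaults to `1e-12 * F0`.
#' @param check if `TRUE` (default) verify flavin/aldehyde conservation to
#'   relative `1e-6` and nonnegativity within solver tolerance.
#' @return Matrix with columns `time` and the eight species (M).
#' @examples
#' tr <- lux_trajectory(lux_default_rates(), lux_init(), seq(0, 15, 0.1))
#' head(tr)
#' @export
lux_trajectory <- function(rates, init, t = seq(0, 15, length.out = 1000),
                           rtol = 1e-8, atol = NULL, check = TRUE) {
  r <- unclass(lux_rates_check(rates))
  ic <- unclass(init)
  if (!all(c("L0", "F0", "A0") %in% names(ic)))
    stop_lux("init must provide L0, F0, A0")
  if (any(ic < 0)) stop_lux("initial concentrations must be nonnegative")
  if (t[1] != 0 || any(diff(t) <= 0))
    stop_lux("t must start at 0 and be strictly increasing")
  if (is.null(atol)) atol <- 1e-12 * max(ic[["F0"]], 1e-9)
  y0 <- setNames(c(ic[["L0"]], ic[["F0"]], 0, 0, 0, ic[["A0"]], 0, 0),
                 lux_species)
  out <- deSolve::ode(y = y0, times = t, func = "lux_derivs",
                      parms = unname(r[1:7]), dllname = "luxkin",
                      initfunc = "lux_initmod", method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop_lux("ODE integration failed (istate = ", attr(out, "istate")[1],
             "); try a coarser grid or looser tolerances")
  out <- unclass(out)
  if (check) lux_check_trajectory(out, ic)
  out
}

lux_check_trajectory <- function(out, ic) {
  F0 <- ic[["F0"]]; A0 <- ic[["A0"]]
  flavin <- rowSums(out[, c("F", "I1", "I2", "I2A", "Fox", "P"), drop = FALSE])
  ald <- rowSums(out[, c("A", "I2A", "P"), drop = FALSE])
  if (F0 > 0 && max(abs(flavin - F0)) > 1e-6 * F0)
    warning("flavin mass conservation violated beyond 1e-6 relative",
            call. = FALSE)
  if (A0 > 0 && max(abs(ald - A0)) > 1e-6 * A0)
    warning("aldehyde mass conservation violated beyond 1e-6 relative",
            call. = FALSE)
  if (min(out[, lux_species]) < -1e-9 * max(F0, A0))
    warning("negative concentrations beyond solver tolerance", call. = FALSE)
  invisible(out)
}

#' Simulate a flash-like bioluminescence intensity curve
#'
#' Integrates the reaction scheme and returns the light intensity
#' `y(t) = scale * k4 * [Intermediate IIA](t)`, the photon emission rate in
#' instrument units.
#'
#' @inheritParams lux_trajectory
#' @param meta extra condition labels stored on the returned curve.
#' @return A [lux_curve()] with `signal = "bioluminescence"`; the full
#'   species trajectory is attached as attribute `"trajectory"`.
#' @examples
#' cv <- lux_simulate(lux_default_rates(), lux_init(A0 = 50))
#' plot(cv)
#' @export
lux_simulate <- function(rates, init, t = seq(0, 15, length.out = 1000),
                         rtol = 1e-8, atol = NULL, check = TRUE,
                         meta = list()) {
  r <- unclass(lux_rates_check(rates))
  out <- lux_trajectory(rates, init, t, rtol = rtol, atol = atol,
                        check = check)
  y <- r[["scale"]] * r[["k4"]] * pmax(out[, "I2A"], 0)
  ic <- unclass(init)
  meta <- modifyList(list(decanal_uM = ic[["A0"]] * 1e6), meta)
  cv <- lux_curve(out[, "time"], y, "bioluminescence", meta)
  attr(cv, "trajectory") <- out
  cv
}

#' Closed-form Bateman solution for a linear four-step chain
#'
#' Analytic concentration of the fourth species of the irreversible
#' sequential first-order chain `F -> I1 -> I2 -> I2A -> P` with rates
#' `a, b, c, k4`, starting from `F(0) = F0` and all else zero.  Used as an
#' independent oracle for the numerical integrator in the pseudo-first-order
#' limit (luciferase and aldehyde in large excess, no side decays).
#'
#' @param a,b,c,k4 chain rates, 1/s; positive and pairwise distinct.
#' @param F0 initial concentration of the first species, M.
#' @param t time(s), s (vectorized).
#' @return `I2A(t)` in M.
#' @examples
#' bateman_i2a(5, 100, 1, 0.5, 1e-6, 1)
#' @export
bateman_i2a <- function(a, b, c, k4, F0, t) {
  lam <- c(a, b, c, k4)
  if (any(lam <= 0)) stop_lux("all chain rates must be positive")
  if (min(abs(diff(sort(lam)))) < 1e-12 * max(lam))
    stop_lux("chain rates must be pairwise distinct ",
             "(perturb degenerate rates slightly)")
  acc <- 0
  for (i in 1:4) acc <- acc + exp(-lam[i] * t) / prod(lam[-i] - lam[i])
  F0 * a * b * c * acc
}
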