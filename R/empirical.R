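#' Empirical parameters of a flash-like bioluminescence curve
#'
#' A flash-like single-turnover curve is conventionally summarized by four
#' empirical quantities: the peak intensity `Imax`, the exponential decay
#' constant of the final phase `k_decay`, the initial velocity `v0` (slope
#' of the starting linear part) and the total quantum yield `Qstar` (area
#' under the curve).
#'
#' @param curve a [lux_curve()].
#' @param v0_window optional `c(t_start, t_end)` for the initial slope; by
#'   default from `t = 0` until the signal first reaches 20% of `Imax`.
#' @param decay_window optional `c(t_start, t_end)` for the exponential
#'   tail; default `[t_peak + 2 s, end of trace]`.
#' @param baseline constant baseline subtracted from `y` before analysis
#'   (default 0, i.e. raw intensities).
#' @return Class `"empirical_params"`: list with `Imax`, `k_decay`, `v0`,
#'   `Qstar` and the windows actually used.
#' @examples
#' cv <- lux_simulate(lux_default_rates(), lux_init())
#' empirical_params(cv)
#' @export
empirical_params <- function(curve, v0_window = NULL, decay_window = NULL,
                             baseline = 0) {
  stopifnot(inherits(curve, "lux_curve"))
  if (baseline != 0)
    curve <- lux_curve(curve$t, curve$y - baseline, curve$signal, curve$meta)
  ip <- which.max(curve$y)
  if (is.null(decay_window))
    decay_window <- c(curve$t[ip] + 2, curve$t[length(curve$t)])
  v0 <- initial_velocity(curve, v0_window)
  structure(list(
    Imax = peak_intensity(curve),
    k_decay = decay_constant(curve, decay_window),
    v0 = v0,
    Qstar = total_quantum_yield(curve),
    v0_window = attr(v0, "window"),
    decay_window = decay_window),
    class = "empirical_params")
}

#' @export
print.empirical_params <- function(x, ...) {
  cat("Empirical flash-curve parameters:\n")
  cat(sprintf("  Imax    = %.5g a.u.\n", x$Imax))
  cat(sprintf("  k_decay = %.5g 1/s   (window %.3g-%.3g s)\n",
              x$k_decay, x$decay_window[1], x$decay_window[2]))
  cat(sprintf("  v0      = %.5g a.u./s (window %.3g-%.3g s)\n",
              x$v0, x$v0_window[1], x$v0_window[2]))
  cat(sprintf("  Q*      = %.5g a.u. s\n", x$Qstar))
  invisible(x)
}

#' @rdname empirical_params
#' @export
peak_intensity <- function(curve) {
  stopifnot(inherits(curve, "lux_curve"))
  max(curve$y)
}

#' @rdname empirical_params
#' @details `Qstar` is the trapezoidal integral of `y` over `t`.
#' @export
total_quantum_yield <- function(curve) {
  stopifnot(inherits(curve, "lux_curve"))
  sum(diff(curve$t) * (head(curve$y, -1) + tail(curve$y, -1)) / 2)
}

#' @rdname empirical_params
#' @param window `c(t_start, t_end)` in s, or `NULL` for the default.
#' @export
initial_velocity <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "lux_curve"))
  if (is.null(window)) {
    thr <- 0.2 * max(curve$y)
    iend <- which(curve$y >= thr)[1]
    iend <- max(iend, 5L)
    window <- c(curve$t[1], curve$t[min(iend, length(curve$t))])
  }
  sel <- curve$t >= window[1] & curve$t <= window[2]
  if (sum(sel) < 5L)
    stop_lux("initial-velocity window contains fewer than 5 points")
  tt <- curve$t[sel]; yy <- curve$y[sel]
  slope <- sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  structure(slope, window = range(tt))
}

#' @rdname empirical_params
#' @details `k_decay` is obtained by linear regression of `log(y)` on `t`
#'   within the tail window (the tail of a flash curve is strictly
#'   positive); `decay_constant()` returns the negated slope.
#' @export
decay_constant <- function(curve, window) {
  stopifnot(inherits(curve, "lux_curve"))
  sel <- curve$t >= window[1] & curve$t <= window[2]
  if (sum(sel) < 3L)
    stop_lux("decay window contains fewer than 3 points")
  yy <- curve$y[sel]
  if (any(yy <= 0))
    stop_lux("decay window contains nonpositive intensities; ",
             "narrow the window or subtract the baseline")
  -unname(coef(lm(log(yy) ~ curve$t[sel]))[2])
}
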