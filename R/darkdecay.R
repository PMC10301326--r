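#' Windowed exponential fit of an absorbance trace
#'
#' Fits `A(t) = offset + amplitude * exp(-k * t)` within a time window by
#' nonlinear least squares with a log-linear warm start (plateau estimated
#' from the window tail, then `log|A - offset|` regressed on `t`).  This is
#' the procedure used to turn absorbance kinetics into apparent first-order
#' constants; it is deliberately phenomenological - flavin autoxidation is
#' a multi-stage autocatalytic chain, and the windowed exponential is only
#' its local approximation.
#'
#' @param trace a [lux_curve()] with an absorbance signal.
#' @param window `c(t_start, t_end)`, s.
#' @return Class `"absorbance_fit"`: list with `k` (1/s), `amplitude` (AU,
#'   signed: negative for rising segments), `offset` (AU), `window`,
#'   `residual_norm`.
#' @examples
#' t <- seq(0, 60, 0.1)
#' tr <- lux_curve(t, 0.3 + 0.2 * exp(-0.05 * t), "absorbance_380")
#' fit_exp_window(tr, c(0, 60))$k
#' @export
fit_exp_window <- function(trace, window) {
  stopifnot(inherits(trace, "lux_curve"))
  sel <- trace$t >= window[1] & trace$t <= window[2]
  if (sum(sel) < 5L)
    stop_lux("window [", window[1], ", ", window[2],
             "] contains fewer than 5 points")
  tt <- trace$t[sel]; yy <- trace$y[sel]

  # warn when the smoothed segment both rises and falls appreciably
  # (interior extrema beyond what noise on a monotone trend would give)
  ks <- max(3L, length(yy) %/% 20)
  ys <- stats::filter(yy, rep(1 / ks, ks), sides = 2)
  ys <- ys[!is.na(ys)]
  rng <- diff(range(ys))
  if (rng > 0 &&
      (max(ys) - max(ys[1], ys[length(ys)]) > 0.2 * rng ||
       min(ys[1], ys[length(ys)]) - min(ys) > 0.2 * rng))
    warning("segment in window [", window[1], ", ", window[2],
            "] is non-monotone; the exponential approximation may be poor",
            call. = FALSE)

  # log-linear warm start: plateau from the last 20% of the window
  ntail <- max(3L, ceiling(0.2 * length(yy)))
  off0 <- mean(tail(yy, ntail))
  dy <- yy - off0
  s <- sign(dy[1])
  if (s == 0) s <- sign(mean(head(dy, 5)))
  pos <- s * dy > 0
  if (sum(pos) >= 3) {
    wf <- lm(log(s * dy[pos]) ~ tt[pos])
    k0 <- max(-unname(coef(wf)[2]), 1e-6)
    a0 <- s * exp(unname(coef(wf)[1]))
  } else {
    k0 <- 1 / max(diff(range(tt)), 1e-6)
    a0 <- dy[1]
  }

  df <- data.frame(tt = tt, yy = yy)
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ off + amp * exp(-k * tt), data = df,
                      start = list(off = off0, amp = a0, k = k0),
                      lower = c(-Inf, -Inf, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("nonlinear refinement failed; returning the log-linear ",
            "warm-start estimate", call. = FALSE)
    cf <- c(off = off0, amp = a0, k = k0)
    rn <- sqrt(sum((yy - off0 - a0 * exp(-k0 * tt))^2))
  } else {
    cf <- coef(fit)
    rn <- sqrt(sum(resid(fit)^2))
  }
  structure(list(k = unname(cf[["k"]]),
                 amplitude = unname(cf[["amp"]]),
                 offset = unname(cf[["off"]]),
                 window = range(tt),
                 residual_norm = rn),
            class = "absorbance_fit")
}

#' @export
print.absorbance_fit <- function(x, ...) {
  cat(sprintf(paste0("<absorbance_fit> k = %.5g 1/s, amplitude = %.4g AU, ",
                     "offset = %.4g AU, window %.3g-%.3g s\n"),
              x$k, x$amplitude, x$offset, x$window[1], x$window[2]))
  invisible(x)
}

#' Apparent flavin autoxidation constant from a 445 nm trace
#'
#' The absorbance change of flavin at 445 nm after mixing reduced FMN with
#' aerated buffer is approximated by exponential functions over two time
#' ranges; the slow-window constant is reported as the apparent
#' autoxidation rate `kd`.
#'
#' @param trace_445 a [lux_curve()] with `signal = "absorbance_445"`.
#' @param window_fast,window_slow disjoint `c(t_start, t_end)` windows, s.
#' @return List with elements `fast` and `slow` ([fit_exp_window()]
#'   results) and `kd` (the slow-window rate, 1/s).
#' @examples
#' t <- seq(0, 60, 0.05)
#' tr <- lux_curve(t, 0.4 - 0.15 * exp(-1.5 * t) - 0.1 * exp(-0.2 * t),
#'                 "absorbance_445")
#' fit_kd(tr, c(0, 2), c(8, 60))$kd
#' @export
fit_kd <- function(trace_445, window_fast, window_slow) {
  if (max(window_fast) > min(window_slow) && max(window_slow) > min(window_fast))
    if (min(max(window_fast), max(window_slow)) >
        max(min(window_fast), min(window_slow)))
      stop_lux("fast and slow windows must be disjoint")
  fast <- fit_exp_window(trace_445, window_fast)
  slow <- fit_exp_window(trace_445, window_slow)
  list(fast = fast, slow = slow, kd = slow$k)
}

#' Peroxyflavin dark-decay constant from a 380 nm trace
#'
#' Single-window exponential fit of the Intermediate II decay recorded as
#' the absorbance change at 380 nm.
#'
#' @param trace_380 a [lux_curve()] with `signal = "absorbance_380"`.
#' @param window `c(t_start, t_end)`, s.
#' @return An [fit_exp_window()] result; its `k` is the apparent `kdd`.
#' @examples
#' t <- seq(0, 120, 0.5)
#' tr <- lux_curve(t, 0.05 + 0.2 * exp(-0.05 * t), "absorbance_380")
#' fit_kdd(tr, c(0, 120))$k
#' @export
fit_kdd <- function(trace_380, window) {
  fit_exp_window(trace_380, window)
}
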