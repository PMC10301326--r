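#' Sampled kinetic curve
#'
#' Container for a time-resolved signal: a bioluminescence intensity trace
#' or an absorbance trace at 445 nm (flavin) or 380 nm (peroxyflavin).
#'
#' @param t time grid, s; strictly increasing, starting at 0 (a nonzero
#'   start is allowed for windows cut from a longer trace).
#' @param y signal values, same length as `t` (a.u. or AU).
#' @param signal one of `"bioluminescence"`, `"absorbance_445"`,
#'   `"absorbance_380"`.
#' @param meta named list of condition labels (e.g. `decanal_uM`,
#'   `cosolvent`, `wt_percent`, `viscosity_cP`).
#' @return An object of class `"lux_curve"`: a list with elements `t`, `y`,
#'   `signal`, `meta`.
#' @examples
#' cv <- lux_curve(seq(0, 15, 0.015), rep(1, 1001))
#' cv
#' @export
lux_curve <- function(t, y,
                      signal = c("bioluminescence", "absorbance_445",
                                 "absorbance_380"),
                      meta = list()) {
  signal <- match.arg(signal)
  t <- as.numeric(t); y <- as.numeric(y)
  if (length(t) != length(y))
    stop_lux("t and y must have equal length")
  if (length(t) < 2L)
    stop_lux("a kinetic curve needs at least 2 points")
  if (anyNA(t) || anyNA(y) || any(!is.finite(t)) || any(!is.finite(y)))
    stop_lux("t and y must be finite")
  if (any(diff(t) <= 0))
    stop_lux("time grid must be strictly increasing (first violation at row ",
             which(diff(t) <= 0)[1] + 1L, ")")
  structure(list(t = t, y = y, signal = signal, meta = meta),
            class = "lux_curve")
}

#' @export
print.lux_curve <- function(x, ...) {
  cat(sprintf("<lux_curve> %s, %d points, t = [%g, %g] s\n",
              x$signal, length(x$t), x$t[1], x$t[length(x$t)]))
  if (length(x$meta))
    cat("  ", paste(names(x$meta), unlist(x$meta), sep = " = ",
                    collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
plot.lux_curve <- function(x, ...,
                           xlab = "time (s)",
                           ylab = if (x$signal == "bioluminescence")
                             "intensity (a.u.)" else "absorbance (AU)",
                           type = "l") {
  plot(x$t, x$y, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
as.data.frame.lux_curve <- function(x, ...) {
  data.frame(time_s = x$t,
             y = x$y,
             check.names = FALSE)
}

#' Five-curve single-turnover dataset
#'
#' Validates a set of flash curves that share all conditions except the
#' aldehyde (decanal) concentration, the input expected by [luxfit()].
#'
#' @param curves list of [lux_curve()] objects (bioluminescence), each with
#'   `meta$decanal_uM` set.
#' @param L0,F0 shared post-mix luciferase and FMNH2 concentrations, uM.
#' @return Class `"lux_dataset"`: the list of curves with attributes
#'   `L0`/`F0` (in M) and `decanal_uM`.
#' @examples
#' synth <- generate_bioluminescence_dataset(seed = 1)
#' ds <- synth$curves
#' length(ds); attr(ds, "decanal_uM")
#' @export
lux_dataset <- function(curves, L0 = 1, F0 = 15) {
  if (!is.list(curves) || !length(curves) ||
      !all(vapply(curves, inherits, logical(1), "lux_curve")))
    stop_lux("curves must be a list of lux_curve objects")
  if (!all(vapply(curves, function(cv) cv$signal == "bioluminescence",
                  logical(1))))
    stop_lux("all curves in a dataset must be bioluminescence traces")
  ald <- vapply(curves, function(cv) {
    a <- cv$meta$decanal_uM
    if (is.null(a)) NA_real_ else as.numeric(a)
  }, numeric(1))
  if (anyNA(ald))
    stop_lux("every curve needs meta$decanal_uM")
  if (anyDuplicated(ald))
    stop_lux("aldehyde concentrations must be distinct across curves")
  structure(unname(curves), class = "lux_dataset",
            L0 = L0 * 1e-6, F0 = F0 * 1e-6, decanal_uM = unname(ald))
}

#' @export
print.lux_dataset <- function(x, ...) {
  cat(sprintf(paste0("<lux_dataset> %d single-turnover curves, ",
                     "L0 = %g uM, F0 = %g uM\n"),
              length(x), attr(x, "L0") * 1e6, attr(x, "F0") * 1e6))
  cat("  decanal (uM):", paste(attr(x, "decanal_uM"), collapse = ", "), "\n")
  invisible(x)
}
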