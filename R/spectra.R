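#' Fluorescence emission spectrum
#'
#' Tryptophan emission spectrum of the enzyme collected in the
#' 305-450 nm range (excitation 295 nm), assumed already corrected for
#' instrument sensitivity, inner-filter effect and background.
#'
#' @param lambda wavelengths, nm, strictly increasing within `[305, 450]`.
#' @param intensity nonnegative intensities, a.u., with at least one
#'   positive value.
#' @param condition label (cosolvent / concentration).
#' @return Class `"emission_spectrum"`: list with `lambda`, `intensity`,
#'   `condition`.
#' @examples
#' sp <- emission_spectrum(305:450, dnorm(305:450, 344, 20))
#' gravity_center(sp)
#' @export
emission_spectrum <- function(lambda, intensity, condition = "") {
  lambda <- as.numeric(lambda); intensity <- as.numeric(intensity)
  if (length(lambda) != length(intensity))
    stop_lux("lambda and intensity must have equal length")
  if (any(diff(lambda) <= 0))
    stop_lux("lambda must be strictly increasing")
  if (min(lambda) < 305 || max(lambda) > 450)
    stop_lux("wavelengths must lie within the 305-450 nm collection range")
  if (any(intensity < 0)) stop_lux("intensities must be nonnegative")
  if (all(intensity == 0)) stop_lux("spectrum must have a positive value")
  structure(list(lambda = lambda, intensity = intensity,
                 condition = condition),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %d points, %g-%g nm, GC = %.2f nm%s\n",
              length(x$lambda), min(x$lambda), max(x$lambda),
              gravity_center(x),
              if (nzchar(x$condition)) paste0(" [", x$condition, "]") else ""))
  invisible(x)
}

#' @export
plot.emission_spectrum <- function(x, ...,
                                   xlab = "wavelength (nm)",
                                   ylab = "intensity (a.u.)", type = "l") {
  plot(x$lambda, x$intensity, type = type, xlab = xlab, ylab = ylab, ...)
  abline(v = gravity_center(x), lty = 2)
  invisible(x)
}

#' Gravity center of an emission spectrum
#'
#' The intensity-weighted mean emission wavelength, computed as the
#' discrete sum `GC = sum(I * lambda) / sum(I)` over the stored grid
#' (no interpolation).
#'
#' @param spec an [emission_spectrum()].
#' @return Gravity center, nm.
#' @examples
#' gravity_center(emission_spectrum(305:450, rep(1, 146)))   # 377.5
#' @export
gravity_center <- function(spec) {
  stopifnot(inherits(spec, "emission_spectrum"))
  s <- sum(spec$intensity)
  if (s == 0) stop_lux("gravity center undefined for an all-zero spectrum")
  sum(spec$intensity * spec$lambda) / s
}

#' Spectral shift between two conditions
#'
#' Difference of gravity centers, `GC(b) - GC(a)`; a negative value is a
#' hypsochromic (blue) shift of condition `b` relative to `a`.
#'
#' @param spec_a,spec_b [emission_spectrum()] objects (reference first).
#' @return Shift in nm.
#' @examples
#' a <- emission_spectrum(305:450, dnorm(305:450, 344, 15))
#' b <- emission_spectrum(305:450, dnorm(305:450, 342, 15))
#' spectral_shift(a, b)   # about -2 nm (hypsochromic)
#' @export
spectral_shift <- function(spec_a, spec_b) {
  gravity_center(spec_b) - gravity_center(spec_a)
}
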