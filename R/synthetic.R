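#' Measurement-noise model for synthetic traces
#'
#' Noise applied to a noise-free signal `y`:
#' `y_obs = y * (1 + e_m) + e_a + baseline`, with `e_m` i.i.d. Gaussian of
#' relative standard deviation `multiplicative` and `e_a` i.i.d. Gaussian
#' of absolute standard deviation `additive` (by default 0.1% of the peak
#' signal, a small instrument floor).  Defaults emulate the residual
#' scatter of curves averaged over several stopped-flow repeats.
#'
#' @param multiplicative relative Gaussian noise fraction (default 0.02).
#' @param additive absolute noise s.d., a.u.; `NULL` (default) means
#'   0.1% of the peak of each noise-free curve.
#' @param baseline constant offset added to the signal, a.u.
#' @param seed integer seed.
#' @return Class `"noise_model"` list.
#' @examples
#' noise_model()                       # the standard 2% model
#' noise_model(multiplicative = 0)    # noise-free
#' @export
noise_model <- function(multiplicative = 0.02, additive = NULL,
                        baseline = 0, seed = 1) {
  if (multiplicative < 0 || (!is.null(additive) && additive < 0))
    stop_lux("noise standard deviations must be nonnegative")
  structure(list(multiplicative = multiplicative, additive = additive,
                 baseline = baseline, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(y, noise) {
  add <- if (is.null(noise$additive)) 0.001 * max(abs(y)) else noise$additive
  y * (1 + rnorm(length(y), 0, noise$multiplicative)) +
    rnorm(length(y), 0, add) + noise$baseline
}

#' Generate a synthetic five-curve single-turnover dataset
#'
#' Simulates flash-like bioluminescence curves at several decanal
#' concentrations from known ground-truth rate constants and adds seeded
#' measurement noise; the generating parameters are returned alongside so
#' that downstream fits can be scored against the truth.
#'
#' @param rates ground-truth [lux_rates()]; default [lux_default_rates()].
#' @param L0,F0 post-mix luciferase and FMNH2 concentrations, uM
#'   (defaults 1 and 15).
#' @param aldehyde_uM decanal concentrations, uM; default
#'   `c(10, 20, 30, 40, 50)`.
#' @param t shared time grid, s; default 1000 points over 15 s.
#' @param noise a [noise_model()]; its `seed` governs all randomness.
#' @param seed convenience override for `noise$seed`.
#' @return List with `curves` (a [lux_dataset()]) and `truth` (list of
#'   the generating `rates`, `L0`, `F0`, `aldehyde_uM`, `noise`, plus the
#'   noise-free curves as `clean`).
#' @examples
#' synth <- generate_bioluminescence_dataset(seed = 42)
#' synth$curves
#' @export
generate_bioluminescence_dataset <- function(rates = lux_default_rates(),
                                             L0 = 1, F0 = 15,
                                             aldehyde_uM = c(10, 20, 30, 40, 50),
                                             t = seq(0, 15, length.out = 1000),
                                             noise = noise_model(),
                                             seed = NULL) {
  if (!is.null(seed)) noise$seed <- as.integer(seed)
  clean <- lapply(aldehyde_uM, function(a)
    lux_simulate(rates, lux_init(L0, F0, a, units = "uM"), t))
  curves <- with_seed(noise$seed, lapply(seq_along(clean), function(i) {
    cv <- clean[[i]]
    lux_curve(cv$t, apply_noise(cv$y, noise), "bioluminescence", cv$meta)
  }))
  list(curves = lux_dataset(curves, L0 = L0, F0 = F0),
       truth = list(rates = rates, L0 = L0, F0 = F0,
                    aldehyde_uM = aldehyde_uM, noise = noise,
                    clean = clean))
}

#' Generate a synthetic absorbance trace with known components
#'
#' Mono- or bi-exponential trace plus offset, the functional form used to
#' emulate the 445 nm (flavin autoxidation) and 380 nm (peroxyflavin
#' decay) dark-decay measurements.
#'
#' @param kind `"mono"` or `"bi"`.
#' @param k rate constant(s), 1/s (length 1 or 2 according to `kind`).
#' @param amplitude signed amplitude(s), AU (negative for rising traces).
#' @param offset plateau absorbance, AU.
#' @param t time grid, s.
#' @param noise a [noise_model()] (applied as for intensity curves).
#' @param signal `"absorbance_445"` or `"absorbance_380"`.
#' @return List with `trace` (a [lux_curve()]) and `truth`.
#' @examples
#' g <- generate_absorbance_trace("mono", k = 0.2, amplitude = -0.2,
#'                                offset = 0.4)
#' plot(g$trace)
#' @export
generate_absorbance_trace <- function(kind = c("mono", "bi"), k,
                                      amplitude, offset = 0,
                                      t = seq(0, 60, 0.05),
                                      noise = noise_model(multiplicative = 0,
                                                          additive = 0),
                                      signal = c("absorbance_445",
                                                 "absorbance_380")) {
  kind <- match.arg(kind); signal <- match.arg(signal)
  nterm <- if (kind == "mono") 1L else 2L
  if (length(k) != nterm || length(amplitude) != nterm)
    stop_lux("kind = '", kind, "' needs ", nterm, " rate(s) and amplitude(s)")
  if (any(k <= 0)) stop_lux("rates must be positive")
  y <- offset
  for (j in seq_len(nterm)) y <- y + amplitude[j] * exp(-k[j] * t)
  yn <- with_seed(noise$seed, apply_noise(y, noise))
  list(trace = lux_curve(t, yn, signal),
       truth = list(kind = kind, k = k, amplitude = amplitude,
                    offset = offset, noise = noise))
}

#' Generate a synthetic rate-versus-viscosity series
#'
#' Points `k_i = A * eta_i^(-delta) * (1 + e_i)` with seeded Gaussian
#' relative noise, emulating a measured viscosity dependence of a rate
#' constant over the 1-6 cP range accessible with cosolvents.
#'
#' @param A amplitude (value of `k` at 1 cP).
#' @param delta power-law exponent (positive for decaying dependence).
#' @param eta viscosities, cP; default 24 points uniform over 1-6 cP.
#' @param noise_fraction relative Gaussian noise (default 0.05).
#' @param seed integer seed.
#' @return List with `points` (data frame `eta`, `k`) and `truth`.
#' @examples
#' s <- generate_viscosity_series(A = 0.35, delta = 0.84, seed = 3)
#' fit_power_law(s$points)
#' @export
generate_viscosity_series <- function(A, delta,
                                      eta = seq(1, 6, length.out = 24),
                                      noise_fraction = 0.05, seed = 1) {
  if (A <= 0 || any(eta <= 0)) stop_lux("A and eta must be positive")
  if (noise_fraction < 0) stop_lux("noise_fraction must be nonnegative")
  k <- with_seed(seed,
                 A * eta^(-delta) * (1 + rnorm(length(eta), 0, noise_fraction)))
  list(points = data.frame(eta = eta, k = k),
       truth = list(A = A, delta = delta, noise_fraction = noise_fraction,
                    seed = as.integer(seed)))
}

#' Generate a synthetic Gaussian emission band
#'
#' Gaussian band sampled on the 305-450 nm grid, a stand-in for tryptophan
#' emission spectra when testing gravity-center analysis.
#'
#' @param peak_nm band center, nm.
#' @param width_nm Gaussian standard deviation, nm.
#' @param lambda wavelength grid, nm (default `305:450`).
#' @param noise_sd additive Gaussian noise, a.u. (negative values are
#'   clipped to keep intensities valid).
#' @param seed integer seed.
#' @param condition label stored on the spectrum.
#' @return An [emission_spectrum()].
#' @examples
#' gravity_center(generate_spectrum(344, 20))
#' @export
generate_spectrum <- function(peak_nm = 344, width_nm = 20,
                              lambda = 305:450, noise_sd = 0, seed = 1,
                              condition = "") {
  if (width_nm < 0) stop_lux("width_nm must be nonnegative")
  I <- if (width_nm == 0) as.numeric(lambda == lambda[which.min(abs(lambda - peak_nm))])
       else exp(-(lambda - peak_nm)^2 / (2 * width_nm^2))
  if (noise_sd > 0)
    I <- with_seed(seed, pmax(I + rnorm(length(I), 0, noise_sd), 0))
  emission_spectrum(lambda, I, condition)
}
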