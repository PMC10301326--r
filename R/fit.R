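#' Pooled relative least-squares error between model and data curves
#'
#' The fit-quality measure used throughout the package:
#' `100 * ||y_model - y_data||_2 / ||y_data||_2`, pooled over all curves of
#' a dataset (and reported per curve as well).
#'
#' @param model list of model [lux_curve()]s (or numeric vectors).
#' @param data list of data [lux_curve()]s (or numeric vectors) on the same
#'   grids.
#' @return List with `pooled` (percent) and `per_curve` (percent vector).
#' @examples
#' a <- list(c(1, 2, 3)); b <- list(c(1, 2, 3) * 1.01)
#' pooled_relative_error(b, a)$pooled   # 1%
#' @export
pooled_relative_error <- function(model, data) {
  if (inherits(model, "lux_curve")) model <- list(model)
  if (inherits(data, "lux_curve")) data <- list(data)
  ym <- lapply(model, function(m) if (inherits(m, "lux_curve")) m$y else as.numeric(m))
  yd <- lapply(data, function(d) if (inherits(d, "lux_curve")) d$y else as.numeric(d))
  if (length(ym) != length(yd))
    stop_lux("model and data must contain the same number of curves")
  if (!all(lengths(ym) == lengths(yd)))
    stop_lux("model and data curves must share grids")
  ssd <- sum(unlist(yd)^2)
  if (ssd == 0) stop_lux("relative error undefined for all-zero data")
  per <- mapply(function(m, d) {
    dd <- sum(d^2)
    if (dd == 0) NA_real_ else 100 * sqrt(sum((m - d)^2) / dd)
  }, ym, yd)
  pooled <- 100 * sqrt(sum(unlist(mapply(`-`, ym, yd, SIMPLIFY = FALSE))^2) / ssd)
  list(pooled = pooled, per_curve = as.numeric(per))
}

# Default log10-space box constraints for the free rate constants,
# bracketing literature magnitudes for flavin monooxygenases.
lux_default_bounds <- function() {
  list(lower = c(k1 = 1e4, k2 = 1e0, k3 = 1e4, k_minus3 = 1e-3, k4 = 1e-3),
       upper = c(k1 = 1e9, k2 = 1e4, k3 = 1e9, k_minus3 = 1e2, k4 = 1e2))
}

# Model intensities (before scaling) for all curves of a dataset.
lux_model_matrix <- function(p, dataset, kd, kdd) {
  L0 <- attr(dataset, "L0"); F0 <- attr(dataset, "F0")
  ald <- attr(dataset, "decanal_uM") * 1e-6
  lapply(seq_along(dataset), function(i) {
    r <- lux_rates(p[["k1"]], p[["k2"]], p[["k3"]], p[["k_minus3"]],
                   p[["k4"]], kd, kdd, scale = 1)
    ic <- structure(c(L0 = L0, F0 = F0, A0 = ald[i]), class = "lux_init")
    out <- lux_trajectory(r, ic, dataset[[i]]$t, check = FALSE)
    p[["k4"]] * pmax(out[, "I2A"], 0)
  })
}

# Residual vector for the optimizer: theta is log10 of the free rates;
# the shared intensity scale is profiled out in closed form (the model is
# linear in it).
lux_residuals_log10 <- function(theta, dataset, kd, kdd) {
  p <- setNames(10^theta, names(theta))
  # silence solver chatter at pathological parameter corners; failures
  # there are handled by the penalty branch below
  utils::capture.output(
    m <- tryCatch(suppressWarnings(lux_model_matrix(p, dataset, kd, kdd)),
                  error = function(e) NULL))
  yd <- unlist(lapply(dataset, `[[`, "y"))
  if (is.null(m))
    return(structure(rep(1e6, length(yd)), scale = 0))
  ym <- unlist(m)
  den <- sum(ym^2)
  sc <- if (den > 0) max(sum(ym * yd) / den, 0) else 0
  res <- sc * ym - yd
  attr(res, "scale") <- sc
  res
}

#' Globally fit elementary rate constants to a single-turnover dataset
#'
#' Fits `k1, k2, k3, k_minus3, k4` (plus one shared intensity scale) to a
#' set of flash-like bioluminescence curves recorded at several decanal
#' concentrations, by bound-constrained nonlinear least squares in
#' log10-parameter space with multi-start.  The two dark-decay constants
#' `kd` and `kdd` are always fixed, mirroring the experimental design in
#' which they are measured in dedicated absorbance experiments.  The scale
#' factor is linear in the model and solved in closed form at every
#' objective evaluation, so the optimizer works in five dimensions.
#'
#' @param dataset a [lux_dataset()] (typically five curves at decanal
#'   10-50 uM sharing `L0`, `F0`).
#' @param kd fixed FMNH2 autoxidation constant, 1/s.
#' @param kdd fixed peroxyflavin dark-decay constant, 1/s.
#' @param n_starts number of local least-squares refinements.  Starting
#'   points are chosen by coarse screening: the objective is evaluated on
#'   `n_screen` seeded log-uniform draws within the bounds plus `start`
#'   (or the geometric center of the bounds), and the `n_starts` best
#'   candidates are refined with Levenberg-Marquardt.
#' @param n_screen size of the screening cloud (default `16 * n_starts`).
#' @param seed integer seed making the start draws (and hence the whole
#'   fit) deterministic.
#' @param lower,upper named bounds on the natural scale for the five free
#'   rates; defaults bracket literature magnitudes
#'   (`k1, k3` in `[1e4, 1e9]` 1/(M s), `k2` in `[1, 1e4]` 1/s,
#'   `k_minus3, k4` in `[1e-3, 1e2]` 1/s).
#' @param start optional named vector of initial values (natural scale).
#' @param control passed to [minpack.lm::nls.lm.control()]; default
#'   `maxiter = 120`.
#' @return An object of class `"luxfit"` with components `rates`
#'   (fitted [lux_rates()], including the fixed `kd`, `kdd` and the
#'   profiled `scale`), `rel_error` (pooled and per-curve percent),
#'   `rss`, `se_log10` (approximate standard errors of the log10 rates),
#'   `max_correlation` (largest pairwise parameter correlation),
#'   `identifiable` (flags rates determined to better than a factor 10 and
#'   not fully correlated with another rate),
#'   `starts` (per-start summary), `best_start`, `convergence`, `dataset`,
#'   and the call.  Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`, `simulate`, `vcov`.
#' @examples
#' \donttest{
#' synth <- generate_bioluminescence_dataset(seed = 7,
#'           t = seq(0, 15, length.out = 400))
#' fit <- luxfit(synth$curves, kd = 0.30, kdd = 0.05, n_starts = 4, seed = 1)
#' summary(fit)
#' }
#' @export
luxfit <- function(dataset, kd, kdd, n_starts = 16, n_screen = 16 * n_starts,
                   seed = 1, lower = NULL, upper = NULL, start = NULL,
                   control = list()) {
  if (!inherits(dataset, "lux_dataset"))
    stop_lux("dataset must be a lux_dataset (see lux_dataset())")
  if (missing(kd) || missing(kdd) || !is.finite(kd) || !is.finite(kdd) ||
      kd < 0 || kdd < 0)
    stop_lux("kd and kdd must be supplied as fixed nonnegative constants")
  b <- lux_default_bounds()
  if (!is.null(lower)) b$lower[names(lower)] <- lower
  if (!is.null(upper)) b$upper[names(upper)] <- upper
  if (any(b$lower <= 0)) stop_lux("lower bounds must be positive")
  if (any(b$upper <= b$lower)) stop_lux("upper bounds must exceed lower")
  lo <- log10(b$lower); hi <- log10(b$upper)
  pn <- names(lo)

  theta0 <- if (is.null(start)) (lo + hi) / 2 else {
    if (!all(pn %in% names(start)))
      stop_lux("start must name all of ", paste(pn, collapse = ", "))
    pmin(pmax(log10(start[pn]), lo), hi)
  }
  cloud <- with_seed(seed, {
    extra <- if (n_screen > 0)
      matrix(runif(n_screen * length(pn), lo, hi), ncol = length(pn),
             byrow = TRUE) else NULL
    rbind(theta0, extra, deparse.level = 0)
  })
  colnames(cloud) <- pn
  ssr <- apply(cloud, 1, function(th)
    sum(lux_residuals_log10(setNames(th, pn), dataset, kd, kdd)^2))
  keep <- order(ssr)[seq_len(min(n_starts, nrow(cloud)))]
  keep <- union(1L, keep)[seq_len(min(n_starts, nrow(cloud)))]
  starts <- cloud[keep, , drop = FALSE]

  ctrl <- do.call(minpack.lm::nls.lm.control,
                  modifyList(list(maxiter = 120), control))
  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    runs[[i]] <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lo, upper = hi,
                         fn = lux_residuals_log10, dataset = dataset,
                         kd = kd, kdd = kdd, control = ctrl),
      error = function(e) NULL)
  }
  dev <- vapply(runs, function(r) if (is.null(r)) Inf else r$deviance,
                numeric(1))
  if (!any(is.finite(dev)))
    stop_lux("no multi-start optimization converged; check the dataset ",
             "and bounds")
  best <- which.min(dev)
  fit <- runs[[best]]
  theta <- coef(fit)
  res <- lux_residuals_log10(theta, dataset, kd, kdd)
  sc <- attr(res, "scale")
  rates <- lux_rates(10^theta[["k1"]], 10^theta[["k2"]], 10^theta[["k3"]],
                     10^theta[["k_minus3"]], 10^theta[["k4"]],
                     kd, kdd, scale = sc)

  model <- lux_model_matrix(setNames(10^theta, pn), dataset, kd, kdd)
  relerr <- pooled_relative_error(lapply(model, function(m) sc * m),
                                  lapply(dataset, `[[`, "y"))

  # approximate curvature-based uncertainty of the log10 parameters
  npt <- sum(lengths(lapply(dataset, `[[`, "y")))
  dof <- max(npt - (length(pn) + 1L), 1L)
  s2 <- fit$deviance / dof
  hin <- tryCatch(chol2inv(chol(fit$hessian)), error = function(e) NULL)
  se <- if (is.null(hin)) rep(Inf, length(pn)) else sqrt(pmax(diag(hin), 0) * s2)
  names(se) <- pn
  # pairwise parameter correlations: near-unity off-diagonals mean the data
  # constrain only a combination of the rates, not each one separately
  maxcor <- rep(1, length(pn))
  if (!is.null(hin)) {
    d <- sqrt(pmax(diag(hin), 1e-300))
    cm <- hin / outer(d, d); diag(cm) <- 0
    maxcor <- apply(abs(cm), 1, max)
  }
  names(maxcor) <- pn

  structure(list(
    rates = rates,
    theta_log10 = theta,
    se_log10 = se,
    max_correlation = maxcor,
    identifiable = se < 1 & maxcor < 0.99,
    rel_error = relerr,
    rss = fit$deviance,
    starts = data.frame(starts,
                        deviance = dev,
                        converged = vapply(runs, function(r)
                          !is.null(r) && r$info %in% 1:4, logical(1))),
    best_start = best,
    convergence = if (is.null(fit$message)) "" else fit$message,
    niter = fit$niter,
    kd = kd, kdd = kdd,
    bounds = b, seed = seed, n_starts = n_starts, n_screen = n_screen,
    dataset = dataset,
    call = match.call()),
    class = "luxfit")
}

#' @export
coef.luxfit <- function(object, ...) unclass(object$rates)

#' @export
vcov.luxfit <- function(object, ...) {
  # covariance of the log10 free parameters
  se <- object$se_log10
  v <- diag(se^2, nrow = length(se))
  dimnames(v) <- list(names(se), names(se))
  v
}

#' @export
print.luxfit <- function(x, ...) {
  cat("Global single-turnover kinetic fit (", length(x$dataset),
      " curves)\n", sep = "")
  print(x$rates)
  cat(sprintf("Pooled relative error: %.3g %%  (rss = %.4g)\n",
              x$rel_error$pooled, x$rss))
  if (!all(x$identifiable))
    cat("Note: poorly identified (se > 1 decade):",
        paste(names(x$identifiable)[!x$identifiable], collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.luxfit <- function(object, ...) {
  km <- michaelis_constants(object$rates)
  out <- list(
    rates = data.frame(
      estimate = 10^object$theta_log10,
      log10 = object$theta_log10,
      se_log10 = object$se_log10,
      max_correlation = object$max_correlation,
      identifiable = object$identifiable),
    fixed = c(kd = object$kd, kdd = object$kdd),
    scale = unclass(object$rates)[["scale"]],
    michaelis_uM = km * 1e6,
    rel_error = object$rel_error,
    rss = object$rss,
    n_starts = object$n_starts,
    best_start = object$best_start,
    converged_starts = sum(object$starts$converged))
  class(out) <- "summary.luxfit"
  out
}

#' @export
print.summary.luxfit <- function(x, ...) {
  cat("Fitted elementary rate constants (log10-space least squares):\n")
  print(signif(x$rates, 4))
  cat(sprintf("Fixed: kd = %g 1/s, kdd = %g 1/s; scale = %.4g a.u. s/M\n",
              x$fixed[["kd"]], x$fixed[["kdd"]], x$scale))
  cat(sprintf("Michaelis constants: KM_F = %.3g uM, KM_a = %.3g uM\n",
              x$michaelis_uM[["KM_F"]], x$michaelis_uM[["KM_a"]]))
  cat(sprintf("Pooled relative error: %.3g %% (per curve: %s)\n",
              x$rel_error$pooled,
              paste(sprintf("%.3g", x$rel_error$per_curve), collapse = ", ")))
  cat(sprintf("Multi-start: %d/%d converged, best = #%d\n",
              x$converged_starts, x$n_starts, x$best_start))
  invisible(x)
}

#' Predicted model curves from a fitted kinetic model
#'
#' @param object a [luxfit()] object.
#' @param decanal_uM aldehyde concentrations to predict for; defaults to
#'   those of the fitted dataset.
#' @param t time grid, s; defaults to the grid of the first fitted curve.
#' @param ... unused.
#' @return List of [lux_curve()]s with the fitted intensity model.
#' @export
predict.luxfit <- function(object, decanal_uM = NULL, t = NULL, ...) {
  ds <- object$dataset
  if (is.null(decanal_uM)) decanal_uM <- attr(ds, "decanal_uM")
  L0 <- attr(ds, "L0") * 1e6; F0 <- attr(ds, "F0") * 1e6
  lapply(seq_along(decanal_uM), function(i) {
    grid <- if (is.null(t)) {
      j <- match(decanal_uM[i], attr(ds, "decanal_uM"))
      if (is.na(j)) ds[[1]]$t else ds[[j]]$t
    } else t
    lux_simulate(object$rates,
                 lux_init(L0, F0, decanal_uM[i], units = "uM"),
                 grid, check = FALSE)
  })
}

#' @export
fitted.luxfit <- function(object, ...) {
  lapply(predict(object), `[[`, "y")
}

#' @export
residuals.luxfit <- function(object, ...) {
  mapply(function(f, d) d$y - f, fitted(object), object$dataset,
         SIMPLIFY = FALSE)
}

#' @export
plot.luxfit <- function(x, ...) {
  ds <- x$dataset
  fit <- fitted(x)
  ylim <- range(unlist(lapply(ds, `[[`, "y")), unlist(fit))
  plot(NA, xlim = range(ds[[1]]$t), ylim = ylim,
       xlab = "time (s)", ylab = "intensity (a.u.)", ...)
  cols <- seq_along(ds)
  for (i in seq_along(ds)) {
    points(ds[[i]]$t, ds[[i]]$y, col = cols[i], pch = 16, cex = 0.25)
    lines(ds[[i]]$t, fit[[i]], col = cols[i], lwd = 2)
  }
  legend("topright", bty = "n", lwd = 2, col = cols,
         legend = sprintf("%g uM decanal", attr(ds, "decanal_uM")))
  invisible(x)
}

#' Simulate new noisy datasets from a fitted kinetic model
#'
#' @param object a [luxfit()] object.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param noise a [noise_model()]; defaults to 2% multiplicative noise.
#' @param ... unused.
#' @return List of `nsim` [lux_dataset()] objects.
#' @export
simulate.luxfit <- function(object, nsim = 1, seed = 1,
                            noise = noise_model(seed = seed), ...) {
  ds <- object$dataset
  lapply(seq_len(nsim), function(i) {
    nm <- noise
    nm$seed <- noise$seed + i - 1L
    generate_bioluminescence_dataset(
      rates = object$rates,
      L0 = attr(ds, "L0") * 1e6, F0 = attr(ds, "F0") * 1e6,
      aldehyde_uM = attr(ds, "decanal_uM"),
      t = ds[[1]]$t, noise = nm)$curves
  })
}
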