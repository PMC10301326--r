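test_that("pooled relative error matches hand computation and handles edge cases", {
  a <- list(c(1, 2, 3), c(4, 5))
  expect_equal(pooled_relative_error(a, a)$pooled, 0)
  b <- lapply(a, function(y) 1.01 * y)
  expect_equal(pooled_relative_error(b, a)$pooled, 1, tolerance = 1e-12)

  set.seed(42)
  ym <- list(runif(50), runif(30)); yd <- list(runif(50), runif(30))
  pe <- pooled_relative_error(ym, yd)
  brute <- 100 * sqrt(sum((unlist(ym) - unlist(yd))^2) / sum(unlist(yd)^2))
  expect_equal(pe$pooled, brute)
  expect_equal(pe$per_curve[1],
               100 * sqrt(sum((ym[[1]] - yd[[1]])^2) / sum(yd[[1]]^2)))

  expect_error(pooled_relative_error(list(0 * a[[1]]), list(0 * a[[1]])),
               "all-zero")
  expect_error(pooled_relative_error(a, a[1]), "number of curves")
})

test_that("Michaelis constants follow their defining formulas", {
  r <- lux_rates(2e6, 3, 1e5, 0, 0.6, 0.3, 0.05)
  expect_equal(unname(michaelis_constants(r)[["KM_a"]]), 0.6 / 1e5)
  r2 <- lux_rates(2e6, 2e6 * 1.5e-6, 1e5, 2.4, 0.6, 0.3, 0.05)
  expect_equal(unname(michaelis_constants(r2)[["KM_F"]]), 1.5e-6)
  set.seed(3)
  for (i in 1:50) {
    rr <- random_rates()
    km <- michaelis_constants(rr)
    v <- unclass(rr)
    expect_equal(unname(km[["KM_F"]]), v[["k2"]] / v[["k1"]])
    expect_equal(unname(km[["KM_a"]]),
                 (v[["k_minus3"]] + v[["k4"]]) / v[["k3"]])
  }
  expect_error(michaelis_constants(lux_rates(0, 1, 1, 1, 1, 1, 1)),
               "positive")
  # the frozen fixture lands inside the buffer windows reported for the enzyme
  km <- michaelis_constants(true_rates()) * 1e6
  expect_gt(km[["KM_F"]], 1); expect_lt(km[["KM_F"]], 2)
  expect_gt(km[["KM_a"]], 25); expect_lt(km[["KM_a"]], 50)
})

test_that("noise-free global fit recovers the generating rates within 1%", {
  synth <- quick_dataset(seed = 5, noise = noise_model(0, 0))
  fit <- luxfit(synth$curves, kd = 0.30, kdd = 0.05, n_starts = 6, seed = 2)
  tru <- unclass(true_rates())[1:5]
  expect_true(all(abs(coef(fit)[1:5] - tru) / tru < 0.01))
  expect_lt(fit$rel_error$pooled, 0.01)
  expect_equal(unname(coef(fit)[["scale"]]), 1e9, tolerance = 0.01)
})

test_that("the objective is minimal at the truth against single-rate doublings", {
  synth <- quick_dataset(seed = 8, noise = noise_model(0, 0))
  ds <- synth$curves
  obj <- function(p) sum(luxkin:::lux_residuals_log10(
    log10(p), ds, kd = 0.30, kdd = 0.05)^2)
  tru <- unclass(true_rates())[1:5]
  at_truth <- obj(tru)
  for (nm in names(tru)) {
    p <- tru; p[nm] <- 2 * p[nm]
    expect_gt(obj(p), at_truth)
    p <- tru; p[nm] <- 0.5 * p[nm]
    expect_gt(obj(p), at_truth)
  }
})

test_that("fitting is deterministic given the seed", {
  synth <- quick_dataset(seed = 3)
  f1 <- luxfit(synth$curves, kd = 0.30, kdd = 0.05, n_starts = 3, seed = 11)
  f2 <- luxfit(synth$curves, kd = 0.30, kdd = 0.05, n_starts = 3, seed = 11)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$rel_error, f2$rel_error)
  expect_identical(f1$starts, f2$starts)
})

test_that("a single-concentration dataset yields wide-uncertainty diagnostics", {
  synth <- generate_bioluminescence_dataset(
    rates = true_rates(), aldehyde_uM = 30,
    t = seq(0, 15, length.out = 300), seed = 4)
  fit <- luxfit(synth$curves, kd = 0.30, kdd = 0.05, n_starts = 4, seed = 1)
  # k3 against k_minus3 cannot be resolved from one aldehyde level
  expect_false(all(fit$identifiable[c("k3", "k_minus3")]))
})

test_that("luxfit validates its inputs", {
  synth <- quick_dataset(seed = 1)
  expect_error(luxfit(synth$curves), "kd and kdd")
  expect_error(luxfit(list(1, 2), kd = 0.3, kdd = 0.05), "lux_dataset")
  expect_error(luxfit(synth$curves, kd = 0.3, kdd = 0.05,
                      lower = c(k1 = -1)), "positive")
})

test_that("fit methods are coherent: predict, residuals, simulate", {
  synth <- quick_dataset(seed = 6)
  fit <- luxfit(synth$curves, kd = 0.30, kdd = 0.05, n_starts = 2, seed = 1)
  pr <- predict(fit)
  expect_length(pr, 5)
  expect_s3_class(pr[[1]], "lux_curve")
  res <- residuals(fit)
  expect_equal(res[[2]], synth$curves[[2]]$y - fitted(fit)[[2]])
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "lux_dataset")
  expect_false(identical(sims[[1]][[1]]$y, sims[[2]][[1]]$y))
  s <- summary(fit)
  expect_s3_class(s, "summary.luxfit")
  expect_output(print(s), "Michaelis")
})
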