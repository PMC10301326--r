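test_that("peak intensity is the grid maximum", {
  expect_equal(peak_intensity(lux_curve(0:3, rep(3, 4))), 3)
  expect_equal(peak_intensity(lux_curve(0:3, c(0, 1, 5, 2))), 5)
  cv <- lux_simulate(true_rates(), lux_init(), seq(0, 15, length.out = 300))
  expect_equal(peak_intensity(cv), max(sapply(seq_along(cv$t),
                                              function(i) cv$y[i])))
})

test_that("quantum yield is the trapezoidal area and converges under refinement", {
  expect_equal(total_quantum_yield(lux_curve(c(0, 5), c(2, 2))), 10)
  expect_equal(total_quantum_yield(lux_curve(c(0, 1, 2), c(0, 1, 0))), 1)
  q1 <- total_quantum_yield(lux_simulate(true_rates(), lux_init(),
                                         seq(0, 15, length.out = 1000)))
  q2 <- total_quantum_yield(lux_simulate(true_rates(), lux_init(),
                                         seq(0, 15, length.out = 2000)))
  expect_lt(abs(q2 - q1) / q1, 0.001)
  # fine-grid Riemann reference
  tf <- seq(0, 15, length.out = 20000)
  cvf <- lux_simulate(true_rates(), lux_init(), tf)
  expect_equal(q1, sum(diff(tf) * (head(cvf$y, -1) + tail(cvf$y, -1)) / 2),
               tolerance = 1e-3)
})

test_that("initial velocity is the OLS slope on the starting window", {
  t <- seq(0, 2, 0.05)
  expect_equal(as.numeric(initial_velocity(lux_curve(t, 4 * t), c(0, 1))), 4)
  expect_equal(as.numeric(initial_velocity(lux_curve(t, rep(2, length(t))),
                                           c(0, 1))), 0)
  set.seed(21)
  y <- 3 * t + rnorm(length(t), 0, 0.05)
  v <- as.numeric(initial_velocity(lux_curve(t, y), c(0, 2)))
  ols <- unname(coef(lm(y ~ t))[2])
  expect_equal(v, ols)
  expect_error(initial_velocity(lux_curve(t, y), c(0, 0.1)), "fewer than 5")
})

test_that("the decay constant is recovered from exponential tails", {
  t <- seq(0, 15, 0.01)
  cv <- lux_curve(t, exp(-0.5 * t))
  expect_equal(decay_constant(cv, c(5, 15)), 0.5, tolerance = 1e-10)
  set.seed(31)
  for (i in 1:20) {
    B <- runif(1, 0.1, 10); k <- runif(1, 0.05, 2)
    cv <- lux_curve(t, B * exp(-k * t))
    expect_equal(decay_constant(cv, c(2, 12)), k, tolerance = 1e-8)
    # time-shift invariance for pure exponentials
    expect_equal(decay_constant(cv, c(5, 15)),
                 decay_constant(cv, c(1, 11)), tolerance = 1e-8)
  }
  set.seed(32)
  ks <- replicate(20, {
    y <- exp(-0.4 * t) * (1 + rnorm(length(t), 0, 0.02))
    decay_constant(lux_curve(t, pmax(y, 1e-12)), c(0, 10))
  })
  expect_lt(max(abs(ks - 0.4) / 0.4), 0.05)
  expect_error(decay_constant(lux_curve(t, exp(-t) - 0.5), c(0, 5)),
               "nonpositive")
})

test_that("empirical parameters are scale-equivariant", {
  cv <- lux_simulate(true_rates(), lux_init(), seq(0, 15, length.out = 500))
  p1 <- empirical_params(cv)
  cv3 <- lux_curve(cv$t, 3 * cv$y, cv$signal, cv$meta)
  p3 <- empirical_params(cv3)
  expect_equal(p3$Imax, 3 * p1$Imax)
  expect_equal(p3$v0, 3 * p1$v0)
  expect_equal(p3$Qstar, 3 * p1$Qstar)
  expect_equal(p3$k_decay, p1$k_decay, tolerance = 1e-10)
})

test_that("baseline subtraction is available but off by default", {
  t <- seq(0, 15, 0.05)
  cv <- lux_curve(t, 10 * exp(-0.5 * t) + 2)
  p_raw <- empirical_params(cv, decay_window = c(5, 15))
  p_sub <- empirical_params(cv, decay_window = c(5, 15), baseline = 2)
  expect_equal(p_sub$k_decay, 0.5, tolerance = 1e-8)
  expect_lt(p_raw$k_decay, 0.5)       # offset flattens the apparent tail
  expect_equal(p_raw$Imax, p_sub$Imax + 2)
})
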