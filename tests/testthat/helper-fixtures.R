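# Shared fixtures for the suite: the frozen ground-truth rate set and a
# random valid state/rate generator for property-style checks.

true_rates <- function() lux_default_rates()

random_state <- function() {
  s <- runif(8, 0, 1e-5)
  names(s) <- c("L", "F", "I1", "I2", "I2A", "A", "Fox", "P")
  s
}

random_rates <- function() {
  lux_rates(k1 = 10^runif(1, 4, 8), k2 = 10^runif(1, 0, 3),
            k3 = 10^runif(1, 4, 8), k_minus3 = 10^runif(1, -2, 2),
            k4 = 10^runif(1, -2, 2), kd = runif(1, 0, 1),
            kdd = runif(1, 0, 0.5), scale = 10^runif(1, 6, 10))
}

# Small fast dataset for fit mechanics (coarser grid than the study design).
quick_dataset <- function(seed = 1, noise = noise_model(seed = seed),
                          t = seq(0, 15, length.out = 300)) {
  generate_bioluminescence_dataset(rates = true_rates(), t = t,
                                   noise = noise, seed = seed)
}
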