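# Small deterministic populations used across tests. Fiber area is scaled so
# that reduced fiber counts keep the physical tendon's total cross-section.
small_pop <- function(n = 2000, mean = 275, sd = 2, seed = 1,
                      youngs_modulus = 1000) {
  set.seed(seed)
  init_gaussian_population(n, mean, sd, fiber_area = scaled_fiber_area(n),
                           youngs_modulus = youngs_modulus)
}

# Peak force at which the most-stressed (shortest) fiber reaches `strain`.
force_at_peak_strain <- function(pop, strain) {
  tendon_force(pop, min(pop$slack_lengths) * (1 + strain))
}

# A fast config for simulation tests: few fibers, small cost-surface grid.
test_config <- function(n_fibers = 2000L) {
  cfg <- default_config()
  cfg$tendon$n_fibers <- n_fibers
  cfg$sim$qmin_n_fibers <- 1000L
  cfg
}
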