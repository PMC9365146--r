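# Shared fixtures, all built in code.

# Random valid parameter sets across the full domain used by the fits.
rand_params <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      gpsa_params(e_cpx = runif(1, 0, 10), s_cpx = runif(1, 0, 10),
                  alpha = runif(1, 0, 10), beta = runif(1, 0, 10))
    })
  })
}

# Observation set straight from model-scale columns.
make_obs <- function(g, tom, gpsa_obs, level = "synthetic") {
  observation_set(tibble::tibble(
    unit_id = sprintf("u%02d", seq_along(g)),
    g = g, tom = tom, gpsa_obs = gpsa_obs), level)
}

# Dispersed, well-identified scenario: uniform g/ToM over the full scale.
uniform_scenario <- function(params, n = 200, noise_sd = 0, seed = 1,
                             level = "synthetic") {
  scenario_spec(params, n_units = n,
                g_dist = list(family = "uniform"),
                tom_dist = list(family = "uniform"),
                noise_sd = noise_sd, seed = seed, level = level)
}

# Cheap fit config for tests.
test_cfg <- function(n_realizations = 5, seed = 42) {
  fit_config(n_realizations = n_realizations, seed = seed)
}
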