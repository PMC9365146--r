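test_that("fitness is the mean squared prediction error", {
  p <- gpsa_params(3, 2, 2, 2)
  g <- c(2, 5, 8); tom <- c(3, 5, 7)
  mu <- gpsa_score(p, g, tom)

  expect_identical(gpsa_fitness(p, make_obs(g, tom, mu)), 0)
  obs1 <- make_obs(5, 5, gpsa_score(p, 5, 5) - 0.1)
  expect_equal(gpsa_fitness(p, obs1), 0.01, tolerance = 1e-12)
  obs2 <- make_obs(c(5, 6), c(5, 6),
                   gpsa_score(p, c(5, 6), c(5, 6)) + c(0.1, -0.3))
  expect_equal(gpsa_fitness(p, obs2), 0.05, tolerance = 1e-12)
  expect_error(gpsa_fitness(p, obs1[0, ]), "empty")
})

test_that("the fast fitness path agrees with the public model evaluation", {
  withr::with_seed(13, {
    obs <- make_obs(runif(30, 0, 10), runif(30, 0, 10), runif(30))
    f <- gpsafit:::make_fitness(obs)
    for (i in 1:20) {
      th <- c(runif(2, 0, 10), runif(2, 1, 10))
      expect_equal(f(th), gpsa_fitness(gpsa_params(th[1], th[2], th[3], th[4]), obs),
                   tolerance = 1e-12)
    }
  })
})

test_that("fits are deterministic and improve with more restarts", {
  spec <- uniform_scenario(gpsa_params(4, 2, 2, 3), n = 40, noise_sd = 0.05,
                           seed = 3)
  obs <- generate_observations(spec)
  f1 <- fit_pooled(obs, test_cfg(n_realizations = 3))
  f2 <- fit_pooled(obs, test_cfg(n_realizations = 3))
  expect_identical(f1$per_realization, f2$per_realization)
  expect_identical(f1$best_params, f2$best_params)

  one <- fit_pooled(obs, test_cfg(n_realizations = 1))
  two <- fit_pooled(obs, test_cfg(n_realizations = 2))
  expect_lte(two$fit_value, one$fit_value)
  # shared seed stream: restart 1 of the pair is the single restart
  expect_identical(two$per_realization$fit[1], one$per_realization$fit[1])
})

test_that("noise-free synthetic data is fit to near machine zero", {
  spec <- uniform_scenario(gpsa_params(2.6, 0, 2.3, 1), n = 200, seed = 7)
  obs <- generate_observations(spec)
  fit <- fit_pooled(obs, test_cfg(n_realizations = 5))
  expect_lte(fit$fit_value, 1e-4)  # oracle: fitness at truth is exactly 0
})

test_that("annealing never does worse than the brute-force grid", {
  for (s in 1:2) {
    spec <- uniform_scenario(gpsa_params(3 * s, 1.5, 2 + s, 1 + s), n = 60,
                             noise_sd = 0.05, seed = 20 + s)
    obs <- generate_observations(spec)
    grid <- coarse_grid_fitness(obs)
    fit <- fit_pooled(obs, test_cfg(n_realizations = 5))
    expect_lte(fit$fit_value, grid$value + 1e-12)
  }
})

test_that("per-unit fits hit attainable scores and expose unattainable ones", {
  p <- gpsa_params(5, 3, 2, 2)
  attainable <- make_obs(c(4, 7), c(5, 2), gpsa_score(p, c(4, 7), c(5, 2)))
  fits <- fit_per_unit(attainable, test_cfg(n_realizations = 3))
  expect_length(fits, 2)
  for (f in fits) expect_lte(f$fit_value, 1e-8)

  # at g = ToM = 10 both weights saturate, so GPSA = 1 - (1.1 E + 2 S)/60
  # never drops below 29/60; observing 0.2 leaves an irreducible residual.
  hard <- make_obs(10, 10, 0.2)
  oracle <- coarse_grid_fitness(hard)           # corner optimum: exact here
  expect_equal(oracle$value, (1 - 31 / 60 - 0.2)^2, tolerance = 1e-12)
  fhard <- fit_per_unit(hard, test_cfg(n_realizations = 3))[[1]]
  expect_equal(fhard$fit_value, oracle$value, tolerance = 1e-9)

  # identical units get identical fits under the shared seed stream
  twin <- make_obs(c(6, 6), c(4, 4), c(0.5, 0.5))
  tf <- fit_per_unit(twin, test_cfg(n_realizations = 2))
  expect_identical(tf[[1]]$fit_value, tf[[2]]$fit_value)
  expect_identical(tf[[1]]$best_params, tf[[2]]$best_params)
})

test_that("fit summaries report elementwise means and population variances", {
  fake_fit <- function(a) {
    structure(list(
      best_params = gpsa_params(5, 1, a, 1), fit_value = 0.01,
      per_realization = tibble::tibble(realization = 1L, e_cpx = 5, s_cpx = 1,
                                       alpha = a, beta = 1, fit = 0.01),
      level = "synthetic", n_obs = 1L, config = NULL), class = "gpsa_fit")
  }
  single <- summarize_fits(fake_fit(2), "realizations")
  expect_identical(unname(single$variance), rep(0, 4))

  pair <- summarize_fits(list(fake_fit(2), fake_fit(4)), "units")
  expect_identical(unname(pair$mean["alpha"]), 3)
  expect_identical(unname(pair$variance["alpha"]), 1)  # population variance
  expect_error(summarize_fits(list(), "units"), "empty")
})

test_that("prediction report applies strict cross-level inequalities", {
  mk_sum <- function(e, s, a, b, ve = 1, vs = 1, va = 1, vb = 1) {
    structure(list(mean = c(e_cpx = e, s_cpx = s, alpha = a, beta = b),
                   variance = c(e_cpx = ve, s_cpx = vs, alpha = va, beta = vb),
                   mean_fit = 0.04, n = 10L, axis = "realizations",
                   level = "x"), class = "gpsa_fit_summary")
  }
  pooled <- list(small_group = mk_sum(2.6, 0, 2.3, 1),
                 country = mk_sum(10, 1.3, 10, 1))
  per_unit <- list(small_group = mk_sum(0, 0, 0, 0, 4.5, 4.3, 0.5, 4.4),
                   country = mk_sum(0, 0, 0, 0, 15.2, 13.7, 1.9, 7.0))
  rep <- prediction_report(pooled, per_unit)
  expect_identical(nrow(rep), 8L)
  expect_true(rep$holds[rep$prediction == "S_cpx_sg < S_cpx_ctr"])   # 0 < 1.3
  expect_true(rep$holds[rep$prediction == "E_cpx_sg < E_cpx_ctr"])
  expect_true(rep$holds[rep$prediction == "alpha_sg < alpha_ctr"])
  # equal betas: the strict inequality does not hold
  expect_false(rep$holds[rep$prediction == "beta_sg < beta_ctr"])
  expect_true(all(rep$holds[5:8]))   # variance rows from the per-unit source

  expect_error(prediction_report(pooled["country"]), "missing level")
})
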