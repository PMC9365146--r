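test_that("diversity and gap weights match direct tanh evaluation", {
  # frozen against high-precision evaluation of M * tanh(x/(M-x))^p
  expect_identical(ability_weight(0, alpha = 2), 1)      # floor active
  expect_identical(ability_weight(10, alpha = 7), 10)    # continuous limit
  expect_equal(ability_weight(5, alpha = 1), 10 * tanh(1), tolerance = 1e-12)
  expect_equal(ability_weight(5, alpha = 2), 10 * tanh(1)^2, tolerance = 1e-12)

  expect_identical(gap_weight(0, beta = 4), 0)           # no floor
  expect_identical(gap_weight(10, beta = 9), 10)
  expect_equal(gap_weight(5, beta = 1), 10 * tanh(1), tolerance = 1e-12)

  # continuity at the scale maximum
  expect_equal(ability_weight(10 - 1e-6, alpha = 3), 10, tolerance = 1e-6)
  expect_equal(gap_weight(10 - 1e-6, beta = 3), 10, tolerance = 1e-6)

  # the two weights share the saturating form wherever the floor is idle
  x <- seq(3.5, 10, by = 0.5)
  expect_equal(ability_weight(x, 1.5), gap_weight(x, 1.5), tolerance = 1e-12)
})

test_that("power-zero and boundary conventions hold", {
  # tanh(.)^0 := 1, so alpha = 0 gives the unrestricted weight even at g = 0
  expect_identical(ability_weight(c(0, 5, 10), alpha = 0), c(10, 10, 10))
  expect_identical(gap_weight(c(0, 5, 10), beta = 0), c(10, 10, 10))
})

test_that("diversity need composes complexities with the ability weight", {
  p0 <- gpsa_params(0, 7, 3, 1)
  expect_identical(diversity_need(p0, c(0, 2, 9.9)), c(7, 7, 7))
  expect_identical(diversity_need(gpsa_params(5, 5, 3, 1), 0), 10)
  expect_equal(diversity_need(gpsa_params(5, 5, 1, 1), 5),
               5 + 5 / (10 * tanh(1)), tolerance = 1e-12)

  # bounds and monotone decline over random draws
  for (p in rand_params(25, seed = 101)) {
    g <- seq(0, 10, length.out = 41)
    rd <- diversity_need(p, g)
    expect_true(all(rd <= p$s_cpx + p$e_cpx + 1e-12))
    expect_true(all(rd >= p$s_cpx + p$e_cpx / 10 - 1e-12))
    expect_true(all(diff(rd) <= 1e-12))
  }
})

test_that("harnessed diversity and GPSA match hand-evaluated cases", {
  expect_identical(harnessed_diversity(gpsa_params(0, 0, 2, 5), g = 3, tom = 10), -20)
  p <- gpsa_params(4, 2, 2, 3)
  expect_identical(harnessed_diversity(p, g = 6, tom = 0), diversity_need(p, 6))

  p1 <- gpsa_params(5, 5, 1, 1)
  rh <- 5 + 5 / (10 * tanh(1)) - 5 * (10 * tanh(1)) / 5
  expect_equal(harnessed_diversity(p1, 5, 5), rh, tolerance = 1e-12)
  expect_equal(gpsa_score(p1, 5, 5), 1 - (10 + rh + 20) / 60, tolerance = 1e-12)

  expect_identical(gpsa_score(gpsa_params(10, 10, 1, 1), 0, 0), 0)
  expect_identical(gpsa_score(gpsa_params(0, 0, 1, 1), 5, 10), 1)
})

test_that("domain violations are rejected", {
  expect_error(ability_weight(-0.1, 1), "\\[0, 10\\]")
  expect_error(ability_weight(10.1, 1), "\\[0, 10\\]")
  expect_error(ability_weight(5, -1), "alpha")
  expect_error(gap_weight(11, 2), "\\[0, 10\\]")
  expect_error(gpsa_params(-1, 0, 1, 1), "complexities")
  expect_error(gpsa_params(1, 1, 1, 1, max_g = 0), "maxima")
  expect_error(gpsa_score(gpsa_params(11, 0, 1, 1), 5, 5), "complexities")
  p11 <- gpsa_params(5, 11, 1, 1)  # valid params, but outside the score's scale
  expect_error(gpsa_score(p11, 5, 5), "\\[0, 10\\]")
})

test_that("score and balance stay in range with the clip never active", {
  withr::with_seed(7, {
    n <- 2000
    for (i in seq_len(n / 100)) {
      p <- gpsa_params(runif(1, 0, 10), runif(1, 0, 10),
                       runif(1, 0, 10), runif(1, 0, 10))
      g <- runif(100, 0, 10); tom <- runif(100, 0, 10)
      raw <- harnessed_diversity(p, g, tom, clip = FALSE)
      expect_true(all(raw >= -20 & raw <= 20))
      expect_identical(raw, harnessed_diversity(p, g, tom, clip = TRUE))
      sc <- gpsa_score(p, g, tom)
      expect_true(all(sc >= 0 & sc <= 1))
      expect_true(all(ability_weight(g, p$alpha) >= 1))
      expect_true(all(ability_weight(g, p$alpha) <= 10))
    }
  })
})

test_that("GPSA responds monotonically to every argument", {
  withr::with_seed(11, {
    for (i in 1:200) {
      e <- runif(1, 0, 9); s <- runif(1, 0, 9)
      a <- runif(1, 0, 9); b <- runif(1, 0, 9)
      g <- runif(1, 0, 9); tom <- runif(1, 0, 9)
      d <- runif(1, 0.01, 1)
      base <- gpsa_score(gpsa_params(e, s, a, b), g, tom)
      expect_gte(gpsa_score(gpsa_params(e, s, a, b), g + d, tom) + 1e-12, base)
      expect_gte(gpsa_score(gpsa_params(e, s, a, b), g, tom + d) + 1e-12, base)
      expect_lte(gpsa_score(gpsa_params(e + d, s, a, b), g, tom) - 1e-12, base)
      expect_lte(gpsa_score(gpsa_params(e, s + d, a, b), g, tom) - 1e-12, base)
      expect_lte(gpsa_score(gpsa_params(e, s, a + d, b), g, tom) - 1e-12, base)
      expect_lte(gpsa_score(gpsa_params(e, s, a, b + d), g, tom) - 1e-12, base)
    }
  })
})

test_that("component table is internally consistent", {
  p <- gpsa_params(3, 2, 2, 4)
  tab <- gpsa_components(p, g = c(0, 5, 10), tom = c(10, 5, 0))
  expect_equal(tab$r_div, p$s_cpx + p$e_cpx / tab$w_div, tolerance = 1e-12)
  expect_equal(tab$r_hdg, tab$r_div - tab$tom * tab$w_gap / 5, tolerance = 1e-12)
  expect_equal(tab$gpsa, 1 - (p$e_cpx + p$s_cpx + tab$r_hdg + 20) / 60,
               tolerance = 1e-12)
})
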