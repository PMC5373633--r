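test_that("the worked 10-value example gives the documented groups", {
  x <- c(10, 10, 10, 9, 1, 1, 1, 1, 1, 1)
  res <- r_nonr_ratio(x, f = 0.4)
  expect_equal(res$n_top, 3)
  expect_equal(res$n_bottom, 5)
  expect_equal(res$r_mean, 10)
  expect_equal(res$nonr_mean, 1)
  expect_equal(res$ratio, 10)
  expect_equal(signal_intensity(x, f = 0.4), 10)
})

test_that("group sizes at F = 0.44 and n = 10,000 are 3,400 and 4,600", {
  res <- r_nonr_ratio(withr::with_seed(1, stats::runif(10000)), f = 0.44)
  expect_equal(res$n_top, 3400)
  expect_equal(res$n_bottom, 4600)
  expect_equal(res$n_total, 10000)
})

test_that("constant signals give a ratio of exactly 1", {
  res <- r_nonr_ratio(rep(7.5, 100), f = 0.44)
  expect_identical(res$ratio, 1)
  expect_equal(signal_intensity(rep(7.5, 100), f = 0.44), 7.5)
})

test_that("the ratio is invariant to positive rescaling", {
  withr::with_seed(2, {
    for (i in 1:20) {
      x <- stats::rlnorm(500, 4, 1)
      f <- stats::runif(1, 0.15, 0.85)
      base <- r_nonr_ratio(x, f)$ratio
      # power-of-two scales are exact in binary floating point: bitwise equal
      for (c2 in c(0.25, 2, 1024))
        expect_identical(r_nonr_ratio(c2 * x, f)$ratio, base)
      # arbitrary positive scales agree to round-off
      c_scale <- stats::runif(1, 1e-3, 1e3)
      expect_equal(r_nonr_ratio(c_scale * x, f)$ratio, base,
                   tolerance = 1e-12)
    }
  })
})

test_that("results match the brute-force sort/slice/mean oracle exactly", {
  withr::with_seed(3, {
    for (i in 1:1000) {
      n <- sample(10:5000, 1)
      f <- stats::runif(1, 0.11 + 1e-3, 0.89 - 1e-3)
      if (n < max(ceiling(1 / (f - 0.1)), ceiling(1 / (0.9 - f)))) next
      x <- stats::rlnorm(n, 5, 1.2)
      got <- r_nonr_ratio(x, f)
      want <- oracle_rnonr(x, f)
      expect_identical(got$n_top, as.integer(want$n_top))
      expect_identical(got$n_bottom, as.integer(want$n_bottom))
      expect_identical(got$r_mean, want$r_mean)
      expect_identical(got$nonr_mean, want$nonr_mean)
      expect_identical(got$ratio, want$ratio)
    }
  })
})

test_that("admissible-f and degenerate inputs are rejected informatively", {
  x <- 1:100
  expect_error(r_nonr_ratio(x, f = 0.1), "0.1, 0.9")
  expect_error(r_nonr_ratio(x, f = 0.95), "0.1, 0.9")
  expect_error(r_nonr_ratio(rep(0, 100), f = 0.44), "zero")
  expect_error(r_nonr_ratio(1:2, f = 0.44), "at least")
})

test_that("a perfectly separated half/half mixture gives F-hat = 0.50", {
  x <- c(rep(100, 500), rep(1, 500))
  est <- estimate_f(x)
  expect_equal(est$f_hat, 0.5)
  expect_true(est$reliable)
})

test_that("F-hat recovers 0.44 within 0.02 on the default population", {
  truth <- generate_population(population_params(n_cells = 10000, seed = 41),
                               cell_cycle_params())
  est <- estimate_f(truth$true_signal)
  expect_lt(abs(est$f_hat - 0.44), 0.02)
  expect_true(est$reliable)
})

test_that("weakly separated components are flagged unreliable", {
  x <- withr::with_seed(42, c(rlnorm_meancv(500, 100, 0.05),
                              rlnorm_meancv(500, 150, 0.05)))
  est <- estimate_f(x)
  expect_false(est$reliable)
  expect_lt(est$separation, 3)
})

test_that("identical signals make F undefined", {
  expect_error(estimate_f(rep(5, 200)), "no separation")
})

test_that("raising the replication component raises the ratio", {
  cyc <- cell_cycle_params()
  base <- generate_population(
    population_params(n_cells = 10000, mu_signal_R = 1000, seed = 43), cyc)
  up <- generate_population(
    population_params(n_cells = 10000, mu_signal_R = 3000, seed = 43), cyc)
  expect_gt(r_nonr_ratio(up$true_signal, 0.44)$ratio,
            r_nonr_ratio(base$true_signal, 0.44)$ratio)
})

test_that("trimmed ratio recovers the component-mean contrast when well separated", {
  # With tight components the trimming buffers change the group means
  # little, so the statistic lands within 10% of the mixture's actual mean
  # contrast at n = 10,000.
  truth <- generate_population(
    population_params(n_cells = 10000, cv_R = 0.1, cv_nonR = 0.05,
                      seed = 44),
    cell_cycle_params())
  rho_true <- mean(truth$true_signal[truth$phase == "S"]) /
    mean(truth$true_signal[truth$phase != "S"])
  est <- r_nonr_ratio(truth$true_signal, 0.44)$ratio
  expect_lt(abs(est - rho_true) / rho_true, 0.1)
  # At the default (wider) component CVs the truncation biases of both
  # trimmed groups point the same way: the statistic reads high relative to
  # the raw component contrast. It is a comparator, not an unbiased
  # estimator of the contrast.
  dflt <- generate_population(population_params(n_cells = 10000, seed = 45),
                              cell_cycle_params())
  rho_dflt <- mean(dflt$true_signal[dflt$phase == "S"]) /
    mean(dflt$true_signal[dflt$phase != "S"])
  expect_gt(r_nonr_ratio(dflt$true_signal, 0.44)$ratio, rho_dflt)
})

test_that("normalisation to a reference is a simple percent scale", {
  expect_equal(normalise_to_reference(42, 42), 100)
  expect_equal(normalise_to_reference(50, 200), 25)
  expect_equal(normalise_to_reference(c(10, 20, 40), 40), c(25, 50, 100))
  expect_error(normalise_to_reference(1, 0), "positive")
  expect_error(normalise_to_reference(1, -3), "positive")
})
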