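test_that("poisson_exceedance matches closed forms and the series oracle", {
  expect_equal(poisson_exceedance(log(2), 1), 0.5)
  expect_equal(poisson_exceedance(0, 1), 0)
  expect_equal(poisson_exceedance(0, 5), 0)

  # term-by-term series oracle
  lam <- 4.277778
  for (n in c(1, 2, 10)) {
    expect_equal(poisson_exceedance(lam, n),
                 1 - sum(dpois(0:(n - 1), lam)), tolerance = 1e-12)
  }

  # the printed-equation variant omits the k = 0 mass from the CDF side
  expect_equal(poisson_exceedance(lam, 10, variant = "printed_eq"),
               min(1, poisson_exceedance(lam, 10) + exp(-lam)),
               tolerance = 1e-12)
  expect_equal(poisson_exceedance(2, 1, variant = "printed_eq"), 1)
  lams <- seq(0, 12, by = 0.5)
  expect_true(all(poisson_exceedance(lams, 10, variant = "printed_eq") >=
                  poisson_exceedance(lams, 10)))

  expect_error(poisson_exceedance(-1, 2), "lambda")
  expect_error(poisson_exceedance(2, 1.5), "integer")
})

test_that("census arithmetic reproduces the printed constants", {
  cen <- derive_census(integration_params())
  expect_identical(cen$synapses_per_neuron, 2366)
  expect_identical(cen$glomeruli_per_odor, 109)
  expect_identical(cen$max_branches, 45)
  expect_identical(cen$min_branches, 16)
})

test_that("clustered response has the right limits and structure", {
  p <- integration_params()
  expect_equal(response_probability(p, 0, 72), 0)
  # a single branch collapses to the plain exceedance probability
  expect_equal(response_probability(p, 30, 72, branch_count = 1),
               poisson_exceedance(30, 10), tolerance = 1e-12)
  # distributed mode is the total-count exceedance
  expect_equal(response_probability(p, 50, 72, mode = "distributed"),
               poisson_exceedance(50, 40), tolerance = 1e-12)
  # complement identity: P = 1 - (1 - p_b)^nb at matched integer nb
  nb <- 20L
  p_b <- poisson_exceedance(70 / nb, 10)
  expect_equal(response_probability(p, 70, 90, branch_count = nb),
               1 - (1 - p_b)^nb, tolerance = 1e-12)
  expect_error(response_probability(p, 70, 2000), "<= TDBL")
  expect_error(response_probability(p, -1, 72), "S")
})

test_that("clustered probability increases strictly in BL and S", {
  p <- integration_params()
  bl <- seq(40, 110, by = 10)
  for (S in c(25, 70)) {
    probs <- vapply(bl, function(b) response_probability(p, S, b), 0)
    expect_true(all(diff(probs) > 0))
  }
  for (b in c(40, 110)) {
    probs <- vapply(c(10, 40, 70), function(S)
      response_probability(p, S, b), 0)
    expect_true(all(diff(probs) > 0))
  }
})

test_that("the Monte-Carlo oracle is seeded and converges to the analytic", {
  p <- integration_params()
  a <- monte_carlo_response(p, 70, 110, n_trials = 2e4, seed = 11)
  b <- monte_carlo_response(p, 70, 110, n_trials = 2e4, seed = 11)
  expect_identical(a$estimate, b$estimate)
  expect_equal(a$branch_count, 16L)

  analytic <- response_probability(p, 70, 110, branch_count = a$branch_count)
  se <- sqrt(analytic * (1 - analytic) / a$n_trials)
  expect_lt(abs(a$estimate - analytic), 4 * se)

  expect_equal(monte_carlo_response(p, 0, 72, seed = 1)$estimate, 0)
  expect_error(monte_carlo_response(p, 70, 72, n_trials = 10), ">= 1000")
})

test_that("the combined mode dominates both single routes", {
  p <- integration_params()
  comb <- response_probability(p, 45, 110, mode = "combined",
                               n_trials = 2e4, seed = 3)
  clus <- monte_carlo_response(p, 45, 110, mode = "clustered",
                               n_trials = 2e4, seed = 3)$estimate
  dist <- monte_carlo_response(p, 45, 110, mode = "distributed",
                               n_trials = 2e4, seed = 3)$estimate
  expect_gte(comb, clus)
  expect_gte(comb, dist)
})

test_that("response curves are tidy and validated", {
  p <- integration_params()
  curve <- response_curve(p, bl_grid = c(40, 72, 110), s_values = c(25, 70))
  expect_s3_class(curve, "response_curve")
  df <- as.data.frame(curve)
  expect_equal(nrow(df), 6L)
  expect_equal(df$probability[df$S == 70 & df$BL == 110],
               response_probability(p, 70, 110), tolerance = 1e-12)
  expect_error(response_curve(p, numeric(0), 70), "empty")
  expect_error(response_curve(p, c(0.5, 40), 70), "within")
})

test_that("integration parameters are validated", {
  expect_error(integration_params(nclus = 50), "nclus")
  expect_error(integration_params(bl_range = c(110, 40)), "bl_range")
  expect_error(integration_params(tdbl = 0), "tdbl")
})
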