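sk6 <- paper_skeleton()
emp <- dose_model("empiric")

test_that("the weighted likelihood matches its closed forms", {
  d <- sk6$probs
  expect_equal(crm_likelihood(trial_history(), d, emp, 0.3), 1)
  h1 <- trial_history(3, 1)                      # x = 0.2, y = 1
  expect_equal(crm_likelihood(h1, d, emp, 0), 0.2)
  h0 <- trial_history(3, 0)
  expect_equal(crm_likelihood(h0, d, emp, 0, weights = 0), 1)
  expect_equal(crm_likelihood(h0, d, emp, 0.7, weights = 0), 1)
  # weights recomputed from follow-up when a window is given
  hp <- trial_history(3, NA, followup = 2)
  expect_equal(crm_likelihood(hp, d, emp, 0, window = 4), 1 - 0.5 * 0.2)
})

test_that("tite_weight implements the linear weight", {
  expect_identical(tite_weight(2, 4, 0), 0.5)
  expect_identical(tite_weight(4, 4, 0), 1)
  expect_identical(tite_weight(1, 12, 1), 1)     # DLT forces weight 1
  expect_error(tite_weight(5, 4, 0), "<= window")
  expect_error(tite_weight(-1, 4, 0), "<= window")
  expect_error(tite_weight(1, 0, 0), "positive")
})

test_that("an empty history returns the prior", {
  p <- bayes_posterior(trial_history(), sk6, emp,
                       prior_spec("normal", mean = 0, sd = sqrt(1.34)))
  expect_equal(p$mean_a, 0, tolerance = 1e-10)
  pe <- bayes_posterior(trial_history(), sk6, emp,
                        prior_spec("unit_exponential"))
  expect_equal(pe$mean_a, 1, tolerance = 5e-3)   # grid truncates the tail
})

test_that("every posterior density integrates to one", {
  set.seed(31)
  for (i in 1:20) {
    h <- random_history(sample(1:12, 1))
    p <- bayes_posterior(h, sk6, emp)
    expect_equal(sum(p$quad_weights * p$density), 1, tolerance = 1e-6)
    expect_true(all(p$density >= 0))
    expect_true(all(diff(dose_tox_estimates(p, "integrated")) > 0))
    expect_true(all(diff(dose_tox_estimates(p, "plugin")) > 0))
  }
})

test_that("posterior mean agrees with a Monte-Carlo oracle", {
  set.seed(32)
  h <- trial_history(3, 1)
  p <- bayes_posterior(h, sk6, emp, prior_spec("unit_exponential"))
  orc <- mc_posterior_oracle(h, sk6, emp, prior_spec("unit_exponential"),
                             ndraws = 2e5)
  expect_lt(abs(p$mean_a - orc$mean_a), 3 * orc$se_mean + 1e-4)
  est <- dose_tox_estimates(p, "integrated")
  expect_true(all(abs(est - orc$est) < 3 * orc$se_est + 1e-4))
})

test_that("integrated estimate matches a quadrature oracle", {
  # empty history, unit-exponential prior: estimate at x = 0.2 is
  # the integral of 0.2^(e^a) e^(-a) over a >= 0
  oracle <- integrate(function(a) 0.2^exp(a) * exp(-a), 0, Inf,
                      rel.tol = 1e-12)$value
  p <- bayes_posterior(trial_history(), sk6, emp,
                       prior_spec("unit_exponential"))
  expect_equal(dose_tox_estimates(p, "integrated")[3], oracle,
               tolerance = 5e-3)
})

test_that("a near-degenerate prior makes both estimate modes coincide", {
  astar <- 0.4
  p <- bayes_posterior(trial_history(), sk6, emp,
                       prior_spec("normal", mean = astar, sd = 1e-7))
  psi <- dlt_probability(emp, sk6$probs, astar)
  expect_equal(dose_tox_estimates(p, "integrated"), psi, tolerance = 1e-6)
  expect_equal(dose_tox_estimates(p, "plugin"), psi, tolerance = 1e-6)
})

test_that("the MLE matches its closed form and a grid search", {
  h <- trial_history(c(3, 3), c(1, 0))           # psi-hat = 0.5 at x = 0.2
  m <- mle_estimate(h, sk6, emp)
  expect_equal(exp(m$estimate), log(0.5) / log(0.2), tolerance = 1e-6)
  set.seed(33)
  for (i in 1:5) {
    h <- random_het_history(10)
    m <- mle_estimate(h, sk6, emp)
    expect_lt(abs(m$estimate - grid_mle_oracle(h, sk6, emp)), 1e-3)
  }
})

test_that("the MLE requires outcome heterogeneity", {
  h <- trial_history(c(3, 4), c(0, 0))
  expect_error(mle_estimate(h, sk6, emp),
               class = "crmdose_no_heterogeneity")
  h1 <- trial_history(c(3, 4), c(1, 1))
  expect_error(mle_estimate(h1, sk6, emp),
               class = "crmdose_no_heterogeneity")
})

test_that("full follow-up weights reproduce the unweighted posterior", {
  set.seed(34)
  for (i in 1:10) {
    n <- sample(2:10, 1)
    h <- random_history(n)
    h$followup <- rep(6, n)
    p_w <- bayes_posterior(h, sk6, emp, window = 6)
    p_u <- bayes_posterior(h, sk6, emp)
    expect_identical(p_w$mean_a, p_u$mean_a)
    expect_identical(p_w$density, p_u$density)
  }
})

test_that("new data moves the estimates in the right direction", {
  set.seed(35)
  for (i in 1:15) {
    h <- random_history(sample(2:10, 1))
    k <- sample.int(6, 1)
    base <- dose_tox_estimates(bayes_posterior(h, sk6, emp), "integrated")
    up <- dose_tox_estimates(
      bayes_posterior(append_dlt(h, k, 1L), sk6, emp), "integrated")
    dn <- dose_tox_estimates(
      bayes_posterior(append_dlt(h, k, 0L), sk6, emp), "integrated")
    expect_gte(up[k], base[k] - 1e-12)
    expect_lte(dn[k], base[k] + 1e-12)
  }
})

test_that("long histories with extreme parameters stay finite", {
  set.seed(36)
  h <- random_history(100)
  d <- sk6$probs
  for (a in c(-10, -5, 5, 10)) {
    ll <- crm_likelihood(h, d, emp, a, log = TRUE)
    expect_true(is.finite(ll))
  }
  p <- bayes_posterior(h, sk6, emp)
  expect_true(all(is.finite(p$density)))
})

test_that("histories round-trip through delimited text", {
  h <- trial_history(c(3, 4, 5), c(0, 1, NA), followup = c(4, 4, 2))
  f <- tempfile(fileext = ".tsv")
  write_history(h, f)
  h2 <- read_history(f)
  expect_equal(as.data.frame(h), as.data.frame(h2))
  unlink(f)
})
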