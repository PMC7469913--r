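sk6 <- paper_skeleton()

crmb_design <- function(...) crm_design("CRMB", sk6, ...)

test_that("degenerate truths drive the trial to the boundary levels", {
  sc0 <- trial_scenario(rep(1e-12, 6), n = 12, n_trials = 1)
  r0 <- run_single_trial(crmb_design(), sc0, seed = 1)
  expect_identical(r0$n_dlt, 0L)
  expect_identical(r0$mtd, 6L)
  sc1 <- trial_scenario(rep(1 - 1e-12, 6), n = 12, n_trials = 1)
  r1 <- run_single_trial(crmb_design(), sc1, seed = 1)
  expect_identical(r1$n_dlt, r1$n)
  expect_identical(r1$mtd, 1L)
})

test_that("simulated trials are reproducible from their seed", {
  sc <- trial_scenario(motivating_truth, n = 10, n_trials = 1)
  a <- run_single_trial(crmb_design(), sc, seed = 99)
  b <- run_single_trial(crmb_design(), sc, seed = 99)
  expect_identical(a, b)
  oc1 <- run_batch(crmb_design(), trial_scenario(motivating_truth, n = 8,
                                                 n_trials = 20), seed = 5)
  oc2 <- run_batch(crmb_design(), trial_scenario(motivating_truth, n = 8,
                                                 n_trials = 20), seed = 5)
  expect_identical(oc1$mtd_dist, oc2$mtd_dist)
  expect_identical(oc1$avg_patients, oc2$avg_patients)
})

test_that("operating characteristics satisfy their accounting identities", {
  sc <- trial_scenario(motivating_truth, n = 8, n_trials = 40)
  oc <- run_batch(crmb_design(), sc, seed = 7)
  expect_equal(sum(oc$mtd_dist), 1, tolerance = 1e-9)
  expect_equal(sum(oc$avg_patients), 8)   # max_n always reached
  expect_equal(oc$pct_under + oc$pct_at + oc$pct_over, 1, tolerance = 1e-12)
  expect_identical(oc$true_mtd_level, 5L)
})

test_that("the engine path agrees with the public recommendation path", {
  sc <- trial_scenario(motivating_truth, n = 10, n_trials = 1)
  for (method in c("CRMB", "CRML", "EWOC")) {
    d <- if (method == "EWOC") crm_design("EWOC", sk6, alpha = 0.25)
         else crm_design(method, sk6)
    r <- run_single_trial(d, sc, seed = 123)
    h <- r$history
    # each patient's dose must equal the public recommendation computed
    # from the records before them
    for (j in 2:nrow(h)) {
      sub <- trial_history(h$dose_level[1:(j - 1)], h$outcome[1:(j - 1)])
      expect_identical(h$dose_level[j], recommend_dose(d, sub)$level,
                       label = sprintf("%s patient %d", method, j))
    }
    expect_identical(r$mtd, recommend_dose(d, h)$level)
  }
})

test_that("TITE timelines respect their support", {
  set.seed(55)
  sc <- trial_scenario(motivating_truth, n = 20, n_trials = 1)
  tl <- simulate_tite_timeline(sc, sample.int(6, 20, replace = TRUE),
                               window = 12)
  expect_true(all(diff(tl$arrival) >= 0))
  expect_true(all(is.na(tl$dlt_time) | (tl$dlt_time > 0 &
                                          tl$dlt_time <= 12)))
  expect_identical(is.na(tl$dlt_time), !tl$dlt)
})

test_that("slow accrual makes TITE-CRM equivalent to CRMB decisions", {
  # inter-arrival equal to the window: every earlier patient is fully
  # observed at each decision, so each dose equals the CRMB recommendation
  # on the resolved records
  d_tite <- crm_design("TITE_CRM", sk6, window = 4)
  d_crmb <- crm_design("CRMB", sk6)
  sc <- trial_scenario(motivating_truth, n = 12, n_trials = 1,
                       accrual_interval = 4)
  r <- run_single_trial(d_tite, sc, seed = 61)
  h <- r$history
  for (j in 2:nrow(h)) {
    sub <- trial_history(h$dose_level[1:(j - 1)], h$outcome[1:(j - 1)])
    expect_identical(h$dose_level[j], recommend_dose(d_crmb, sub)$level)
  }
})

test_that("concurrent accrual leaves early decisions at the prior", {
  # zero inter-arrival: all pending with weight 0, so every decision before
  # the end is the prior recommendation (start level under no-skip)
  d_tite <- crm_design("TITE_CRM", sk6, window = 4)
  sc <- trial_scenario(rep(1e-12, 6), n = 5, n_trials = 1,
                       accrual_interval = 0)
  r <- run_single_trial(d_tite, sc, seed = 62)
  expect_identical(r$history$dose_level[1], 3L)
  for (j in 2:5) {
    # all earlier patients pending with weight zero
    pend <- trial_history(r$history$dose_level[1:(j - 1)],
                          rep(NA_integer_, j - 1),
                          rep(0, j - 1))
    expect_identical(r$history$dose_level[j],
                     recommend_dose(d_tite, pend)$level)
  }
})

test_that("Monte-Carlo error shrinks with more replicates", {
  sc_small <- trial_scenario(motivating_truth, n = 8, n_trials = 60)
  sc_big <- trial_scenario(motivating_truth, n = 8, n_trials = 960)
  oc_s <- run_batch(crmb_design(), sc_small, seed = 11)
  oc_b <- run_batch(crmb_design(), sc_big, seed = 12)
  p <- oc_b$mtd_dist[oc_b$true_mtd_level]
  se <- sqrt(p * (1 - p)) * sqrt(1 / 60 + 1 / 960)
  expect_lt(abs(oc_s$mtd_dist[oc_s$true_mtd_level] - p), 4 * se)
})

test_that("the motivating scenario concentrates patients on upper levels", {
  sc <- trial_scenario(motivating_truth, n = 25, n_trials = 150)
  d <- crm_design("CRMB", sk6, model = dose_model("logistic1"))
  oc <- run_batch(d, sc, seed = 21)
  expect_gt(sum(oc$avg_patients[4:6]), sum(oc$avg_patients[1:3]))
})

test_that("scenario construction validates and warns", {
  expect_error(trial_scenario(c(0.1, 1.5)), "probabilities")
  expect_warning(trial_scenario(c(0.3, 0.1)), "nondecreasing")
  expect_error(trial_scenario(c(0.1, 0.2), n_trials = 0), "n_trials")
  d <- crm_design("CRMB", crm_skeleton(c(0.1, 0.25), 0.25, 2))
  expect_error(run_single_trial(d, trial_scenario(rep(0.1, 6)), 1),
               "disagree")
})
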