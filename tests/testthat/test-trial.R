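sk6 <- paper_skeleton()

new_crmb_trial <- function(max_n = 25)
  trial_start(crm_design("CRMB", sk6,
                         stopping = list(stopping_rule("max_n", n = max_n))))

new_tite_trial <- function(max_n = 25, window = 12)
  trial_start(crm_design("TITE_CRM", sk6, window = window,
                         stopping = list(stopping_rule("max_n", n = max_n))))

test_that("the first inclusion opens the trial at the start level", {
  tr <- new_crmb_trial()
  expect_identical(tr$status, "setup")
  expect_identical(next_dose(tr)$level, 3L)   # the design's start level
  tr <- include_patient(tr, outcome = 0)
  expect_identical(tr$status, "open")
  expect_identical(nrow(tr$history), 1L)
  expect_identical(tr$history$dose_level, 3L)
  expect_identical(tr$recommendations$recommended, 3L)
})

test_that("inclusions validate the dose level and respect stopping", {
  tr <- new_crmb_trial(max_n = 4)
  expect_error(include_patient(tr, outcome = 0, dose_level = 9),
               "outside the")
  for (i in 1:4) tr <- include_patient(tr, outcome = 0)
  expect_identical(tr$status, "stopped")
  expect_error(include_patient(tr, outcome = 0), "stopped")
})

test_that("clinician overrides are recorded next to the recommendation", {
  tr <- new_crmb_trial()
  tr <- include_patient(tr, outcome = 0, dose_level = 2)   # override
  expect_identical(tr$recommendations$recommended, 3L)
  expect_identical(tr$recommendations$administered, 2L)
})

test_that("pending outcomes block model recommendations outside TITE", {
  tr <- new_crmb_trial()
  tr <- include_patient(tr, outcome = 0)
  tr <- include_patient(tr, outcome = "pending", dose_level = 3)
  expect_error(next_dose(tr), "pending|resolved")
  # a new inclusion without an explicit dose is impossible while blocked
  expect_error(include_patient(tr, outcome = 0), "pending|resolved")
  tr <- update_pending(tr, 2, outcome = 0)
  expect_s3_class(next_dose(tr), "dose_recommendation")
})

test_that("pending updates advance follow-up and recompute weights", {
  tr <- new_tite_trial(window = 12)
  tr <- include_patient(tr, outcome = "pending", followup = 4)
  tr <- update_pending(tr, 1, followup = 8)
  expect_equal(summary(tr)$per_patient$weight, 8 / 12)
  expect_error(update_pending(tr, 1, followup = 5), "decrease")
  expect_error(update_pending(tr, 99, outcome = 0), "unknown")
  tr <- update_pending(tr, 1, outcome = 0, followup = 12)
  expect_equal(summary(tr)$per_patient$weight, 1)
  expect_error(update_pending(tr, 1, outcome = 1), "resolved")
})

test_that("pending inclusions must sit strictly inside the window", {
  tr <- new_tite_trial(window = 12)
  expect_error(include_patient(tr, outcome = "pending", followup = 12),
               "strictly below")
  expect_error(include_patient(tr, outcome = 0, followup = 14),
               "exceed")
})

test_that("corrections require a reason and replay the whole trial", {
  tr <- new_crmb_trial()
  tr <- include_patient(tr, outcome = 0)
  tr <- include_patient(tr, outcome = 0)
  tr <- include_patient(tr, outcome = 0)
  expect_error(modify_patient(tr, 2, outcome = 1), "reason")
  tr2 <- modify_patient(tr, 2, outcome = 1, reason = "lab review")
  expect_identical(tr2$history$outcome[2], 1L)
  # replay determinism: stored recommendations equal a fresh replay
  fresh <- crmdose:::replay_recommendations(tr2$design, tr2$history,
                                            tr2$recommendations)
  expect_identical(tr2$recommendations$recommended, fresh$recommended)
  # and the correction changed the downstream recommendation
  expect_false(identical(tr$recommendations$recommended,
                         tr2$recommendations$recommended) &&
                 identical(next_dose(tr)$level, next_dose(tr2)$level))
})

test_that("batch inclusion equals sequential inclusion and is atomic", {
  rows <- data.frame(dose_level = c(3, 3, 4), outcome = c(0, 0, 0),
                     followup = c(12, 12, 12))
  tb <- batch_include(new_tite_trial(), rows)
  ts <- new_tite_trial()
  for (r in 1:3)
    ts <- include_patient(ts, outcome = rows$outcome[r],
                          dose_level = rows$dose_level[r],
                          followup = rows$followup[r])
  expect_identical(as.data.frame(tb$history), as.data.frame(ts$history))
  expect_identical(tb$recommendations, ts$recommendations)
  expect_identical(next_dose(tb)$level, next_dose(ts)$level)
  # a malformed row aborts the whole batch
  bad <- rbind(rows, data.frame(dose_level = 3, outcome = 0, followup = 99))
  t0 <- new_tite_trial()
  expect_error(batch_include(t0, bad), "batch rejected")
  expect_identical(nrow(t0$history), 0L)
  expect_error(batch_include(new_crmb_trial(), rows), "time-to-event")
})

test_that("summaries conserve counts", {
  tr <- new_crmb_trial()
  expect_identical(nrow(summary(tr)$per_patient), 0L)
  tr <- include_patient(tr, outcome = 0, dose_level = 3)
  tr <- include_patient(tr, outcome = 1, dose_level = 3)
  tr <- include_patient(tr, outcome = 0, dose_level = 2)
  s <- summary(tr)
  expect_identical(sum(s$per_dose$n_treated), 3L)
  expect_true(all(s$per_dose$n_dlt <= s$per_dose$n_treated))
  expect_equal(s$per_dose$obs_rate[3], 0.5)
  expect_identical(s$trajectory$level, c(3L, 3L, 2L))
})

test_that("the design is frozen once the trial is open", {
  tr <- new_crmb_trial()
  d2 <- crm_design("CRMB", sk6, start_level = 2)
  tr <- replace_design(tr, d2)            # allowed during setup
  tr <- include_patient(tr, outcome = 0)
  expect_error(replace_design(tr, d2), "no longer be modified")
})

test_that("save/load round-trips the trial and its recommendations", {
  tr <- new_crmb_trial()
  tr <- include_patient(tr, outcome = 0)
  tr <- include_patient(tr, outcome = 1)
  before <- next_dose(tr)$level
  f <- tempfile(fileext = ".json")
  save_trial(tr, f)
  tr2 <- load_trial(f)
  expect_identical(as.data.frame(tr2$history), as.data.frame(tr$history))
  expect_identical(tr2$status, tr$status)
  expect_identical(length(tr2$audit), length(tr$audit))
  expect_identical(next_dose(tr2)$level, before)
  expect_equal(tr2$design$skeleton$probs, tr$design$skeleton$probs)
  unlink(f)
})

test_that("future schema versions and corrupt files are rejected", {
  tr <- new_crmb_trial()
  f <- tempfile(fileext = ".json")
  save_trial(tr, f)
  doc <- jsonlite::read_json(f)
  doc$schema_version <- 99L
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_error(load_trial(f), "schema version")
  writeLines("not json at all {", f)
  expect_error(load_trial(f), "corrupted")
  unlink(f)
})

test_that("audit log grows append-only with ISO timestamps", {
  tr <- new_crmb_trial()
  n0 <- length(tr$audit)
  tr <- include_patient(tr, outcome = 0)
  tr <- include_patient(tr, outcome = "pending", dose_level = 3)
  tr <- update_pending(tr, 2, outcome = 0)
  expect_identical(length(tr$audit), n0 + 3L)
  expect_true(all(grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}Z$",
                        vapply(tr$audit, `[[`, "", "time"))))
  expect_identical(vapply(tr$audit, `[[`, "", "action")[n0 + 1:3],
                   c("include", "include", "update"))
})

test_that("exported tables land as CSV", {
  tr <- new_crmb_trial()
  tr <- include_patient(tr, outcome = 0)
  dir <- tempfile()
  paths <- export_trial(tr, dir)
  expect_true(all(file.exists(paths)))
  pp <- read.csv(paths[1])
  expect_identical(nrow(pp), 1L)
  unlink(dir, recursive = TRUE)
})
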