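test_that("the outcome-deterministic AZD4877 curve always yields dose 4", {
  sc <- clinical_scenarios()$AZD4877
  for (nm in names(default_skeletons())) {
    r <- run_crm_trial(sc, extended_crm_config(nm), outcome_stream(sc, 1))
    expect_identical(r$selected_mtd, 4L)
    expect_identical(r$stop_reason, "seventh_patient_rule")
  }
})

test_that("with no DLTs stage 2 is never entered and the top dose is selected", {
  sc <- dose_scenario("all-safe", rep(0, 5))
  r <- run_crm_trial(sc, extended_crm_config("oquigley"), outcome_stream(sc, 1))
  expect_identical(r$stage_at_stop, 1L)
  expect_identical(r$selected_mtd, 5L)
  expect_identical(r$stop_reason, "seventh_patient_rule")
  # four escalation cohorts plus top-dose expansion to the per-dose cap
  expect_identical(r$n_total, 18L)
  expect_identical(r$n, c(3L, 3L, 3L, 3L, 6L))
})

test_that("stage 1 escalates one level per clean cohort from the lowest dose", {
  sc <- dose_scenario("s", c(0.1, 0.2, 0.3, 0.5, 0.7))
  # six clean patients, then a DLT mid-cohort at dose 3
  st <- replay_stream(sc, c(0, 0, 0, 0, 0, 0, 0, 1, rep(0, 25)))
  r <- run_crm_trial(sc, extended_crm_config("oquigley"), st)
  tr <- r$trace
  expect_equal(tr$dose[1:8], c(1, 1, 1, 2, 2, 2, 3, 3))
  expect_equal(tr$stage[1:8], rep(1, 8))
  # default: the interrupted cohort is abandoned, the model takes over
  expect_true(all(tr$stage[-(1:8)] == 2))
})

test_that("the stage-1 cohort can be configured to complete after a DLT", {
  sc <- dose_scenario("s", c(0.1, 0.2, 0.3, 0.5, 0.7))
  outs <- c(0, 0, 0, 1, 0, 0, rep(0, 24))
  r_int <- run_crm_trial(sc, extended_crm_config("oquigley"), replay_stream(sc, outs))
  r_fin <- run_crm_trial(sc, extended_crm_config("oquigley", finish_stage1_cohort = TRUE),
                         replay_stream(sc, outs))
  expect_identical(sum(r_int$trace$stage == 1), 4L)  # stops at the DLT patient
  expect_identical(sum(r_fin$trace$stage == 1), 6L)  # completes the cohort of 3
})

test_that("an early toxicity cluster triggers the safety stop with no MTD", {
  sc <- dose_scenario("hot", c(0.6, 0.7, 0.8, 0.9, 0.95))
  r <- run_crm_trial(sc, extended_crm_config("conservative"),
                     replay_stream(sc, c(1, 1, 1, 1, 1)))
  expect_identical(r$stop_reason, "safety_stop")
  expect_identical(r$selected_mtd, NA_integer_)
  expect_identical(r$stage_at_stop, 2L)
})

test_that("trials are reproducible and pure functions of the outcome stream", {
  sc <- clinical_scenarios()$AZD3514
  cfg <- extended_crm_config("sigmoidal")
  r1 <- run_crm_trial(sc, cfg, outcome_stream(sc, 314))
  r2 <- run_crm_trial(sc, cfg, outcome_stream(sc, 314))
  expect_identical(r1[c("selected_mtd", "n_total", "n", "t", "stop_reason")],
                   r2[c("selected_mtd", "n_total", "n", "t", "stop_reason")])
  expect_identical(r1$trace, r2$trace)

  # replaying the recorded outcomes reproduces the trial bit for bit
  stream <- outcome_stream(sc, 314)
  r3 <- run_crm_trial(sc, cfg, stream)
  r4 <- run_crm_trial(sc, cfg, replay_stream(sc, recorded_outcomes(stream)$dlt))
  expect_identical(r3$trace, r4$trace)
  expect_identical(r3$selected_mtd, r4$selected_mtd)
})

test_that("every trial trace honours the design constraints", {
  set.seed(5)
  scens <- builtin_scenarios()
  models <- names(default_skeletons())
  for (i in 1:40) {
    sc <- scens[[sample(length(scens), 1)]]
    cfg <- extended_crm_config(sample(models, 1))
    r <- run_crm_trial(sc, cfg, outcome_stream(sc, 20000 + i))
    tr <- r$trace
    expect_identical(tr$dose[1], 1L)                  # first patient at dose 1
    expect_true(all(diff(tr$dose) <= 1))             # no dose skipping
    expect_true(all(r$n <= cfg$per_dose_cap))
    expect_lte(r$n_total, cfg$max_n)
    expect_true(all(r$t <= r$n))
    cnt <- trace_counts(tr, sc$n_doses)
    expect_equal(cnt$n, r$n)
    expect_equal(cnt$t, r$t)
    expect_true(r$stop_reason %in% c("seventh_patient_rule", "safety_stop", "max_n"))
    if (r$stop_reason == "safety_stop") expect_identical(r$selected_mtd, NA_integer_)
  }
})

test_that("abundant clean data at a dose keeps the recommendation there or above", {
  # skeleton agreeing with a mostly-safe truth; all outcomes clean at dose 4
  model <- crm_model("oquigley")
  post <- posterior_update(model, list(n = c(3, 3, 3, 12, 0), t = c(0, 0, 0, 0, 0)))
  expect_gte(recommend_dose(post, 0.33, 4L), 4L)
})
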