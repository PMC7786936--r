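test_that("two or more DLTs at the lowest dose end the trial with no MTD", {
  st <- step_3p3(new_3p3_state(5), 3L)
  expect_true(st$finished)
  expect_identical(st$mtd, NA_integer_)
  st <- step_3p3(new_3p3_state(5), 2L)
  expect_true(st$finished)
  expect_identical(st$mtd, NA_integer_)
})

test_that("one DLT in six leads to escalation", {
  st <- new_3p3_state(5)
  st <- step_3p3(st, 0L)            # dose 1: 0/3, escalate
  expect_identical(st$dose, 2L)
  st <- step_3p3(st, 1L)            # dose 2: 1/3, expand
  expect_identical(st$dose, 2L)
  expect_false(st$finished)
  st <- step_3p3(st, 0L)            # dose 2: 1/6 total, escalate
  expect_identical(st$dose, 3L)
})

test_that("a toxic top dose de-escalates and expands the dose below", {
  st <- new_3p3_state(5)
  for (k in 1:4) st <- step_3p3(st, 0L)   # clean cohorts at doses 1..4
  expect_identical(st$dose, 5L)
  st <- step_3p3(st, 3L)                  # 3/3 at the top: too toxic
  expect_false(st$finished)
  expect_identical(st$dose, 4L)           # expand dose 4 (3 patients, 0 DLT)
  st <- step_3p3(st, 0L)
  expect_true(st$finished)
  expect_identical(st$mtd, 4L)
  expect_identical(sum(st$n), 18L)
})

test_that("de-escalation into a dose already carrying six declares it MTD", {
  st <- new_3p3_state(5)
  st <- step_3p3(st, 0L)   # dose 1 clean
  st <- step_3p3(st, 1L)   # dose 2: 1/3 -> expand
  st <- step_3p3(st, 0L)   # dose 2: 1/6 -> escalate with 6 on board
  expect_identical(st$dose, 3L)
  st <- step_3p3(st, 2L)   # dose 3 toxic -> dose 2 already has 6 with 1 DLT
  expect_true(st$finished)
  expect_identical(st$mtd, 2L)
})

test_that("the no-de-escalation variant declares the dose below immediately", {
  st <- new_3p3_state(5, "no-de-escalation")
  st <- step_3p3(st, 0L)
  st <- step_3p3(st, 2L)
  expect_true(st$finished)
  expect_identical(st$mtd, 1L)
  expect_identical(st$n[1], 3L)   # never expanded to six under this variant
})

test_that("degenerate curves give deterministic trials", {
  # AZD4877: all true probabilities 0 or 1 -> a single possible trace
  r <- run_3p3_trial("AZD4877", outcome_stream(clinical_scenarios()$AZD4877, 1))
  expect_identical(r$selected_mtd, 4L)
  expect_identical(r$n_total, 18L)

  r <- run_3p3_trial(rep(1, 5), outcome_stream(rep(1, 5), 1))
  expect_identical(r$selected_mtd, NA_integer_)
  expect_identical(r$n_total, 3L)
  expect_identical(r$stop_reason, "lowest_dose_too_toxic")

  r <- run_3p3_trial(rep(0, 5), outcome_stream(rep(0, 5), 1))
  expect_identical(r$selected_mtd, 5L)
})

test_that("exact enumeration is a probability distribution with known anchors", {
  for (sc in builtin_scenarios()) {
    d <- exact_3p3_distribution(sc)
    expect_equal(sum(d$mass), 1, tolerance = 1e-12)
    expect_true(all(d$mass >= 0))
    expect_lte(d$expected_n, 6 * sc$n_doses)
  }
  expect_equal(exact_3p3_distribution("AZD4877")$mass[["dose4"]], 1)
  expect_equal(exact_3p3_distribution("AZD4877")$expected_n, 18)
  # the selection probability for the true AZD3514 MTD, from first principles
  expect_equal(exact_3p3_distribution("AZD3514")$mass[["dose3"]], 0.649,
               tolerance = 0.001)
})

test_that("Monte-Carlo frequencies agree with the enumeration oracle", {
  for (scn in c("AZD3514", "AZD1208", "AZD1480")) {
    ex <- exact_3p3_distribution(scn)
    batch <- run_replicates("3p3", scn, reps = 1000, master_seed = 404)
    sel <- ifelse(is.na(batch$selected), "none", paste0("dose", batch$selected))
    for (key in names(ex$mass)) {
      p <- ex$mass[[key]]
      se <- sqrt(p * (1 - p) / 1000)
      expect_lt(abs(mean(sel == key) - p), 3 * se + 1e-12)
    }
  }
})

test_that("every selected MTD carries six patients with at most one DLT", {
  set.seed(88)
  scens <- builtin_scenarios()
  for (i in 1:60) {
    sc <- scens[[sample(length(scens), 1)]]
    r <- run_3p3_trial(sc, outcome_stream(sc, 10000 + i))
    expect_lte(r$n_total, 6 * sc$n_doses)
    expect_true(all(r$n <= 6))
    expect_true(all(r$t <= r$n))
    if (!is.na(r$selected_mtd)) {
      expect_identical(r$n[r$selected_mtd], 6L)
      expect_lte(r$t[r$selected_mtd], 1L)
    } else {
      expect_gte(r$t[1], 2L)
    }
  }
})
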