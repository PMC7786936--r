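test_that("dose labels backsolve the skeleton exactly at the prior-central slope", {
  expect_equal(backsolve_labels(0.5, a0 = 3), -3)
  expect_equal(backsolve_labels(0.05, a0 = 3), log(1 / 19) - 3)
  expect_equal(backsolve_labels(0.05, a0 = 3), -5.94443898, tolerance = 1e-8)
  for (nm in names(default_skeletons())) {
    p0 <- default_skeletons()[[nm]]
    expect_equal(psi_logistic(backsolve_labels(p0), 0), p0)
  }
  expect_error(backsolve_labels(c(0, 0.5)), "strictly inside")
})

test_that("the logistic working model behaves at its anchor points and limits", {
  expect_equal(psi_logistic(-3, 0), 0.5)
  expect_equal(psi_logistic(-5.94443898, 0), 0.05, tolerance = 1e-8)
  # as the slope vanishes every dose collapses to plogis(a0)
  expect_equal(psi_logistic(-3, -50), plogis(3), tolerance = 1e-12)
  expect_equal(psi_logistic(-7, -50), plogis(3), tolerance = 1e-12)
  # monotone in the dose label
  b <- rnorm(5)
  for (bb in b) expect_true(all(diff(psi_logistic(seq(-8, -1, 0.5), bb)) > 0))
})

test_that("posterior quadrature matches the dense-grid oracle to 1e-6", {
  datasets <- list(
    list(n = c(0, 0, 0, 0, 0), t = c(0, 0, 0, 0, 0)),   # prior
    list(n = c(1, 0, 0, 0, 0), t = c(0, 0, 0, 0, 0)),   # one clean patient
    list(n = c(0, 0, 1, 0, 0), t = c(0, 0, 1, 0, 0)),   # one DLT at dose 3
    list(n = c(3, 3, 6, 2, 0), t = c(0, 0, 1, 1, 0)),   # mid-trial mix
    list(n = c(3, 3, 3, 6, 6), t = c(0, 0, 0, 0, 6)))   # concentrated
  for (nm in c("oquigley", "conservative", "aggressive")) {
    model <- crm_model(nm)
    for (d in datasets) {
      post <- posterior_update(model, d)
      expect_lt(max(abs(post$p_hat - trapezoid_posterior(
        default_skeletons()[[nm]], d$n, d$t))), 1e-6)
      expect_lt(post$integration_error, model$tol)
    }
  }
})

test_that("the prior mean DLT probability differs from the skeleton (Jensen)", {
  model <- crm_model("oquigley")
  prior <- posterior_update(model)
  expect_gt(max(abs(prior$p_hat - model$skeleton$p0)), 0.01)
  expect_true(all(diff(prior$p_hat) > 0))
})

test_that("normalizing constants agree across quadrature resolutions", {
  d <- list(n = c(3, 3, 3, 2, 0), t = c(0, 0, 1, 1, 0))
  z1 <- posterior_update(crm_model("oquigley", nodes = 321), d)$log_Z
  z2 <- posterior_update(crm_model("oquigley", nodes = 801), d)$log_Z
  expect_lt(abs(exp(z1 - z2) - 1), 1e-8)
})

test_that("a DLT raises and a non-DLT lowers every estimated probability", {
  set.seed(11)
  for (i in 1:12) {
    nm <- sample(names(default_skeletons()), 1)
    model <- crm_model(nm)
    n <- rbinom(5, 4, 0.5)
    t <- rbinom(5, n, 0.3)
    base <- posterior_update(model, list(n = n, t = t))$p_hat
    d <- sample(5, 1)
    n2 <- n; n2[d] <- n2[d] + 1
    with_dlt <- posterior_update(model, list(n = n2, t = `[<-`(t, d, t[d] + 1)))$p_hat
    without <- posterior_update(model, list(n = n2, t = t))$p_hat
    expect_true(all(with_dlt > base))
    expect_true(all(without < base))
    expect_true(all(diff(base) > 0))       # strictly increasing in dose
  }
})

test_that("the posterior depends only on sufficient statistics, not order", {
  model <- crm_model("sigmoidal")
  pts <- data.frame(dose = c(1, 1, 1, 2, 2, 2, 3, 3), dlt = c(0, 0, 0, 0, 0, 1, 0, 1))
  p1 <- posterior_update(model, pts)$p_hat
  set.seed(3)
  p2 <- posterior_update(model, pts[sample(nrow(pts)), ])$p_hat
  p3 <- posterior_update(model, list(n = c(3, 3, 2, 0, 0), t = c(0, 1, 1, 0, 0)))$p_hat
  expect_identical(p1, p2)
  expect_identical(p1, p3)
})

test_that("quadrature failure is raised rather than silently degraded", {
  model <- crm_model("oquigley", nodes = 21, tol = 1e-12)
  expect_error(posterior_update(model, list(n = c(3, 3, 3, 6, 6), t = c(0, 0, 0, 0, 6))),
               "failed to converge")
})

test_that("dose recommendation honours the target and the no-skip rule", {
  expect_identical(recommend_dose(c(0.10, 0.20, 0.30, 0.40, 0.50), 0.33, 2L), 3L)
  # unconstrained pick would be dose 4; no-skip caps at current + 1
  expect_identical(recommend_dose(c(0.01, 0.05, 0.10, 0.32, 0.40), 0.33, 1L), 2L)
  expect_identical(recommend_dose(c(0.40, 0.5, 0.6, 0.7, 0.8), 0.33, 1L), NA_integer_)
  # boundary equality is admissible
  expect_identical(recommend_dose(c(0.05, 0.33, 0.50), 0.33, 1L), 2L)
})

test_that("final MTD selection is uncapped and inclusive at the target", {
  expect_identical(select_final_mtd(c(0.10, 0.20, 0.30, 0.40, 0.50), 0.33), 3L)
  expect_identical(select_final_mtd(c(0.40, 0.45, 0.50), 0.33), NA_integer_)
  expect_identical(select_final_mtd(c(0.05, 0.33, 0.50), 0.33), 2L)
  # no adjacency cap: far doses are eligible at selection time
  expect_identical(select_final_mtd(c(0.01, 0.02, 0.03, 0.04, 0.05), 0.33), 5L)
})
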