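#' Configuration for the two-stage extended CRM design
#'
#' Bundles the design parameters of the extended CRM: stage 1 escalates in
#' cohorts of three from the lowest dose until the first DLT; stage 2 is
#' model-guided with single-patient cohorts. At most six patients may be
#' treated at any one dose — when the model recommends a seventh the trial
#' stops and the MTD is estimated from the final posterior — and the total
#' sample size is capped (30 for five doses).
#'
#' @param skeleton A `crm_skeleton`, skeleton name, or numeric vector.
#' @param target Maximum acceptable DLT probability; default 0.33.
#' @param a0,prior_mean,prior_var,nodes,span_sd,estimate Passed to
#'   [crm_model()].
#' @param stage1_cohort Stage-1 cohort size; default 3 (Goodman's
#'   modification, matching the 3+3 comparator).
#' @param stage2_cohort Stage-2 cohort size; default 1 (per-patient
#'   updating).
#' @param per_dose_cap Maximum patients on one dose; default 6.
#' @param max_n Maximum total sample size; default 30.
#' @param finish_stage1_cohort If `FALSE` (default) the stage-1 cohort is
#'   interrupted at the first DLT and the model takes over with the next
#'   patient; if `TRUE` the cohort of three is completed first.
#' @return Object of class `extended_crm_config`.
#' @export
extended_crm_config <- function(skeleton, target = 0.33, a0 = 3,
                                prior_mean = 0, prior_var = 1.34,
                                nodes = 321L, span_sd = 8,
                                estimate = c("posterior_mean_p", "plugin"),
                                stage1_cohort = 3L, stage2_cohort = 1L,
                                per_dose_cap = 6L, max_n = 30L,
                                finish_stage1_cohort = FALSE) {
  structure(
    list(skeleton = skeleton, target = target, a0 = a0,
         prior_mean = prior_mean, prior_var = prior_var,
         nodes = nodes, span_sd = span_sd, estimate = match.arg(estimate),
         stage1_cohort = as.integer(stage1_cohort),
         stage2_cohort = as.integer(stage2_cohort),
         per_dose_cap = as.integer(per_dose_cap),
         max_n = as.integer(max_n),
         finish_stage1_cohort = isTRUE(finish_stage1_cohort)),
    class = "extended_crm_config")
}

#' Run one simulated two-stage extended CRM trial
#'
#' Stage 1 enrolls cohorts (default three patients) starting at the lowest
#' dose and escalates one level after each DLT-free cohort; at the top
#' dose it expands until the per-dose cap would be exceeded. The first
#' observed DLT hands control to the CRM, which after every subsequent
#' patient refits the posterior, stops for safety if the estimated DLT
#' probability at the lowest dose exceeds the target, and otherwise
#' assigns the highest dose with estimated toxicity at or below the
#' target, never more than one level above the last administered dose.
#' The trial ends when the model recommends a dose already holding the
#' per-dose cap of patients (a "seventh patient"), when the sample-size
#' cap is reached, or at a safety stop; except after a safety stop the
#' MTD is then estimated from the final posterior via
#' [select_final_mtd()].
#'
#' @param scenario A [dose_scenario] or built-in scenario name.
#' @param config An [extended_crm_config()] (or a skeleton, from which a
#'   default config is built).
#' @param stream An [outcome_stream()].
#' @param keep_phat If `TRUE`, store the per-step posterior `p_hat`
#'   vectors in the trace (stage 2 only).
#' @return Object of class `trial_result` with `selected_mtd`, `n_total`,
#'   per-dose `n`/`t`, `stop_reason` (`"seventh_patient_rule"`,
#'   `"safety_stop"`, or `"max_n"`), `stage_at_stop`, and a per-patient
#'   `trace`.
#' @export
run_crm_trial <- function(scenario, config, stream, keep_phat = FALSE) {
  scenario <- as_scenario(scenario)
  if (!inherits(config, "extended_crm_config")) config <- extended_crm_config(config)
  K <- scenario$n_doses
  model <- crm_model(as_skeleton(config$skeleton, K),
                     a0 = config$a0, prior_mean = config$prior_mean,
                     prior_var = config$prior_var, target = config$target,
                     nodes = config$nodes, span_sd = config$span_sd,
                     estimate = config$estimate)
  run_crm_trial_fitted(scenario, config, model, stream, keep_phat)
}

# Internal runner taking a prebuilt crm_model, so replicate drivers can
# reuse the quadrature grids across trials.
run_crm_trial_fitted <- function(scenario, config, model, stream,
                                 keep_phat = FALSE) {
  K <- scenario$n_doses
  n <- integer(K); t <- integer(K)
  trace <- vector("list", config$max_n)
  phats <- if (keep_phat) vector("list", config$max_n) else NULL
  n_total <- 0L
  dose <- 1L                      # first patient always at the lowest dose
  stage <- 1L
  stop_reason <- NULL
  selected <- NA_integer_
  seen_dlt <- FALSE
  cohort_left <- config$stage1_cohort

  enroll <- function(d) {
    out <- draw_outcome(stream, d)
    n_total <<- n_total + 1L
    n[d] <<- n[d] + 1L
    t[d] <<- t[d] + out
    trace[[n_total]] <<- c(patient = n_total, dose = d, dlt = out, stage = stage)
    out
  }
  final_select <- function() {
    post <- posterior_update(model, list(n = n, t = t))
    select_final_mtd(post, config$target)
  }

  # ---- stage 1: rule-based escalation until the first DLT ----
  while (stage == 1L) {
    if (n[dose] >= config$per_dose_cap) {
      # the escalation rule would assign a 7th patient to this dose
      stop_reason <- "seventh_patient_rule"
      selected <- final_select()
      break
    }
    if (n_total >= config$max_n) {
      stop_reason <- "max_n"
      selected <- final_select()
      break
    }
    out <- enroll(dose)
    cohort_left <- cohort_left - 1L
    if (out == 1L) seen_dlt <- TRUE
    if (seen_dlt && (!config$finish_stage1_cohort || cohort_left == 0L)) {
      stage <- 2L
      break
    }
    if (cohort_left == 0L) {
      if (dose < K) dose <- dose + 1L    # no skipping: one level per cohort
      cohort_left <- config$stage1_cohort
    }
  }

  # ---- stage 2: CRM-guided single-patient cohorts ----
  if (is.null(stop_reason) && stage == 2L) {
    repeat {
      post <- posterior_update(model, list(n = n, t = t))
      if (keep_phat) phats[[max(n_total, 1L)]] <- post$p_hat
      if (post$p_hat[1L] > config$target) {
        # estimated toxicity at the lowest dose exceeds the target
        stop_reason <- "safety_stop"
        selected <- NA_integer_
        break
      }
      rec <- recommend_dose(post, config$target, dose)
      if (n[rec] >= config$per_dose_cap) {
        stop_reason <- "seventh_patient_rule"
        selected <- select_final_mtd(post, config$target)
        break
      }
      if (n_total >= config$max_n) {
        stop_reason <- "max_n"
        selected <- select_final_mtd(post, config$target)
        break
      }
      dose <- rec
      cohort <- min(config$stage2_cohort, config$max_n - n_total)
      for (i in seq_len(cohort)) enroll(dose)
    }
  }

  trace <- as.data.frame(do.call(rbind, trace[seq_len(n_total)]))
  structure(
    list(design = "crm",
         skeleton = model$skeleton$name,
         selected_mtd = selected,
         n_total = n_total, n = n, t = t,
         stop_reason = stop_reason,
         stage_at_stop = stage,
         trace = trace,
         p_hat_trace = if (keep_phat) phats[!vapply(phats, is.null, logical(1))]),
    class = "trial_result")
}
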