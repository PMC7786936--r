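#' Run replicate trials of a design under a scenario
#'
#' The Monte-Carlo driver. Replicate `r` draws its outcomes from an
#' [outcome_stream()] seeded with `master_seed + r` — a documented,
#' order-independent splitting rule: a replicate's result never depends on
#' which other replicates ran, and running two designs with the same
#' `master_seed` exposes them to common random numbers.
#'
#' @param design `"3p3"` or `"crm"`.
#' @param scenario A [dose_scenario] or built-in scenario name.
#' @param skeleton Required for `design = "crm"`: skeleton name, vector,
#'   or `crm_skeleton`. Ignored for `"3p3"`.
#' @param reps Number of replicate trials; the published analysis used
#'   1000 per curve.
#' @param master_seed Integer master seed.
#' @param config Optional [extended_crm_config()] overriding the defaults
#'   (CRM only).
#' @param variant 3+3 variant, see [new_3p3_state()].
#' @return Object of class `replicate_batch`: a data.frame with one row
#'   per replicate (`replicate`, `seed`, `scenario`, `design`, `skeleton`,
#'   `selected`, `true_mtd`, `determined`, `n_total`, `stop_reason`) and
#'   attributes `scenario`, `master_seed`.
#' @export
run_replicates <- function(design = c("3p3", "crm"), scenario, skeleton = NULL,
                           reps = 1000L, master_seed = 1L, config = NULL,
                           variant = c("de-escalation", "no-de-escalation")) {
  design <- match.arg(design)
  variant <- match.arg(variant)
  scenario <- as_scenario(scenario)
  stopifnot(reps >= 1L)
  K <- scenario$n_doses

  model <- NULL
  if (design == "crm") {
    if (is.null(config)) {
      if (is.null(skeleton)) stop("design 'crm' requires a skeleton")
      config <- extended_crm_config(skeleton)
    }
    model <- crm_model(as_skeleton(config$skeleton, K),
                       a0 = config$a0, prior_mean = config$prior_mean,
                       prior_var = config$prior_var, target = config$target,
                       nodes = config$nodes, span_sd = config$span_sd,
                       estimate = config$estimate)
  }

  run_one <- function(r) {
    stream <- outcome_stream(scenario$curve, master_seed + r)
    res <- tryCatch(
      if (design == "3p3") run_3p3_trial(scenario, stream, variant)
      else run_crm_trial_fitted(scenario, config, model, stream),
      error = function(e) stop("replicate ", r, " failed: ", conditionMessage(e)))
    data.frame(replicate = r, seed = master_seed + r,
               scenario = scenario$name, design = design,
               skeleton = if (design == "crm") model$skeleton$name else NA_character_,
               selected = res$selected_mtd,
               true_mtd = scenario$true_mtd,
               determined = !is.na(res$selected_mtd),
               n_total = res$n_total,
               stop_reason = res$stop_reason)
  }
  out <- do.call(rbind, lapply(seq_len(reps), run_one))
  attr(out, "scenario") <- scenario
  attr(out, "master_seed") <- master_seed
  class(out) <- c("replicate_batch", "data.frame")
  out
}

#' Sweep designs, skeletons and scenarios
#'
#' Runs [run_replicates()] over the cross of the given scenarios with the
#' 3+3 design and/or the extended CRM under each skeleton, and binds the
#' per-scenario summaries into one table — the shape of the published
#' operating-characteristics grids. Each scenario uses its own seed block
#' (`master_seed + 100000 * combo_index`) so combinations are independent
#' while the two designs within a combination can share randomness.
#'
#' @param scenarios List of [dose_scenario]s (or names); default all
#'   built-ins.
#' @param skeletons Character vector of skeleton names for the CRM rows;
#'   `NULL` for none.
#' @param include_3p3 Include the 3+3 rows; default `TRUE`.
#' @param reps Replicates per combination.
#' @param master_seed Integer master seed.
#' @return data.frame of per-combination summaries (see
#'   [summarize_scenario()]).
#' @export
sweep_designs <- function(scenarios = builtin_scenarios(),
                          skeletons = names(default_skeletons()),
                          include_3p3 = TRUE, reps = 1000L, master_seed = 1L) {
  scenarios <- lapply(scenarios, as_scenario)
  combos <- list()
  ci <- 0L
  for (sc in scenarios) {
    seed_sc <- master_seed + 100000L * ci
    ci <- ci + 1L
    if (include_3p3) {
      combos[[length(combos) + 1L]] <- summarize_scenario(
        run_replicates("3p3", sc, reps = reps, master_seed = seed_sc))
    }
    for (sk in skeletons) {
      combos[[length(combos) + 1L]] <- summarize_scenario(
        run_replicates("crm", sc, skeleton = sk, reps = reps,
                       master_seed = seed_sc))
    }
  }
  do.call(rbind, combos)
}
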