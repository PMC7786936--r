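#' Initialise a 3+3 trial state
#'
#' The 3+3 design is represented as a pure decision state machine: the
#' state holds per-dose enrollment and DLT counts, the dose at which the
#' next cohort of three will be enrolled, and — once finished — the
#' declared MTD. Feeding cohort outcomes through [step_3p3()] advances the
#' state deterministically.
#'
#' @param K Number of dose levels.
#' @param variant `"de-escalation"` (default): after a toxic dose the next
#'   lower dose must be expanded to six patients with at most one DLT
#'   before it can be declared the MTD. `"no-de-escalation"`: a toxic dose
#'   immediately declares the dose below it as MTD.
#' @return Object of class `three_plus_three_state`.
#' @export
new_3p3_state <- function(K, variant = c("de-escalation", "no-de-escalation")) {
  stopifnot(K >= 2L)
  structure(
    list(K = as.integer(K), n = integer(K), t = integer(K), dose = 1L,
         finished = FALSE, mtd = NA_integer_,
         variant = match.arg(variant),
         trace = data.frame(dose = integer(0), dlts = integer(0))),
    class = "three_plus_three_state")
}

# Resolution when a dose proves too toxic (>= 2 DLTs among its patients).
too_toxic_3p3 <- function(state) {
  d <- state$dose
  if (d == 1L) {
    # two or more DLTs at the lowest dose: the MTD cannot be determined
    state$finished <- TRUE
    state$mtd <- NA_integer_
    return(state)
  }
  if (state$variant == "no-de-escalation") {
    state$finished <- TRUE
    state$mtd <- d - 1L
    return(state)
  }
  if (state$n[d - 1L] >= 6L) {
    # the dose below already carries 6 patients with <= 1 DLT (it was
    # escalated from), so it is the MTD
    state$finished <- TRUE
    state$mtd <- d - 1L
  } else {
    # expand the dose below (it has 3 patients, 0 DLTs) to 6
    state$dose <- d - 1L
  }
  state
}

#' Advance a 3+3 trial by one cohort
#'
#' Applies the 3+3 decision rules to the outcome of a cohort of three
#' enrolled at the state's current dose: 0/3 DLTs escalate (or expand the
#' top dose), 1/3 expands the same dose to six, two or more DLTs among a
#' dose's patients mark it too toxic and trigger de-escalation. A dose is
#' declared the MTD only when it carries six patients with at most one DLT
#' and no higher dose remains admissible; two or more DLTs at the lowest
#' dose end the trial with no MTD.
#'
#' @param state A `three_plus_three_state` (not finished).
#' @param cohort_dlt_count Number of DLTs (0..3) in the cohort of three
#'   just treated at `state$dose`.
#' @return The updated state; check `$finished` and `$mtd`.
#' @export
step_3p3 <- function(state, cohort_dlt_count) {
  stopifnot(inherits(state, "three_plus_three_state"))
  if (state$finished) stop("trial already finished")
  k <- as.integer(cohort_dlt_count)
  if (k < 0L || k > 3L) stop("'cohort_dlt_count' must be between 0 and 3")
  d <- state$dose
  state$n[d] <- state$n[d] + 3L
  state$t[d] <- state$t[d] + k
  state$trace <- rbind(state$trace, data.frame(dose = d, dlts = k))

  if (state$t[d] >= 2L) return(too_toxic_3p3(state))

  if (state$n[d] == 3L) {
    if (k == 1L) return(state)            # expand this dose to 6
    # 0/3: escalate, or expand the top dose
    if (d < state$K) state$dose <- d + 1L
    return(state)
  }
  # n == 6 with <= 1 DLT: escalate if an untried dose remains above,
  # otherwise this is the MTD
  if (d < state$K && state$n[d + 1L] == 0L) {
    state$dose <- d + 1L
  } else {
    state$finished <- TRUE
    state$mtd <- d
  }
  state
}

#' @export
print.three_plus_three_state <- function(x, ...) {
  status <- if (x$finished) {
    if (is.na(x$mtd)) "finished: MTD not determined" else
      paste0("finished: MTD = dose ", x$mtd)
  } else paste0("enrolling cohort at dose ", x$dose)
  cat("<three_plus_three_state>", status, "\n")
  print(data.frame(dose = seq_len(x$K), n = x$n, dlt = x$t))
  invisible(x)
}

#' Run one simulated 3+3 trial
#'
#' @param scenario A [dose_scenario], built-in scenario name, or bare
#'   numeric true curve.
#' @param stream An [outcome_stream()] supplying per-patient outcomes.
#' @param variant See [new_3p3_state()].
#' @return Object of class `trial_result` with `selected_mtd` (dose index
#'   or `NA`), `n_total`, per-dose `n`/`t`, `stop_reason`, and the
#'   per-cohort decision `trace`.
#' @export
run_3p3_trial <- function(scenario, stream,
                          variant = c("de-escalation", "no-de-escalation")) {
  curve <- if (is.numeric(scenario)) scenario else as_scenario(scenario)$curve
  state <- new_3p3_state(length(curve), match.arg(variant))
  while (!state$finished) {
    k <- sum(vapply(1:3, function(i) draw_outcome(stream, state$dose), integer(1)))
    state <- step_3p3(state, k)
  }
  structure(
    list(design = "3p3",
         selected_mtd = state$mtd,
         n_total = sum(state$n),
         n = state$n, t = state$t,
         stop_reason = if (is.na(state$mtd)) "lowest_dose_too_toxic" else "mtd_declared",
         trace = state$trace),
    class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  sel <- if (is.na(x$selected_mtd)) "not determined" else paste0("dose ", x$selected_mtd)
  cat(sprintf("<trial_result> design %s | MTD %s | n = %d | stop: %s\n",
              x$design, sel, x$n_total, x$stop_reason))
  print(data.frame(dose = seq_along(x$n), n = x$n, dlt = x$t))
  invisible(x)
}

#' Exact operating characteristics of the 3+3 design
#'
#' Exhaustively enumerates every cohort-outcome path of the 3+3 state
#' machine under a true curve, weighting each path by its binomial
#' probability. Cohort outcomes are grouped into decision-equivalent
#' classes (e.g. 2/3 and 3/3 DLTs trigger identical actions), so the tree
#' is small and the resulting MTD selection distribution is exact — it is
#' the infinite-replicate limit of [run_3p3_trial()] frequencies.
#'
#' @inheritParams run_3p3_trial
#' @return Object of class `mtd_distribution`: `mass` (named probabilities
#'   over dose 1..K and `"none"`, summing to 1) and `expected_n`.
#' @export
exact_3p3_distribution <- function(scenario,
                                   variant = c("de-escalation", "no-de-escalation")) {
  curve <- if (is.numeric(scenario)) scenario else as_scenario(scenario)$curve
  variant <- match.arg(variant)
  K <- length(curve)
  if (K > 10L) stop("enumeration supports at most 10 dose levels")
  acc <- new.env(parent = emptyenv())
  acc$mass <- stats::setNames(numeric(K + 1L), c(paste0("dose", 1:K), "none"))
  acc$en <- 0

  recurse <- function(state, prob) {
    if (state$finished) {
      key <- if (is.na(state$mtd)) "none" else paste0("dose", state$mtd)
      acc$mass[key] <- acc$mass[key] + prob
      acc$en <- acc$en + prob * sum(state$n)
      return(invisible(NULL))
    }
    d <- state$dose
    p <- curve[d]
    pk <- stats::dbinom(0:3, 3, p)
    # decision-equivalent classes: representative DLT count -> class probability
    classes <- if (state$n[d] == 0L) {
      list(c(0L, pk[1]), c(1L, pk[2]), c(2L, pk[3] + pk[4]))
    } else if (state$t[d] == 0L) {
      list(c(0L, pk[1] + pk[2]), c(2L, pk[3] + pk[4]))
    } else {                       # t = 1 among the first three
      list(c(0L, pk[1]), c(1L, pk[2] + pk[3] + pk[4]))
    }
    for (cl in classes) {
      if (cl[2] > 0) recurse(step_3p3(state, cl[1]), prob * cl[2])
    }
    invisible(NULL)
  }
  recurse(new_3p3_state(K, variant), 1)

  total <- sum(acc$mass)
  if (abs(total - 1) > 1e-12) {
    stop(sprintf("enumeration mass %.15f does not sum to 1", total))
  }
  structure(list(mass = acc$mass, expected_n = acc$en, variant = variant),
            class = "mtd_distribution")
}

#' @export
print.mtd_distribution <- function(x, ...) {
  cat("<mtd_distribution> 3+3 (", x$variant, ") exact selection probabilities\n", sep = "")
  print(round(x$mass, 4))
  cat(sprintf("expected sample size: %.2f\n", x$expected_n))
  invisible(x)
}
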