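#' Monotonize an observed dose-toxicity curve
#'
#' Enforces the non-decreasing dose-toxicity assumption on a vector of
#' observed DLT proportions: any dose whose proportion falls below that of
#' the dose beneath it is raised to the running maximum, i.e. the result is
#' the cumulative maximum of the input. Monotone inputs are fixed points.
#'
#' @param observed Numeric vector of per-dose DLT proportions, low dose to
#'   high, each in \[0, 1\].
#' @return Numeric vector of the same length, non-decreasing.
#' @examples
#' monotonize_curve(c(0, 0.20, 0.20, 0.67, 0))
#' @export
monotonize_curve <- function(observed) {
  if (length(observed) == 0L) stop("'observed' must be a non-empty numeric vector")
  if (!is.numeric(observed) || anyNA(observed)) {
    stop("'observed' must be numeric with no missing values")
  }
  if (any(observed < 0) || any(observed > 1)) {
    stop("all values in 'observed' must lie in [0, 1]")
  }
  cummax(as.numeric(observed))
}

#' True maximum tolerated dose of a toxicity curve
#'
#' The true MTD is the highest dose whose true DLT probability is at or
#' below the maximum acceptable toxicity level (the comparison is
#' inclusive). When even the lowest dose exceeds the target there is no
#' tolerable dose and `NA` is returned.
#'
#' @param curve Non-decreasing numeric vector of true DLT probabilities.
#' @param target Maximum acceptable DLT probability, in (0, 1). Default 0.33.
#' @return Integer dose index, or `NA_integer_` when no dose is tolerable.
#' @examples
#' true_mtd(c(0, 0, 0.17, 0.50, 1.00), 0.33)  # dose 3
#' @export
true_mtd <- function(curve, target = 0.33) {
  stopifnot(is.numeric(curve), length(curve) >= 1L, target > 0, target < 1)
  if (is.unsorted(curve)) stop("'curve' must be non-decreasing; see monotonize_curve()")
  ok <- which(curve <= target)
  if (length(ok) == 0L) NA_integer_ else as.integer(max(ok))
}

#' Construct a dose-toxicity scenario
#'
#' A scenario bundles the dose levels of a trial with the true dose-toxicity
#' curve used as simulation ground truth, the target toxicity level, and the
#' implied true MTD.
#'
#' @param name Scenario name.
#' @param probs True per-dose DLT probabilities, low dose to high (K >= 2).
#' @param dose_labels Optional character vector of dose labels (e.g.
#'   `"1000 mg QD"`); defaults to `"dose 1"`, ..., `"dose K"`.
#' @param target Maximum acceptable DLT probability; default 0.33.
#' @param monotonize If `TRUE`, apply [monotonize_curve()] to `probs`;
#'   if `FALSE` (default) a non-monotone `probs` is an error.
#' @return An object of class `dose_scenario`: a list with elements `name`,
#'   `dose_labels`, `curve`, `target`, `true_mtd` (dose index or `NA`), and
#'   `n_doses`.
#' @examples
#' dose_scenario("AZD3514", c(0, 0, 0.17, 0.50, 1.00),
#'               dose_labels = c("250 mg QD", "500 mg QD", "1000 mg QD",
#'                               "1000 mg BID", "2000 mg BID"))
#' @export
dose_scenario <- function(name, probs, dose_labels = NULL, target = 0.33,
                          monotonize = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(probs) < 2L) stop("a scenario needs at least two dose levels")
  if (any(probs < 0) || any(probs > 1) || anyNA(probs)) {
    stop("'probs' must lie in [0, 1]")
  }
  if (monotonize) {
    probs <- monotonize_curve(probs)
  } else if (is.unsorted(probs)) {
    stop("'probs' is not non-decreasing; pass monotonize = TRUE to apply the ",
         "monotonization rule, or fix the curve")
  }
  if (is.null(dose_labels)) dose_labels <- paste("dose", seq_along(probs))
  stopifnot(length(dose_labels) == length(probs))
  structure(
    list(name = name,
         dose_labels = as.character(dose_labels),
         curve = as.numeric(probs),
         target = target,
         true_mtd = true_mtd(probs, target),
         n_doses = length(probs)),
    class = "dose_scenario")
}

#' @export
print.dose_scenario <- function(x, ...) {
  cat("<dose_scenario>", x$name, "\n")
  mtd <- if (is.na(x$true_mtd)) "none (lowest dose too toxic)" else
    sprintf("dose %d (%s)", x$true_mtd, x$dose_labels[x$true_mtd])
  cat(sprintf("  target DLT probability: %.2f; true MTD: %s\n", x$target, mtd))
  print(data.frame(dose = seq_len(x$n_doses), label = x$dose_labels,
                   p_dlt = x$curve))
  invisible(x)
}

#' Built-in clinical dose-toxicity scenarios
#'
#' The four true curves derived from phase 1 oncology trials of AZD3514,
#' AZD1208, AZD1480 and AZD4877. Probabilities are the published rounded
#' observed DLT proportions (e.g. 0.17, not 1/6), monotonized where the
#' observed proportions decreased with dose (AZD1480 top dose).
#'
#' @param target Maximum acceptable DLT probability; default 0.33.
#' @return Named list of [dose_scenario] objects.
#' @export
clinical_scenarios <- function(target = 0.33) {
  list(
    AZD3514 = dose_scenario(
      "AZD3514", c(0, 0, 0.17, 0.50, 1.00), target = target,
      dose_labels = c("250 mg QD", "500 mg QD", "1000 mg QD",
                      "1000 mg BID", "2000 mg BID")),
    AZD1208 = dose_scenario(
      "AZD1208", c(0, 0, 0, 0.25, 0.67), target = target,
      dose_labels = c("120 mg QD", "240 mg QD", "480 mg QD",
                      "700 mg QD", "900 mg QD")),
    AZD1480 = dose_scenario(
      "AZD1480", c(0, 0.20, 0.20, 0.67, 0), target = target, monotonize = TRUE,
      dose_labels = c("15 mg BID", "20 mg BID", "30 mg BID",
                      "35 mg BID", "45 mg BID")),
    AZD4877 = dose_scenario(
      "AZD4877", c(0, 0, 0, 0, 1.00), target = target,
      dose_labels = c("2 mg twice weekly", "4 mg twice weekly",
                      "7 mg twice weekly", "11 mg twice weekly",
                      "15 mg twice weekly")))
}

#' Built-in theoretical dose-toxicity scenarios
#'
#' Four shaped true curves (conservative, step-up, dose-linear, sigmoidal)
#' spanning a range of dose-toxicity relationships, sharing the shape
#' vocabulary of the skeletons in [default_skeletons()]. The exact
#' published values are not available, so these are synthetic
#' reconstructions, calibrated so that the exact 3+3 operating
#' characteristics (which depend only on the true curve) land near the
#' published ones, and should be treated as defaults overridable through
#' [load_scenarios()]. The sigmoidal curve places the dose immediately
#' above its MTD at a DLT probability of 0.35, just above the 0.33
#' target, which makes it the hardest curve for any design.
#'
#' @inheritParams clinical_scenarios
#' @return Named list of [dose_scenario] objects.
#' @export
theoretical_scenarios <- function(target = 0.33) {
  list(
    conservative = dose_scenario("conservative",
                                 c(0.25, 0.35, 0.45, 0.55, 0.65), target = target),
    `step-up`    = dose_scenario("step-up",
                                 c(0.15, 0.17, 0.20, 0.22, 0.60), target = target),
    `dose-linear` = dose_scenario("dose-linear",
                                  c(0.05, 0.09, 0.13, 0.17, 0.21), target = target),
    sigmoidal    = dose_scenario("sigmoidal",
                                 c(0.08, 0.15, 0.35, 0.70, 0.90), target = target))
}

#' All built-in scenarios
#' @inheritParams clinical_scenarios
#' @return Named list of [dose_scenario] objects, clinical then theoretical.
#' @export
builtin_scenarios <- function(target = 0.33) {
  c(clinical_scenarios(target), theoretical_scenarios(target))
}

#' Load scenarios from a configuration document
#'
#' Reads a YAML or JSON scenario configuration, or an equivalent R list.
#' The document has a top-level `scenarios` list; each entry has `name`,
#' optionally `target` (default 0.33) and `monotonize` (default `FALSE`),
#' and `doses`, a list of `{label, prob}` pairs (or a bare `probs` vector).
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or a list already
#'   parsed into that shape.
#' @return Named list of [dose_scenario] objects.
#' @export
load_scenarios <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config) || is.null(config$scenarios)) {
    stop("scenario config must contain a top-level 'scenarios' list")
  }
  out <- lapply(config$scenarios, function(sc) {
    if (is.null(sc$name)) stop("every scenario needs a 'name'")
    if (!is.null(sc$doses)) {
      probs <- vapply(sc$doses, function(d) as.numeric(d$prob), numeric(1))
      labels <- vapply(sc$doses, function(d) {
        if (is.null(d$label)) NA_character_ else as.character(d$label)
      }, character(1))
      if (anyNA(labels)) labels <- NULL
    } else if (!is.null(sc$probs)) {
      probs <- as.numeric(unlist(sc$probs))
      labels <- NULL
    } else {
      stop("scenario '", sc$name, "' needs 'doses' or 'probs'")
    }
    dose_scenario(sc$name, probs, dose_labels = labels,
                  target = if (is.null(sc$target)) 0.33 else as.numeric(sc$target),
                  monotonize = isTRUE(sc$monotonize))
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  if (anyDuplicated(names(out))) stop("duplicate scenario names in config")
  out
}

# Resolve a scenario given by name or object; used across the package.
as_scenario <- function(scenario, target = 0.33) {
  if (inherits(scenario, "dose_scenario")) return(scenario)
  if (is.character(scenario) && length(scenario) == 1L) {
    all <- builtin_scenarios(target)
    if (!scenario %in% names(all)) {
      stop("unknown built-in scenario '", scenario, "'; available: ",
           paste(names(all), collapse = ", "))
    }
    return(all[[scenario]])
  }
  stop("'scenario' must be a dose_scenario or the name of a built-in scenario")
}
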