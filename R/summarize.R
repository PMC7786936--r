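#' Classify a trial's selected MTD against the truth
#'
#' Each trial outcome falls in exactly one category: `correct` (selected
#' equals the true MTD), `underestimated`, `overestimated`, or
#' `not_determined` (the design stopped without an MTD — the 3+3 saw two
#' or more DLTs at the lowest dose, or the CRM stopped for safety; the
#' published tables label this "< lowest dose").
#'
#' @param selected Integer vector of selected dose indices (`NA` = not
#'   determined).
#' @param true_mtd True MTD dose index (scalar or vector).
#' @return Factor with levels `correct`, `underestimated`,
#'   `overestimated`, `not_determined`.
#' @export
classify_result <- function(selected, true_mtd) {
  stopifnot(!anyNA(true_mtd))
  out <- ifelse(is.na(selected), "not_determined",
                ifelse(selected == true_mtd, "correct",
                       ifelse(selected < true_mtd, "underestimated",
                              "overestimated")))
  factor(out, levels = c("correct", "underestimated", "overestimated",
                         "not_determined"))
}

#' Summarise a replicate batch into classification percentages
#'
#' @param batch A `replicate_batch` from [run_replicates()].
#' @return One-row data.frame: `scenario`, `design`, `skeleton`, `reps`,
#'   percentages `pct_correct`, `pct_under`, `pct_over`, `pct_not_determined`
#'   (summing to 100), `pct_determined`, the Monte-Carlo standard error of
#'   the correct-selection percentage (`se_correct`,
#'   \eqn{100\sqrt{p(1-p)/reps}}), and `mean_n`.
#' @export
summarize_scenario <- function(batch) {
  stopifnot(nrow(batch) >= 1L)
  cls <- classify_result(batch$selected, batch$true_mtd)
  reps <- nrow(batch)
  pct <- 100 * as.numeric(table(cls)) / reps
  p <- pct[1] / 100
  data.frame(scenario = batch$scenario[1],
             design = batch$design[1],
             skeleton = batch$skeleton[1],
             reps = reps,
             pct_correct = pct[1],
             pct_under = pct[2],
             pct_over = pct[3],
             pct_not_determined = pct[4],
             pct_determined = 100 - pct[4],
             se_correct = 100 * sqrt(p * (1 - p) / reps),
             mean_n = mean(batch$n_total))
}

#' Aggregate summaries across scenarios
#'
#' Unweighted mean of each classification percentage across scenarios (all
#' scenarios use equal replicate counts), as in the published
#' across-curve summary table.
#'
#' @param summaries data.frame of rows from [summarize_scenario()], all
#'   with the same design and skeleton.
#' @return One-row data.frame of mean percentages.
#' @export
aggregate_across_scenarios <- function(summaries) {
  stopifnot(nrow(summaries) >= 1L)
  if (length(unique(summaries$design)) != 1L ||
      length(unique(ifelse(is.na(summaries$skeleton), "", summaries$skeleton))) != 1L) {
    stop("summaries mix designs or skeletons; aggregate one method at a time")
  }
  data.frame(scenario = paste0("mean of ", nrow(summaries), " curves"),
             design = summaries$design[1],
             skeleton = summaries$skeleton[1],
             reps = sum(summaries$reps),
             pct_correct = mean(summaries$pct_correct),
             pct_under = mean(summaries$pct_under),
             pct_over = mean(summaries$pct_over),
             pct_not_determined = mean(summaries$pct_not_determined),
             pct_determined = mean(summaries$pct_determined),
             se_correct = NA_real_,
             mean_n = mean(summaries$mean_n))
}

#' Render a sweep as a selection-accuracy grid
#'
#' Reshapes a [sweep_designs()] result into the familiar wide layout:
#' one row per method (3+3 and each CRM skeleton), one column per
#' scenario, entries the percent of replicates selecting the true MTD.
#'
#' @param sweep data.frame from [sweep_designs()].
#' @return data.frame with a `method` column and one column per scenario.
#' @export
accuracy_grid <- function(sweep) {
  method <- ifelse(sweep$design == "3p3", "3+3",
                   paste0("CRM ", sweep$skeleton))
  wide <- stats::reshape(
    data.frame(method = method, scenario = sweep$scenario,
               pct = round(sweep$pct_correct, 1)),
    idvar = "method", timevar = "scenario", direction = "wide")
  names(wide) <- sub("^pct\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
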