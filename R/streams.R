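#' Reproducible Bernoulli DLT outcome stream
#'
#' An outcome stream supplies per-patient binary DLT outcomes drawn from a
#' true dose-toxicity curve. Each stream carries its own RNG state (saved
#' and restored around every draw, so streams never disturb the global
#' RNG): the same seed and the same sequence of requested doses always
#' reproduce the same outcomes. All doses share one underlying uniform
#' stream — patient j's uniform is compared against the probability of
#' whichever dose patient j receives — which lets competing designs be run
#' against common random numbers.
#'
#' Every draw is recorded, so a completed trial can be replayed exactly via
#' [replay_stream()].
#'
#' @param curve Numeric vector of true per-dose DLT probabilities, or a
#'   [dose_scenario].
#' @param seed Integer seed for the stream's private RNG.
#' @return Object of class `outcome_stream`.
#' @export
outcome_stream <- function(curve, seed) {
  if (inherits(curve, "dose_scenario")) curve <- curve$curve
  stopifnot(is.numeric(curve), length(curve) >= 1L,
            all(curve >= 0), all(curve <= 1))
  env <- new.env(parent = emptyenv())
  env$curve <- curve
  env$doses <- integer(0)
  env$outcomes <- integer(0)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  env$rng <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, globalenv())
  structure(list(env = env, seed = as.integer(seed)), class = "outcome_stream")
}

#' Draw one patient outcome from a stream
#'
#' @param stream An [outcome_stream()] or [replay_stream()].
#' @param dose Dose index (1-based) the patient receives.
#' @return Integer 0 (no DLT) or 1 (DLT).
#' @export
draw_outcome <- function(stream, dose) {
  env <- stream$env
  dose <- as.integer(dose)
  if (dose < 1L || dose > length(env$curve)) {
    stop("dose index ", dose, " out of range 1..", length(env$curve))
  }
  if (!is.null(env$replay)) {
    i <- length(env$doses) + 1L
    if (i > length(env$replay)) stop("replay stream exhausted at draw ", i)
    out <- env$replay[i]
  } else {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    assign(".Random.seed", env$rng, globalenv())
    u <- stats::runif(1)
    env$rng <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    out <- as.integer(u < env$curve[dose])
  }
  env$doses <- c(env$doses, dose)
  env$outcomes <- c(env$outcomes, out)
  out
}

#' Recorded draws of a stream
#' @param stream An outcome stream.
#' @return data.frame with columns `dose` and `dlt`, one row per draw.
#' @export
recorded_outcomes <- function(stream) {
  data.frame(dose = stream$env$doses, dlt = stream$env$outcomes)
}

#' Replay stream from recorded outcomes
#'
#' Feeds back a fixed outcome sequence (e.g. from [recorded_outcomes()]),
#' ignoring probabilities: draw i returns the i-th recorded outcome. Used
#' to verify that trial results are a pure function of the outcome stream.
#'
#' @param curve True curve (only its length is used for dose validation),
#'   or a [dose_scenario].
#' @param outcomes Integer vector of 0/1 outcomes in draw order.
#' @return Object of class `outcome_stream`.
#' @export
replay_stream <- function(curve, outcomes) {
  if (inherits(curve, "dose_scenario")) curve <- curve$curve
  stopifnot(all(outcomes %in% c(0L, 1L)))
  env <- new.env(parent = emptyenv())
  env$curve <- curve
  env$doses <- integer(0)
  env$outcomes <- integer(0)
  env$replay <- as.integer(outcomes)
  structure(list(env = env, seed = NA_integer_), class = "outcome_stream")
}

#' @export
print.outcome_stream <- function(x, ...) {
  kind <- if (is.null(x$env$replay)) sprintf("seeded (%d)", x$seed) else "replay"
  cat("<outcome_stream>", kind, "|", length(x$env$doses), "draws so far\n")
  invisible(x)
}
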