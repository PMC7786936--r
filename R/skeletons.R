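#' Default CRM skeleton vectors
#'
#' The six named prior skeletons compared by the package, for five dose
#' levels. The names describe the dose-escalation behaviour each prior
#' induces in the CRM: `conservative` assumes toxicity is already near
#' the acceptable limit at the lowest dose (high prior DLT probabilities,
#' so the model escalates cautiously and rarely overshoots the MTD);
#' `aggressive` assumes the drug is well tolerated throughout (low prior
#' probabilities, eager escalation); `dose-linear` rises by equal small
#' increments; `step-up` is a low plateau followed by a jump; `sigmoidal`
#' is S-shaped with the steep rise just above the target; `oquigley` is
#' the conventional (0.05, 0.10, 0.20, 0.30, 0.50) skeleton of the early
#' CRM literature. The exact published vectors are not available, so
#' these are documented reconstructions calibrated to the behaviour each
#' named skeleton is reported to produce; every one can be overridden via
#' [get_skeleton()]'s `values` argument or a config file.
#'
#' @return Named list of numeric prior DLT-probability vectors (length 5).
#' @export
default_skeletons <- function() {
  list(
    conservative  = c(0.25, 0.40, 0.55, 0.70, 0.85),
    aggressive    = c(0.01, 0.04, 0.09, 0.16, 0.25),
    `step-up`     = c(0.02, 0.06, 0.13, 0.45, 0.65),
    `dose-linear` = c(0.05, 0.12, 0.19, 0.26, 0.33),
    sigmoidal     = c(0.08, 0.15, 0.35, 0.70, 0.90),
    oquigley      = c(0.05, 0.10, 0.20, 0.30, 0.50))
}

#' Validate a CRM skeleton vector
#'
#' The CRM's one-parameter model requires prior DLT probabilities that are
#' strictly increasing in dose (the monotone dose-toxicity assumption) and
#' strictly inside (0, 1) so every logit is finite. Values within 0.001 of
#' the boundary are rejected rather than clamped: a silently clamped
#' skeleton would change the design's operating characteristics.
#'
#' @param p0 Numeric vector of prior DLT probabilities.
#' @return A list with `ok` (logical) and `problems` (character vector,
#'   empty when `ok`).
#' @export
validate_skeleton <- function(p0) {
  problems <- character()
  if (!is.numeric(p0) || length(p0) < 2L || anyNA(p0)) {
    problems <- c(problems, "skeleton must be a numeric vector of length >= 2 with no NAs")
    return(list(ok = FALSE, problems = problems))
  }
  if (any(p0 <= 0.001) || any(p0 >= 0.999)) {
    problems <- c(problems,
                  "skeleton values must lie strictly inside [0.001, 0.999] (logit must be finite)")
  }
  if (any(diff(p0) <= 0)) {
    problems <- c(problems, "skeleton must be strictly increasing in dose")
  }
  list(ok = length(problems) == 0L, problems = problems)
}

#' Retrieve a named CRM skeleton
#'
#' @param name One of `"conservative"`, `"aggressive"`, `"step-up"`,
#'   `"dose-linear"`, `"sigmoidal"`, `"oquigley"`, or `"custom"` (which
#'   requires `values`).
#' @param K Number of dose levels the skeleton must cover (default 5).
#' @param values Optional numeric vector overriding the default for `name`.
#' @return An object of class `crm_skeleton`: list with `name` and `p0`.
#' @examples
#' get_skeleton("oquigley")
#' get_skeleton("custom", values = c(0.02, 0.06, 0.12, 0.25, 0.40))
#' @export
get_skeleton <- function(name, K = 5L, values = NULL) {
  name <- match.arg(name, c(names(default_skeletons()), "custom"))
  if (is.null(values)) {
    if (name == "custom") stop("skeleton 'custom' requires a 'values' vector")
    values <- default_skeletons()[[name]]
  }
  if (length(values) != K) {
    stop("skeleton '", name, "' has ", length(values),
         " values but the scenario has ", K, " dose levels")
  }
  v <- validate_skeleton(values)
  if (!v$ok) stop("invalid skeleton '", name, "': ",
                  paste(v$problems, collapse = "; "))
  structure(list(name = name, p0 = as.numeric(values)), class = "crm_skeleton")
}

#' @export
print.crm_skeleton <- function(x, ...) {
  cat("<crm_skeleton>", x$name, ":", paste(format(x$p0), collapse = ", "), "\n")
  invisible(x)
}

as_skeleton <- function(skeleton, K = 5L) {
  if (inherits(skeleton, "crm_skeleton")) {
    if (length(skeleton$p0) != K) stop("skeleton length does not match dose count")
    return(skeleton)
  }
  if (is.character(skeleton) && length(skeleton) == 1L) return(get_skeleton(skeleton, K))
  if (is.numeric(skeleton)) return(get_skeleton("custom", K, values = skeleton))
  stop("'skeleton' must be a crm_skeleton, a skeleton name, or a numeric vector")
}
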