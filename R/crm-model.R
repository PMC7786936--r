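#' One-parameter logistic dose-toxicity function
#'
#' The working model of the CRM:
#' \deqn{\psi(x, \beta) = \frac{1}{1 + \exp(-(a_0 + e^{\beta} x))}}
#' with a fixed intercept `a0` and the slope parameterised through its
#' natural logarithm `beta`, so the slope \eqn{e^\beta} is always positive
#' and the model is monotone in the dose label `x` for every `beta`.
#'
#' @param x Real dose label(s).
#' @param beta Log-slope parameter.
#' @param a0 Fixed intercept; default 3.
#' @return DLT probability in (0, 1), same shape as `x`.
#' @export
psi_logistic <- function(x, beta, a0 = 3) {
  stats::plogis(a0 + exp(beta) * x)
}

#' Backsolve dose labels from a skeleton
#'
#' Chooses the real-valued dose labels so that the working model at the
#' prior-central slope (`beta = 0`, slope 1) reproduces the skeleton
#' exactly: `x_i = logit(p0_i) - a0`, hence
#' `psi_logistic(x_i, 0, a0) == p0_i`.
#'
#' @param p0 Skeleton probabilities, strictly inside (0, 1).
#' @param a0 Fixed intercept; default 3.
#' @return Numeric vector of dose labels, strictly increasing.
#' @export
backsolve_labels <- function(p0, a0 = 3) {
  if (any(p0 <= 0) || any(p0 >= 1)) stop("skeleton values must be strictly inside (0, 1)")
  stats::qlogis(p0) - a0
}

#' Construct a CRM working model
#'
#' Precomputes everything the per-patient posterior updates need: the
#' backsolved dose labels, the quadrature grid for the log-slope `beta`
#' (Gauss-Legendre nodes spanning `span_sd` prior standard deviations
#' on either side of the prior mean, weighted by the Gaussian prior
#' density), and the working-model probabilities at every node. A second
#' grid at double resolution is kept so every posterior update can verify
#' its own integration error.
#'
#' @param skeleton A `crm_skeleton`, skeleton name, or numeric vector.
#' @param a0 Fixed model intercept; default 3.
#' @param prior_mean,prior_var Gaussian prior on `beta` (the log of the
#'   logistic slope); defaults 0 and 1.34.
#' @param target Maximum acceptable DLT probability; default 0.33.
#' @param nodes Number of quadrature nodes; default 321.
#' @param span_sd Half-width of the integration interval in prior standard
#'   deviations; default 8.
#' @param estimate Either `"posterior_mean_p"` (default: the posterior mean
#'   of `psi`, the "mean predicted posterior probability" of a DLT) or
#'   `"plugin"` (`psi` evaluated at the posterior mean of `beta`).
#' @param tol Maximum tolerated discrepancy between the base and
#'   double-resolution grids in any posterior-mean probability; default 1e-8.
#' @return Object of class `crm_model`.
#' @export
crm_model <- function(skeleton, a0 = 3, prior_mean = 0, prior_var = 1.34,
                      target = 0.33, nodes = 321L, span_sd = 8,
                      estimate = c("posterior_mean_p", "plugin"), tol = 1e-8) {
  skeleton <- as_skeleton(skeleton, K = if (inherits(skeleton, "crm_skeleton"))
    length(skeleton$p0) else if (is.numeric(skeleton)) length(skeleton) else 5L)
  estimate <- match.arg(estimate)
  stopifnot(prior_var > 0, nodes >= 21L, span_sd > 0)
  x <- backsolve_labels(skeleton$p0, a0)

  sd <- sqrt(prior_var)
  make_grid <- function(n) {
    gl <- pracma::gaussLegendre(n, prior_mean - span_sd * sd, prior_mean + span_sd * sd)
    beta <- gl$x
    lpsi <- outer(x, beta, function(xx, bb) stats::plogis(a0 + exp(bb) * xx, log.p = TRUE))
    l1m  <- outer(x, beta, function(xx, bb) stats::plogis(a0 + exp(bb) * xx,
                                                          log.p = TRUE, lower.tail = FALSE))
    list(beta = beta,
         log_wprior = log(gl$w) + stats::dnorm(beta, prior_mean, sd, log = TRUE),
         psi = exp(lpsi), log_psi = lpsi, log_1m_psi = l1m)
  }
  structure(
    list(skeleton = skeleton, a0 = a0, x = x,
         prior_mean = prior_mean, prior_var = prior_var, target = target,
         nodes = as.integer(nodes), span_sd = span_sd,
         estimate = estimate, tol = tol,
         grid = make_grid(as.integer(nodes)),
         grid_fine = make_grid(2L * as.integer(nodes) + 1L)),
    class = "crm_model")
}

#' @export
print.crm_model <- function(x, ...) {
  cat("<crm_model> skeleton:", x$skeleton$name,
      sprintf("| a0 = %g, beta ~ N(%g, %g), target = %g\n",
              x$a0, x$prior_mean, x$prior_var, x$target))
  cat("  skeleton p0:", paste(format(x$skeleton$p0), collapse = ", "), "\n")
  invisible(x)
}

# Coerce toxicity data to per-dose sufficient statistics (n, t).
as_dose_counts <- function(data, K) {
  if (is.null(data)) return(list(n = numeric(K), t = numeric(K)))
  if (is.list(data) && !is.data.frame(data) && all(c("n", "t") %in% names(data))) {
    stopifnot(length(data$n) == K, length(data$t) == K)
    if (any(data$t > data$n) || any(data$n < 0)) stop("invalid counts: need 0 <= t <= n")
    return(list(n = as.numeric(data$n), t = as.numeric(data$t)))
  }
  if (is.data.frame(data)) {
    stopifnot(all(c("dose", "dlt") %in% names(data)))
    if (nrow(data) && (any(data$dose < 1) || any(data$dose > K))) {
      stop("dose indices must lie in 1..K")
    }
    n <- tabulate(data$dose, nbins = K)
    t <- tabulate(data$dose[data$dlt == 1], nbins = K)
    return(list(n = as.numeric(n), t = as.numeric(t)))
  }
  stop("'data' must be a data.frame with columns dose/dlt or a list(n =, t =)")
}

post_on_grid <- function(model, grid, n, t) {
  # log-likelihood at each node from per-dose sufficient statistics
  ll <- drop(t %*% grid$log_psi + (n - t) %*% grid$log_1m_psi)
  lw <- grid$log_wprior + ll
  m <- max(lw)
  w <- exp(lw - m)
  Z <- sum(w)
  list(p_hat = drop(grid$psi %*% w) / Z,
       beta_mean = sum(grid$beta * w) / Z,
       log_Z = m + log(Z))
}

#' Posterior update of the CRM model
#'
#' Computes the posterior-mean DLT probability at every dose given the
#' toxicity data observed so far, by 1-D numerical integration of the
#' working model against the posterior of the log-slope `beta`:
#' \deqn{\hat p_i = \frac{\int \psi(x_i,\beta)\, L(\mathrm{data}\mid\beta)\,
#'   \varphi(\beta; \mu, \sigma^2)\, d\beta}{\int L(\mathrm{data}\mid\beta)\,
#'   \varphi(\beta; \mu, \sigma^2)\, d\beta}}
#' with `L` the Bernoulli likelihood. Every update is recomputed on a
#' double-resolution grid; if any `p_hat` differs by more than the model's
#' tolerance the update aborts rather than silently degrade.
#'
#' @param model A [crm_model()].
#' @param data Toxicity data: a data.frame with columns `dose` (index) and
#'   `dlt` (0/1), a `list(n =, t =)` of per-dose patient and DLT counts, or
#'   `NULL` for the prior.
#' @return Object of class `crm_posterior`: list with `p_hat` (per-dose
#'   posterior-mean DLT probabilities), `beta_mean`, `log_Z` (log normalizing
#'   constant), `integration_error` (max abs difference between grids), and
#'   the counts used.
#' @export
posterior_update <- function(model, data = NULL) {
  stopifnot(inherits(model, "crm_model"))
  K <- length(model$x)
  cnt <- as_dose_counts(data, K)
  base <- post_on_grid(model, model$grid, cnt$n, cnt$t)
  fine <- post_on_grid(model, model$grid_fine, cnt$n, cnt$t)
  err <- max(abs(base$p_hat - fine$p_hat))
  if (!is.finite(err) || err > model$tol) {
    stop(sprintf("posterior quadrature failed to converge: error %.3e exceeds tolerance %.3e",
                 err, model$tol))
  }
  p_hat <- if (model$estimate == "plugin") {
    psi_logistic(model$x, fine$beta_mean, model$a0)
  } else {
    fine$p_hat
  }
  structure(
    list(p_hat = p_hat, beta_mean = fine$beta_mean, log_Z = fine$log_Z,
         integration_error = err, n = cnt$n, t = cnt$t,
         target = model$target, estimate = model$estimate),
    class = "crm_posterior")
}

#' @export
print.crm_posterior <- function(x, ...) {
  cat("<crm_posterior> estimate:", x$estimate, "\n")
  print(data.frame(dose = seq_along(x$p_hat), n = x$n, dlt = x$t,
                   p_hat = round(x$p_hat, 4)))
  invisible(x)
}

#' Recommend the next dose from a CRM posterior
#'
#' The unconstrained recommendation is the highest dose whose estimated DLT
#' probability is at or below the target ("closest to but below" the
#' maximum acceptable toxicity, with equality included). Dose skipping is
#' prohibited: the returned dose never exceeds the last administered dose
#' plus one. If even the lowest dose exceeds the target the trial must stop
#' for safety and `NA` is returned.
#'
#' @param posterior A `crm_posterior` (or bare numeric `p_hat` vector).
#' @param target Maximum acceptable DLT probability.
#' @param current_dose Last administered dose index (the no-skip anchor).
#' @return Integer dose index, or `NA_integer_` for a safety stop.
#' @export
recommend_dose <- function(posterior, target = 0.33, current_dose = 1L) {
  p_hat <- if (inherits(posterior, "crm_posterior")) posterior$p_hat else posterior
  ok <- which(p_hat <= target)
  if (length(ok) == 0L) return(NA_integer_)
  as.integer(min(max(ok), current_dose + 1L))
}

#' Final MTD selection from a CRM posterior
#'
#' The selected MTD is the dose with the largest estimated DLT probability
#' at or below the target. Unlike [recommend_dose()] no dose-skipping cap
#' applies: this is a terminal estimate, not an assignment.
#'
#' @inheritParams recommend_dose
#' @return Integer dose index, or `NA_integer_` when every dose exceeds the
#'   target.
#' @export
select_final_mtd <- function(posterior, target = 0.33) {
  p_hat <- if (inherits(posterior, "crm_posterior")) posterior$p_hat else posterior
  ok <- which(p_hat <= target)
  if (length(ok) == 0L) NA_integer_ else as.integer(max(ok))
}
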