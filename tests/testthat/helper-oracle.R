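# Independent brute-force oracle for the CRM posterior: dense trapezoid
# integration of the one-parameter logistic model over beta in [-10, 10].
# Deliberately re-derives psi and the Bernoulli likelihood from scratch so
# it shares no code with the package's quadrature path.
trapezoid_posterior <- function(p0, n, t, a0 = 3, prior_mean = 0,
                                prior_var = 1.34, npts = 200001L) {
  x <- log(p0 / (1 - p0)) - a0
  beta <- seq(-10, 10, length.out = npts)
  h <- beta[2] - beta[1]
  loglik <- numeric(npts)
  for (i in seq_along(x)) {
    eta <- a0 + exp(beta) * x[i]
    # numerically stable log(psi) and log(1 - psi)
    lp <- ifelse(eta > 0, -log1p(exp(-eta)), eta - log1p(exp(eta)))
    lq <- lp - eta
    loglik <- loglik + t[i] * lp + (n[i] - t[i]) * lq
  }
  w <- exp(loglik - max(loglik)) * dnorm(beta, prior_mean, sqrt(prior_var))
  w[c(1, npts)] <- w[c(1, npts)] / 2   # trapezoid ends
  Z <- sum(w) * h
  vapply(x, function(xx) sum(1 / (1 + exp(-(a0 + exp(beta) * xx))) * w) * h / Z,
         numeric(1))
}

# Per-dose (n, t) counts actually administered along a trial trace.
trace_counts <- function(trace, K) {
  list(n = tabulate(trace$dose, nbins = K),
       t = tabulate(trace$dose[trace$dlt == 1], nbins = K))
}
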