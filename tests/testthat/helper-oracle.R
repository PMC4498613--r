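# Independent numerical oracles for the mixture fits.

# Direct mixture log-likelihood: one shared genotype per individual across
# environments, so component densities are products over environments.
mixture_loglik <- function(dy, pi1, mu1, mu2, sigma2) {
  n <- nrow(dy)
  ll <- 0
  for (i in seq_len(n)) {
    lf1 <- sum(stats::dnorm(dy[i, ], mu1, sqrt(sigma2), log = TRUE),
               na.rm = TRUE)
    lf2 <- sum(stats::dnorm(dy[i, ], mu2, sqrt(sigma2), log = TRUE),
               na.rm = TRUE)
    m <- max(log(pi1[i]) + lf1, log(1 - pi1[i]) + lf2)
    ll <- ll + m + log(exp(log(pi1[i]) + lf1 - m) +
                         exp(log(1 - pi1[i]) + lf2 - m))
  }
  ll
}

# Generic unconstrained maximization of the mixture likelihood over
# (mu1, mu2, log sigma2); returns the best log-likelihood found across the
# supplied starting points.
oracle_max_h1 <- function(dy, pi1, starts) {
  e <- ncol(dy)
  obj <- function(par) {
    -mixture_loglik(dy, pi1, par[1:e], par[e + 1:e], exp(par[2 * e + 1:e]))
  }
  best <- -Inf
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    best <- max(best, -fit$value)
  }
  best
}

# Equality-constrained maximization: mean_h(mu1h - mu2h) = 0 imposed by
# parameterizing the differences d_1..d_{e-1} with d_e = -sum(d_-e).
oracle_max_h2 <- function(dy, pi1, starts) {
  e <- ncol(dy)
  obj <- function(par) {
    mu2 <- par[1:e]
    d <- if (e > 1) c(par[e + seq_len(e - 1)], -sum(par[e + seq_len(e - 1)]))
    else 0
    -mixture_loglik(dy, pi1, mu2 + d, mu2, exp(par[2 * e - 1 + 1:e]))
  }
  best <- -Inf
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    best <- max(best, -fit$value)
  }
  best
}

# random toy dataset with a planted QTL in a single interval
toy_instance <- function(seed, n = 20, e = 2, a = NULL) {
  set.seed(seed)
  if (is.null(a)) a <- stats::runif(e, -1, 1)
  g <- sample(c(1, -1), n, replace = TRUE)
  r <- 0.06
  xl <- ifelse(stats::runif(n) < r, -g, g)
  xr <- ifelse(stats::runif(n) < r, -g, g)
  dy <- outer(g, a) + matrix(stats::rnorm(n * e, sd = 0.8), n, e)
  d <- inverse_haldane(r)      # distance with one-side fraction r
  ip <- interval_probabilities(d, d, "DH")
  grp <- ifelse(xl > 0, ifelse(xr > 0, 1L, 2L), ifelse(xr > 0, 3L, 4L))
  list(dy = dy, pi1 = ip$pi[grp, 1], g = g)
}
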