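# Independent brute-force oracle for the cumulative log viral-load metric:
# for every visit, sum trapezoids over all consecutive pairs of observed
# nodes at or before that visit's time. Deliberately written without the
# cumulative/bridging machinery of the implementation.
oracle_cvl2 <- function(t, vl, dl = 400) {
  le <- ifelse(is.na(vl), NA, pmax(0, log10(vl / dl)))
  obs <- which(!is.na(le))
  vapply(seq_along(t), function(j) {
    nodes <- obs[t[obs] <= t[j]]
    if (length(nodes) < 2) return(0)
    s <- 0
    for (k in 2:length(nodes))
      s <- s + (t[nodes[k]] - t[nodes[k - 1]]) *
        (le[nodes[k]] + le[nodes[k - 1]]) / 2
    s
  }, numeric(1))
}

# closed-form multivariate normal-normal posterior for a fixed-effects
# Gaussian model with known error sd and independent N(m0, 1/p0) priors
conjugate_posterior <- function(X, y, sigma, prior_prec = 1e-6,
                                prior_mean = 0) {
  P0 <- diag(rep(prior_prec, ncol(X)))
  V <- solve(crossprod(X) / sigma^2 + P0)
  m <- V %*% (crossprod(X, y) / sigma^2 + P0 %*% rep(prior_mean, ncol(X)))
  list(mean = drop(m), V = V)
}

# analytic conditional DIC for the same conjugate model:
# Dbar = n log(2 pi s^2) + (RSS(m) + tr(X'X V)) / s^2, pD = tr(X'X V) / s^2
conjugate_cdic <- function(X, y, sigma, prior_prec = 1e-6) {
  post <- conjugate_posterior(X, y, sigma, prior_prec)
  rss <- sum((y - X %*% post$mean)^2)
  trterm <- sum(diag(crossprod(X) %*% post$V))
  n <- length(y)
  Dhat <- n * log(2 * pi * sigma^2) + rss / sigma^2
  pD <- trterm / sigma^2
  list(cdic = Dhat + 2 * pD, pD = pD, Dbar = Dhat + pD)
}
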