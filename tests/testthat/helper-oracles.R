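# Independent oracles used to cross-check the implementation.

# Closed-form posterior mean of a Bayesian linear regression with fixed
# variances and no selection: the ridge solution (X'X + lambda I)^-1 X'y.
ridge_oracle <- function(X, y, lambda) {
  M <- ncol(X)
  drop(solve(crossprod(X) + diag(lambda, M), crossprod(X, y)))
}

# Brute-force restricted-likelihood grid search for the two-component
# animal model y ~ N(Xb, sigma2_p (h2 G + (1 - h2) I)) on the eigenbasis
# of G.  Returns the h2 maximizing the restricted log-likelihood.
profile_h2_oracle <- function(y, X, G, grid = seq(0.001, 0.999, by = 0.002)) {
  eg <- eigen(G, symmetric = TRUE)
  U <- eg$vectors
  d <- pmax(eg$values, 0)
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  n <- length(y); p <- ncol(X)
  ll <- vapply(grid, function(h2) {
    w <- h2 * d + (1 - h2)
    if (any(w <= 0)) return(-Inf)
    XtWX <- crossprod(Xt, Xt / w)
    b <- solve(XtWX, crossprod(Xt, yt / w))
    r <- yt - drop(Xt %*% b)
    rss <- sum(r^2 / w)
    s2 <- rss / (n - p)
    -0.5 * (sum(log(w)) + determinant(XtWX, logarithm = TRUE)$modulus +
            (n - p) * log(s2) + (n - p))
  }, numeric(1))
  grid[which.max(ll)]
}

# small shared data set with one strong QTL, built once per test run
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_animals = 400L, n_snps = 300L, n_sires = 40L,
                        h2 = 0.5, n_large_qtl = 1L,
                        large_qtl_var_fraction = 0.3, n_poly_qtl = 60L,
                        missing_rate = 0.002, seed = 42L)
      dat <- simulate_study(cfg)
      qc <- run_qc(dat$genotypes, dat$map, seed = 7L)
      cache <<- list(cfg = cfg, dat = dat, qc = qc)
    }
    cache
  }
})
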