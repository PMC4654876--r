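make_reml_data <- function(seed = 1, n = 250, M = 400, h2 = 0.4) {
  cfg <- sim_config(n_animals = n, n_snps = M, n_sires = max(10, n %/% 10),
                    h2 = h2, n_large_qtl = 0, n_poly_qtl = min(M, 150),
                    cg_var_fraction = 0.1, missing_rate = 0, seed = seed)
  dat <- simulate_study(cfg)
  G <- grm_vanraden1(dat$genotypes)
  des <- adjustment_design(dat$traits)
  list(dat = dat, G = G, des = des)
}

test_that("two-component REML agrees with the eigenbasis grid-search oracle", {
  d <- make_reml_data(seed = 31)
  y <- d$dat$truth$true_breeding_values + d$dat$truth$residuals +
    d$dat$truth$cg_effects  # cg noise folded into the 2-component error
  Gr <- d$G$values + diag(1e-6, length(y))
  X <- matrix(1, length(y), 1)
  fit <- fit_reml(y, X, d$G$values, Zcg = NULL)
  h2_oracle <- profile_h2_oracle(y, X, Gr)
  expect_equal(fit$h2, h2_oracle, tolerance = 0.02)
})

test_that("heritability is invariant to affine rescaling of the trait", {
  d <- make_reml_data(seed = 5, n = 200, M = 300)
  y <- d$dat$traits$trait
  f1 <- fit_reml(y, d$des$X, d$G$values, d$des$Zcg)
  f2 <- fit_reml(3.7 * y - 12, d$des$X, d$G$values, d$des$Zcg)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-4)
  expect_equal(f2$sigma2_a, 3.7^2 * f1$sigma2_a, tolerance = 1e-3 * f1$sigma2_a)
})

test_that("null additive variance is recovered as a boundary solution", {
  cfg <- sim_config(n_animals = 250, n_snps = 300, n_sires = 25, h2 = 0,
                    cg_var_fraction = 0.1, missing_rate = 0, seed = 8)
  dat <- simulate_study(cfg)
  G <- grm_vanraden1(dat$genotypes)
  des <- adjustment_design(dat$traits)
  fit <- fit_reml(dat$traits$trait, des$X, G$values, des$Zcg)
  expect_lt(fit$h2, 0.1)
})

test_that("G = identity triggers an identifiability warning", {
  set.seed(2)
  y <- rnorm(100)
  expect_warning(fit_reml(y, matrix(1, 100, 1), diag(100), ridge = 0),
                 "identifiab")
})

test_that("restricted log-likelihood is non-decreasing and fits are deterministic", {
  d <- make_reml_data(seed = 17, n = 200, M = 300)
  f1 <- fit_reml(d$dat$traits$trait, d$des$X, d$G$values, d$des$Zcg)
  f2 <- fit_reml(d$dat$traits$trait, d$des$X, d$G$values, d$des$Zcg)
  expect_identical(f1$loglik_history, f2$loglik_history)
  expect_true(all(diff(f1$loglik_history) > -1e-8))
  expect_true(f1$converged)
  expect_gt(f1$se_h2, 0)
})

test_that("adjustment removes nuisance variance and centers phenotypes", {
  d <- make_reml_data(seed = 23, n = 300, M = 300, h2 = 0.5)
  y <- d$dat$traits$trait
  fit <- fit_reml(y, d$des$X, d$G$values, d$des$Zcg)
  ys <- adjust_phenotypes(y, d$des$X, d$des$Zcg, fit)
  expect_lt(abs(mean(ys)), 0.05)  # GLS intercept, so near- but not exactly 0
  target <- d$dat$truth$true_breeding_values + d$dat$truth$residuals
  expect_gt(cor(ys, target), cor(y, target))
  # with an intercept-only model, y* is centered y up to the GLS/OLS
  # intercept difference (a single small scalar shift)
  fit0 <- fit_reml(y, matrix(1, length(y), 1), d$G$values, Zcg = NULL)
  ys0 <- adjust_phenotypes(y, matrix(1, length(y), 1), NULL, fit0)
  expect_lt(max(abs(ys0 - (y - mean(y)))), 0.2)
  expect_gt(cor(ys0, y - mean(y)), 0.9999)
})
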