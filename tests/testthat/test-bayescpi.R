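test_that("prior scales reproduce the anchored formulas", {
  # S_a^2 = sigma_u^2 (v_a - 2) / [v_a (1 - pi) sum 2p(1-p)]
  freqs <- rep(0.5, 20)                       # sum 2p(1-p) = 10
  s <- prior_scales(1, 1, v_a = 4, v_e = 10, pi = 0.9, allele_freqs = freqs)
  expect_equal(s$S2_a, 0.5)                   # (1*2)/(4*0.1*10)
  expect_equal(s$S2_e, 0.8)                   # (10-2)/10
  expect_equal(prior_scales(0, 1, 4, 10, 0.9, freqs)$S2_a, 0)
  expect_error(prior_scales(1, 1, 4, 10, 1, freqs), "pi = 1")
  expect_error(prior_scales(1, 1, 2, 10, 0.9, freqs), "exceed 2")
})

test_that("pi fixed at 1 forces every SNP out of the model", {
  sh <- shared_sim()
  geno <- sh$qc$genotypes
  y <- rnorm(nrow(geno)); names(y) <- rownames(geno)
  post <- run_gibbs(y, geno, chain_config(300, 50, seed = 2), pi_fixed = 1)
  expect_true(all(post$ppi == 0))
  expect_true(all(post$effect_mean == 0))
  expect_true(all(gebv_from_effects(post$effect_mean, geno) == 0))
})

test_that("with pi = 0 and fixed variances the sampler matches the ridge oracle", {
  set.seed(99)
  n <- 50; M <- 5
  X <- matrix(rbinom(n * M, 2, 0.5), n, M)
  b <- c(0.8, -0.5, 0, 0.3, 0)
  y <- drop(X %*% b) + rnorm(n)
  y <- y - mean(y)
  s2a <- 0.2; s2e <- 1
  post <- run_gibbs(y, X, chain_config(6000, 1000, seed = 3),
                    pi_fixed = 0, fix_variances = TRUE,
                    sigma2_a_init = s2a, sigma2_e_init = s2e,
                    sample_mu = FALSE)
  oracle <- ridge_oracle(X, y, s2e / s2a)
  expect_equal(post$effect_mean, oracle, tolerance = 0.05)
  expect_gt(cor(post$effect_mean, oracle), 0.99)
})

test_that("chains are bit-reproducible given the seed and differ across seeds", {
  sh <- shared_sim()
  geno <- sh$qc$genotypes
  y <- sh$dat$truth$true_breeding_values + sh$dat$truth$residuals
  a <- run_gibbs(y, geno, chain_config(200, 50, seed = 7))
  b <- run_gibbs(y, geno, chain_config(200, 50, seed = 7))
  c <- run_gibbs(y, geno, chain_config(200, 50, seed = 8))
  expect_identical(a$effect_mean, b$effect_mean)
  expect_identical(a$sigma2_e_chain, b$sigma2_e_chain)
  expect_false(identical(a$effect_mean, c$effect_mean))
})

test_that("a pure-noise phenotype drives sampled pi toward 1", {
  sh <- shared_sim()
  geno <- sh$qc$genotypes
  set.seed(12)
  y <- rnorm(nrow(geno))
  post <- run_gibbs(y, geno, chain_config(1000, 200, seed = 5))
  expect_gt(mean(post$pi_chain), 0.8)
  # residual-variance chain mixes with positive, decaying autocorrelation
  s2e <- post$sigma2_e_chain
  ac <- acf(s2e, lag.max = 5, plot = FALSE)$acf[-1]
  expect_true(all(is.finite(s2e)) && all(s2e > 0))
  expect_gt(ac[1], 0)
})

test_that("GEBVs are dot products, linear in effects, and alignment-checked", {
  geno <- matrix(c(2, 1, 1, 1), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  eff <- c(s1 = 0.5, s2 = -0.2)
  expect_equal(gebv_from_effects(eff, geno), c(a = 0.8, b = 0.3))
  expect_equal(gebv_from_effects(2 * eff, geno),
               2 * gebv_from_effects(eff, geno))
  expect_equal(unname(gebv_from_effects(c(s2 = -0.2, s1 = 0.5), geno)),
               c(0.8, 0.3))  # aligned by SNP name
  expect_error(gebv_from_effects(c(sX = 1, s1 = 1), geno), "do not match")
  expect_error(gebv_from_effects(c(1, 2, 3), unname(geno)), "length")
})
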