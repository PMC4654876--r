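test_that("invalid configurations are rejected with the violated invariant", {
  expect_error(sim_config(h2 = 0.7, cg_var_fraction = 0.4), "h2 \\+ cg")
  expect_error(sim_config(n_snps = 50, n_large_qtl = 10, n_poly_qtl = 60),
               "n_large_qtl \\+ n_poly_qtl")
  expect_error(sim_config(allele_freq_range = c(0.005, 0.5)),
               "allele_freq_range")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(n_large_qtl = 2, large_qtl_var_fraction = 0),
               "large_qtl_var_fraction")
})

test_that("missing_rate = 0 yields a complete dosage matrix in {0,1,2}", {
  cfg <- sim_config(n_animals = 60, n_snps = 40, n_sires = 10,
                    n_large_qtl = 0, n_poly_qtl = 10,
                    missing_rate = 0, seed = 3)
  sim <- simulate_genotypes(cfg)
  expect_false(anyNA(sim$genotypes))
  expect_true(all(sim$genotypes %in% 0:2))
  expect_identical(dim(sim$genotypes), c(60L, 40L))
})

test_that("observed allele frequencies track the configured founder range", {
  cfg <- sim_config(n_animals = 1000, n_snps = 60, n_sires = 100,
                    allele_freq_range = c(0.3, 0.3), ld_block_size = 1,
                    n_large_qtl = 0, n_poly_qtl = 20,
                    missing_rate = 0, seed = 11)
  sim <- simulate_genotypes(cfg)
  p <- colMeans(sim$true_genotypes) / 2
  expect_true(all(abs(p - 0.3) < 0.05))
})

test_that("ld_block_size = 1 gives uncorrelated adjacent SNPs on average", {
  rs <- vapply(1:10, function(s) {
    cfg <- sim_config(n_animals = 300, n_snps = 50, n_sires = 300,
                      ld_block_size = 1, n_large_qtl = 0, n_poly_qtl = 10,
                      missing_rate = 0, seed = s)
    g <- simulate_genotypes(cfg)$true_genotypes
    mean(abs(diag(cor(g[, -ncol(g)], g[, -1]))), na.rm = TRUE)
  }, numeric(1))
  # half-sib structure alone leaves only weak spurious correlation
  expect_lt(mean(rs), 0.1)
  cfg <- sim_config(n_animals = 300, n_snps = 50, n_sires = 300,
                    ld_block_size = 10, n_founder_haplotypes = 4,
                    n_large_qtl = 0, n_poly_qtl = 10,
                    missing_rate = 0, seed = 1)
  g <- simulate_genotypes(cfg)$true_genotypes
  r_ld <- mean(abs(diag(cor(g[, -ncol(g)], g[, -1]))), na.rm = TRUE)
  expect_gt(r_ld, 0.3)  # blocks induce strong adjacent-SNP correlation
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_animals = 80, n_snps = 60, n_sires = 8,
                    n_large_qtl = 1, n_poly_qtl = 20, seed = 9)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$traits, b$traits)
  expect_identical(a$truth, b$truth)
})

test_that("true breeding values are the centered dosages times QTL effects", {
  sh <- shared_sim()
  X <- sh$dat$true_genotypes
  p <- colMeans(X) / 2
  eff <- numeric(ncol(X))
  eff[sh$dat$truth$qtl_indices] <- sh$dat$truth$qtl_effects
  tbv <- drop(sweep(X, 2, 2 * p) %*% eff)
  expect_equal(tbv, sh$dat$truth$true_breeding_values, tolerance = 1e-12)
})

test_that("h2 = 0 removes all genetic signal; zero variance fractions give pure noise", {
  cfg <- sim_config(n_animals = 300, n_snps = 50, n_sires = 30, h2 = 0,
                    n_large_qtl = 0, n_poly_qtl = 20,
                    cg_var_fraction = 0, missing_rate = 0, seed = 5)
  dat <- simulate_study(cfg)
  expect_true(all(dat$truth$true_breeding_values == 0))
  noise <- dat$traits$trait - 10 - dat$truth$fixed_effect_values
  expect_equal(noise, dat$truth$residuals, tolerance = 1e-12)
  expect_equal(sd(noise), 1, tolerance = 0.15)
})

test_that("realized heritability and QTL variance shares match the configuration", {
  cfg <- sim_config(n_animals = 5000, n_snps = 300, n_sires = 250, h2 = 0.5,
                    n_large_qtl = 1, large_qtl_var_fraction = 0.25,
                    n_poly_qtl = 100, missing_rate = 0, seed = 21)
  dat <- simulate_study(cfg)
  expect_gt(dat$truth$true_h2_realized, 0.45)
  expect_lt(dat$truth$true_h2_realized, 0.55)
  # the large QTL's 2p(1-p)a^2 carries ~25% of var(TBV)
  qi <- dat$truth$large_qtl_indices
  p <- dat$truth$allele_freqs[qi]
  a <- dat$truth$qtl_effects[match(qi, dat$truth$qtl_indices)]
  share <- 2 * p * (1 - p) * a^2 / var(dat$truth$true_breeding_values)
  expect_equal(unname(share), 0.25, tolerance = 0.12)
  # regression of phenotype on TBV has slope ~ 1
  slope <- coef(lm(dat$traits$trait ~ dat$truth$true_breeding_values))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)
})

test_that("half-sib families are balanced across sires and dams unrecorded", {
  sh <- shared_sim()
  ped <- sh$dat$pedigree
  expect_true(all(is.na(ped$dam)))
  expect_true(max(table(ped$sire)) - min(table(ped$sire)) <= 1)
})
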