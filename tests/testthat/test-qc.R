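test_that("minor allele frequency follows the allele-count definition", {
  expect_equal(compute_maf(c(0, 0, 1, 2, 2, 1)), 0.5)      # 6 of 12 alleles
  expect_equal(compute_maf(c(0, 0, 0, 0)), 0)              # monomorphic
  expect_equal(compute_maf(c(2, 2, 2, 1)), 0.125)          # min(7/8, 1/8)
  expect_equal(compute_maf(c(2, NA, 0)), 0.5)              # missing excluded
  expect_error(compute_maf(c(NA, NA)), "all genotypes missing")
})

test_that("Hardy-Weinberg chi-square test matches closed-form expectations", {
  expect_equal(hwe_test(c(25, 50, 25)), 1)                 # exact HWE
  expect_equal(hwe_test(c(100, 0, 0)), 1)                  # monomorphic
  # (50, 0, 50): expected (25, 50, 25) at p = 0.5 gives chi2 = 100
  p <- hwe_test(c(50, 0, 50))
  expect_equal(p, pchisq(100, df = 1, lower.tail = FALSE))
  expect_lt(p, 1e-6)
  expect_error(hwe_test(c(-1, 2, 3)), "non-negative")
})

test_that("correlation pruning keeps the first of each correlated pair", {
  set.seed(1)
  x <- rbinom(200, 2, 0.4)
  y <- rbinom(200, 2, 0.4)  # independent, |r| << 0.95
  geno <- cbind(a = x, dup1 = x, b = y, dup2 = x)
  map <- data.frame(snp = colnames(geno), chr = 1L, pos = 1:4 * 1000L)
  kept <- prune_correlated(geno, map, corr_max = 0.95)
  expect_identical(kept, c(1L, 3L))  # both duplicates dropped, b kept
  expect_identical(prune_correlated(cbind(x, y), map[1:2, ], 0.95), c(1L, 2L))
})

test_that("sporadic imputation is frequency-preserving and leaves observed cells", {
  geno <- matrix(c(0, 1, 2, 1, NA, 2, 2, 2), ncol = 2)
  out <- impute_sporadic(geno, seed = 4)
  expect_false(anyNA(out$genotypes))
  expect_identical(out$genotypes[!is.na(geno)], geno[!is.na(geno)])
  # p-hat = 1 forces dosage 2
  g2 <- matrix(c(2, 2, 2, NA), ncol = 1)
  expect_equal(impute_sporadic(g2, seed = 1)$genotypes[4, 1], 2)
  # p-hat = 0.5 with many missing: mean imputed dosage ~ 1
  g3 <- matrix(c(rep(c(0, 2), 50), rep(NA, 10000)), ncol = 1)
  imp <- impute_sporadic(g3, seed = 2)$genotypes[101:10100, 1]
  expect_equal(mean(imp), 1, tolerance = 0.03)
  # identical output when nothing is missing
  g4 <- matrix(rbinom(40, 2, 0.5), ncol = 4)
  expect_identical(impute_sporadic(g4, seed = 3)$genotypes, g4)
})

test_that("filters apply in fixed order with order-consistent counts", {
  set.seed(2)
  n <- 120
  ok <- replicate(6, rbinom(n, 2, runif(1, 0.3, 0.7)))
  rare <- rbinom(n, 2, 0.01)                      # fails MAF
  gap <- c(rep(NA, 40), rbinom(n - 40, 2, 0.5))   # fails missingness
  hw <- sample(c(0, 2), n, replace = TRUE)        # no hets: fails HWE
  dup <- ok[, 1]                                  # fails correlation
  geno <- cbind(ok[, 1:3], rare, gap, hw, ok[, 4:6], dup)
  map <- data.frame(snp = paste0("s", 1:10), chr = 1L, pos = 1:10 * 1000L)
  res <- run_qc(geno, map, qc_thresholds(), seed = 1)
  rem <- res$report$n_removed_by_filter
  expect_equal(rem$missingness, 1)
  expect_equal(rem$maf, 1)
  expect_equal(rem$hwe, 1)
  expect_equal(rem$correlation, 1)
  expect_equal(res$report$n_input_snps,
               res$report$n_kept + sum(unlist(rem)))
  # MAF exactly at the 0.05 boundary is kept
  g_edge <- cbind(matrix(rbinom(200, 2, 0.5), ncol = 2),
                  edge = rep(c(1, rep(0, 9)), 10))  # p exactly 0.05
  expect_equal(compute_maf(g_edge[, 3]), 0.05)
  map3 <- data.frame(snp = paste0("s", 1:3), chr = 1L, pos = 1:3)
  expect_equal(run_qc(g_edge, map3, seed = 1)$report$n_removed_by_filter$maf, 0)
})

test_that("QC on an already-clean matrix removes nothing", {
  sh <- shared_sim()
  again <- run_qc(sh$qc$genotypes, sh$qc$map, seed = 1)
  expect_equal(again$report$n_kept, ncol(sh$qc$genotypes))
  expect_equal(sum(unlist(again$report$n_removed_by_filter)), 0)
  expect_identical(again$genotypes, sh$qc$genotypes)
})
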