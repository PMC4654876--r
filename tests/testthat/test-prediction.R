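toy_pedigree <- function(n_sires, per_family) {
  n <- n_sires * per_family
  data.frame(animal = sprintf("a%03d", seq_len(n)),
             sire = rep(sprintf("s%02d", seq_len(n_sires)), each = per_family),
             dam = NA_character_, stringsAsFactors = FALSE)
}

test_that("folds are sire-disjoint, breed-covered and size-balanced", {
  ped <- toy_pedigree(50, 10)
  breed <- rep(paste0("B", 1 + (seq_len(50) - 1) %% 5), each = 10)
  folds <- make_folds(ped, breed, k = 10, seed = 4)
  expect_equal(as.vector(table(folds$fold)), rep(50L, 10))
  # no sire family split across folds
  expect_true(all(tapply(folds$fold, folds$sire,
                         function(f) length(unique(f))) == 1))
  # every breed in every fold
  cover <- table(folds$fold, folds$breed)
  expect_true(all(cover > 0))
})

test_that("k equal to the number of families gives one family per fold", {
  ped <- toy_pedigree(8, 5)
  breed <- rep("B1", 40)
  folds <- make_folds(ped, breed, k = 8, seed = 1)
  expect_equal(sort(as.vector(table(folds$fold))), rep(5L, 8))
  expect_error(make_folds(ped, rep(c("B1", "Rare"), c(39, 1)), k = 8),
               "Rare")
  expect_error(make_folds(toy_pedigree(3, 5), rep("B1", 15), k = 5),
               "fewer sire families")
})

test_that("BLUP gives zero EBV without information and follows the shrinkage limit", {
  ids <- c("t1", "t2", "t3", "v1")
  K <- diag(4); dimnames(K) <- list(ids, ids)
  Kr <- structure(list(values = K, kind = "genomic", animal_ids = ids),
                  class = "relationship_matrix")
  y <- c(t1 = 1.2, t2 = -0.5, t3 = 0.3)
  expect_equal(unname(blup_predict(y, Kr, "v1", 1, 1)), 0)  # K_vt = 0
  # validation animal duplicating one training animal, sigma2_a -> large:
  # EBV converges to that animal's centered record (shrinkage vanishes)
  ids2 <- c("t1", "t2", "v1")
  K2 <- diag(3); dimnames(K2) <- list(ids2, ids2)
  K2["t1", "v1"] <- K2["v1", "t1"] <- 0.999
  Kr2 <- structure(list(values = K2, kind = "genomic", animal_ids = ids2),
                   class = "relationship_matrix")
  y2 <- c(t1 = 2, t2 = -1)
  ebv <- blup_predict(y2, Kr2, "v1", sigma2_a = 1e6, sigma2_e = 1)
  expect_equal(unname(ebv), unname(y2["t1"] - mean(y2)), tolerance = 0.05)
  expect_error(blup_predict(y, Kr, "nope", 1, 1), "absent")
})

test_that("MME and kernel GBLUP routes agree to numerical precision", {
  sh <- shared_sim()
  G <- grm_vanraden1(sh$qc$genotypes)
  ids <- G$animal_ids
  y <- sh$dat$truth$true_breeding_values + sh$dat$truth$residuals
  names(y) <- ids
  val <- ids[1:40]; trn <- setdiff(ids, val)
  e1 <- blup_predict(y[trn], G, val, 0.5, 0.5, route = "kernel")
  e2 <- blup_predict(y[trn], G, val, 0.5, 0.5, route = "mme")
  expect_equal(e1, e2, tolerance = 1e-8)
})

test_that("pedigree BLUP propagates information through half-sib ties only", {
  ped <- toy_pedigree(6, 10)
  A <- a_matrix(ped)
  set.seed(1)
  y <- rnorm(59)
  names(y) <- ped$animal[-1]   # first animal held out
  # validation animal's half-sibs are phenotyped -> nonzero EBV
  ebv <- blup_predict(y, A, ped$animal[1], 0.5, 0.5)
  expect_gt(abs(ebv), 0)
  # validation animal from an entirely unphenotyped family with unknown sire
  ped2 <- rbind(ped, data.frame(animal = "lone", sire = NA, dam = NA))
  A2 <- a_matrix(ped2)
  expect_equal(unname(blup_predict(y, A2, "lone", 0.5, 0.5)), 0)
})

test_that("fold metrics implement r, realized accuracy and bias slope", {
  m <- evaluate_fold(c(1, 2, 3, 4), c(1, 2, 3, 4), h2 = 0.36)
  expect_equal(m$r, 1); expect_equal(m$slope, 1)
  set.seed(4)
  ebv <- rnorm(200); ys <- 0.3 * scale(ebv) + sqrt(1 - 0.09) * rnorm(200)
  m2 <- evaluate_fold(ebv, drop(ys), h2 = 0.36)
  expect_equal(m2$accuracy, m2$r / 0.6)
  expect_true(is.na(evaluate_fold(rep(1, 10), rnorm(10), 0.4)$r))
  expect_true(is.na(evaluate_fold(rnorm(10), rnorm(10), h2 = 0)$accuracy))
})

test_that("a noise predictor has realized accuracy near zero", {
  set.seed(6)
  accs <- replicate(30, evaluate_fold(rnorm(100), rnorm(100), 0.25)$accuracy)
  se <- sd(accs) / sqrt(30)
  expect_lt(abs(mean(accs)), 2 * se + 0.1)
})

test_that("cross-validation aggregates per-fold metrics with SE across folds", {
  sh <- shared_sim()
  G <- grm_vanraden1(sh$qc$genotypes)
  y <- sh$dat$truth$true_breeding_values + sh$dat$truth$residuals
  names(y) <- G$animal_ids
  folds <- make_folds(sh$dat$pedigree, sh$dat$traits$breed, k = 5, seed = 2)
  cv <- cross_validate(y, folds, methods = "gblup", G = G,
                       sigma2_a = 0.5, sigma2_e = 0.5, h2 = 0.5)
  expect_equal(nrow(cv$per_fold), 5)
  expect_equal(cv$summary$mean_accuracy,
               mean(cv$per_fold$accuracy))
  expect_equal(cv$summary$se_accuracy,
               sd(cv$per_fold$accuracy) / sqrt(5))
  expect_gt(cv$summary$mean_accuracy, 0.3)  # real signal, h2 = 0.5
})
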