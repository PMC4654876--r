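#' Sire-family-disjoint, breed-balanced cross-validation folds
#'
#' Whole sire families (paternal half-sib groups) are packed into `k` folds
#' so that no family is split across folds and fold sizes stay close to
#' `n/k`.  Families carry a majority-breed label, and families of each breed
#' are spread round-robin across folds (smallest fold first) so every breed
#' present in a validation fold is also represented in training.
#'
#' @param pedigree data.frame (animal, sire, dam).
#' @param breed per-animal breed labels aligned with `pedigree` rows.
#' @param k number of folds (default 10).
#' @param seed integer seed; the packing is deterministic given it.
#' @return a `fold_assignment`: data.frame (animal, sire, breed, fold).
#' @export
make_folds <- function(pedigree, breed, k = 10L, seed = 1L) {
  stopifnot(nrow(pedigree) == length(breed))
  sire <- as.character(pedigree$sire)
  sire[is.na(sire)] <- paste0(".founder", seq_len(sum(is.na(sire))))
  fam <- split(seq_along(sire), sire)
  if (length(fam) < k)
    stop("fewer sire families (", length(fam), ") than folds (", k, ")")
  breed <- as.character(breed)
  n_by_breed <- table(breed)
  scarce <- names(n_by_breed)[n_by_breed < k]
  if (length(scarce) > 0L)
    stop("breed ", scarce[1L], " has fewer than k = ", k,
         " animals; breed-balanced folds impossible")

  fam_breed <- vapply(fam, function(ix)
    names(which.max(table(breed[ix]))), character(1))
  fam_size <- lengths(fam)

  set.seed(seed)
  fold_of_fam <- integer(length(fam))
  names(fold_of_fam) <- names(fam)
  fold_size <- numeric(k)
  for (b in sample(unique(fam_breed))) {
    fs <- names(fam)[fam_breed == b]
    fs <- fs[order(-fam_size[fs], stats::runif(length(fs)))]
    for (f in fs) {
      tgt <- which.min(fold_size)
      fold_of_fam[f] <- tgt
      fold_size[tgt] <- fold_size[tgt] + fam_size[f]
    }
  }
  fold <- integer(nrow(pedigree))
  for (f in names(fam)) fold[fam[[f]]] <- fold_of_fam[f]
  out <- data.frame(animal = as.character(pedigree$animal), sire = sire,
                    breed = breed, fold = fold, stringsAsFactors = FALSE)
  class(out) <- c("fold_assignment", "data.frame")
  out
}

#' BLUP of breeding values with a relationship matrix
#'
#' Solves the animal model `y* = 1 mu + Z a + e` with `a ~ N(0, K sigma2_a)`
#' for the combined training + validation set, validation records absent.
#' Two algebraically equivalent routes are provided: the mixed-model
#' equations over all animals, and direct kernel regression
#' `a_hat_v = K_vt (K_tt + lambda I)^-1 (y*_t - mu_hat)` with
#' `lambda = sigma2_e / sigma2_a` and `mu_hat` the training mean.
#'
#' @param y_star named vector of adjusted phenotypes for training animals.
#' @param K a `relationship_matrix` (genomic or pedigree) covering training
#'   and validation animals.
#' @param validation_ids IDs of animals to predict.
#' @param sigma2_a,sigma2_e variance components (full-data REML estimates).
#' @param route `"kernel"` (default) or `"mme"`.
#' @param ridge diagonal stabilization added to K before inversion.
#' @return named numeric vector of EBVs for `validation_ids`.
#' @export
blup_predict <- function(y_star, K, validation_ids, sigma2_a, sigma2_e,
                         route = c("kernel", "mme"), ridge = 1e-6) {
  route <- match.arg(route)
  stopifnot(sigma2_a > 0, sigma2_e > 0)
  train_ids <- names(y_star)
  if (is.null(train_ids)) stop("y_star must be named by animal ID")
  missing <- setdiff(c(train_ids, validation_ids), K$animal_ids)
  if (length(missing) > 0L)
    stop("animals absent from relationship matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  lambda <- sigma2_e / sigma2_a
  if (route == "kernel") {
    Ktt <- K$values[train_ids, train_ids, drop = FALSE] + diag(ridge, length(train_ids))
    Kvt <- K$values[validation_ids, train_ids, drop = FALSE]
    mu_hat <- mean(y_star)
    alpha <- solve(Ktt + diag(lambda, length(train_ids)), y_star - mu_hat)
    ebv <- drop(Kvt %*% alpha)
  } else {
    # mixed-model equations over all animals, intercept absorbed by
    # centering on the training mean (identical to the kernel route's mu_hat)
    all_ids <- unique(c(train_ids, validation_ids))
    nA <- length(all_ids)
    Kall <- K$values[all_ids, all_ids, drop = FALSE] + diag(ridge, nA)
    Kinv <- solve(Kall)
    nT <- length(train_ids)
    Z <- matrix(0, nT, nA, dimnames = list(train_ids, all_ids))
    Z[cbind(seq_len(nT), match(train_ids, all_ids))] <- 1
    yc <- y_star - mean(y_star)
    C <- crossprod(Z) + Kinv * lambda
    a_hat <- drop(solve(C, crossprod(Z, yc)))
    names(a_hat) <- all_ids
    ebv <- a_hat[validation_ids]
  }
  names(ebv) <- validation_ids
  ebv
}

#' Fold-level prediction metrics
#'
#' Returns the Pearson correlation between EBV and adjusted phenotype in
#' the validation set, the realized accuracy `r/sqrt(h2)`, and the slope
#' of the least-squares regression of `y*` on EBV (1 for unbiased
#' predictions).
#'
#' @param ebv predicted breeding values of the validation animals.
#' @param y_star their adjusted phenotypes.
#' @param h2 full-data heritability estimate (> 0; accuracy is undefined and
#'   reported `NA` at h2 = 0).
#' @return list(r, accuracy, slope, n); all metrics `NA` (fold flagged) when
#'   the EBVs have zero variance or fewer than 3 animals are available.
#' @export
evaluate_fold <- function(ebv, y_star, h2) {
  n <- length(ebv)
  if (n < 3L || !(stats::var(ebv) > 0) || !(stats::var(y_star) > 0))
    return(list(r = NA_real_, accuracy = NA_real_, slope = NA_real_, n = n))
  r <- stats::cor(ebv, y_star)
  acc <- if (!is.na(h2) && h2 > 0) r / sqrt(h2) else NA_real_
  slope <- stats::cov(y_star, ebv) / stats::var(ebv)
  list(r = r, accuracy = acc, slope = slope, n = n)
}

#' Cross-validated genomic/pedigree prediction
#'
#' Runs sire-family-disjoint k-fold cross-validation for one or more
#' prediction methods and aggregates realized accuracy across folds.
#' Variance components and heritability come from the full-data REML fit
#' (per-fold re-estimation via `refit_each_fold`).
#'
#' @param y_star named vector of adjusted phenotypes (all animals).
#' @param folds a [make_folds()] assignment.
#' @param methods subset of `"gblup"`, `"pblup"`, `"bayescpi"`.
#' @param G genomic `relationship_matrix` (for gblup).
#' @param A pedigree `relationship_matrix` (for pblup).
#' @param geno complete dosage matrix (for bayescpi), rows named by animal.
#' @param sigma2_a,sigma2_e,h2 full-data REML variance components and
#'   heritability.
#' @param chain [chain_config()] for the Bayesian method.
#' @param refit_each_fold re-estimate variance components on each training
#'   set (GBLUP/PBLUP only; slower).
#' @param ... further arguments to [run_gibbs()].
#' @return a `prediction_report`: `per_fold` data.frame (method, fold, r,
#'   accuracy, slope, n) and `summary` data.frame (method, mean +/- SE of
#'   each metric across folds).
#' @export
cross_validate <- function(y_star, folds, methods = c("gblup", "pblup"),
                           G = NULL, A = NULL, geno = NULL,
                           sigma2_a, sigma2_e, h2,
                           chain = chain_config(n_iter = 2000L, burn_in = 500L),
                           refit_each_fold = FALSE, ...) {
  methods <- match.arg(methods, c("gblup", "pblup", "bayescpi"),
                       several.ok = TRUE)
  ids <- names(y_star)
  stopifnot(!is.null(ids), all(folds$animal %in% ids))
  rows <- list()
  for (method in methods) {
    for (f in sort(unique(folds$fold))) {
      val_ids <- folds$animal[folds$fold == f]
      trn_ids <- folds$animal[folds$fold != f]
      yt <- y_star[trn_ids]
      s2a <- sigma2_a; s2e <- sigma2_e
      if (refit_each_fold && method %in% c("gblup", "pblup")) {
        K <- if (method == "gblup") G else A
        Kt <- subset_relationship(K, trn_ids)
        fit <- fit_reml(yt, matrix(1, length(yt), 1), Kt$values)
        s2a <- fit$sigma2_a; s2e <- fit$sigma2_e
      }
      ebv <- switch(method,
        gblup = blup_predict(yt, G, val_ids, s2a, s2e),
        pblup = blup_predict(yt, A, val_ids, s2a, s2e),
        bayescpi = {
          cfg <- chain
          cfg$seed <- chain$seed + f
          post <- run_gibbs(yt, geno[trn_ids, , drop = FALSE], cfg, ...)
          gebv_from_effects(post$effect_mean, geno[val_ids, , drop = FALSE])
        })
      m <- evaluate_fold(ebv, y_star[val_ids], h2)
      rows[[length(rows) + 1L]] <-
        data.frame(method = method, fold = f, r = m$r, accuracy = m$accuracy,
                   slope = m$slope, n = m$n, stringsAsFactors = FALSE)
    }
  }
  per_fold <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_fold, per_fold$method), function(d) {
    kf <- sum(!is.na(d$accuracy))
    data.frame(method = d$method[1L],
               mean_r = mean(d$r, na.rm = TRUE),
               mean_accuracy = mean(d$accuracy, na.rm = TRUE),
               se_accuracy = stats::sd(d$accuracy, na.rm = TRUE) / sqrt(max(kf, 1L)),
               mean_slope = mean(d$slope, na.rm = TRUE),
               n_folds = kf, stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(list(per_fold = per_fold, summary = agg),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("Cross-validated prediction accuracy (realized, r / sqrt(h2))\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-9s %.3f +/- %.3f  (slope %.2f, %d folds)\n",
                x$summary$method[i], x$summary$mean_accuracy[i],
                x$summary$se_accuracy[i], x$summary$mean_slope[i],
                x$summary$n_folds[i]))
  invisible(x)
}
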