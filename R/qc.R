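#' SNP quality-control thresholds
#'
#' Filters mirror routine 50K-chip QC: SNPs are removed when call rate is too
#' low, the minor allele is too rare, genotype frequencies deviate extremely
#' from Hardy-Weinberg expectations, or the SNP is nearly collinear with an
#' already-retained neighbour.
#'
#' @param maf_min minimum minor allele frequency; SNPs with MAF strictly
#'   below this are removed (MAF equal to the threshold is kept).
#' @param missing_max maximum per-SNP missing-call rate; strictly greater is
#'   removed.
#' @param hwe_p_min minimum Hardy-Weinberg chi-square p-value; strictly
#'   smaller is removed.
#' @param corr_max pairwise dosage correlation at or above which the later
#'   SNP (in map order) of a pair is removed.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.05, missing_max = 0.20,
                          hwe_p_min = 1e-6, corr_max = 0.95) {
  stopifnot(maf_min > 0, maf_min < 1, missing_max > 0, missing_max < 1,
            hwe_p_min > 0, hwe_p_min < 1, corr_max > 0, corr_max <= 1)
  structure(list(maf_min = maf_min, missing_max = missing_max,
                 hwe_p_min = hwe_p_min, corr_max = corr_max),
            class = "qc_thresholds")
}

#' Minor allele frequency of a dosage vector
#'
#' @param dosages vector of dosages in \{0, 1, 2\}, `NA` allowed.
#' @return `min(p, 1 - p)` where `p` is the observed frequency of the coded
#'   allele among non-missing calls.
#' @export
compute_maf <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("allele frequency undefined: all genotypes missing")
  p <- sum(dosages[ok]) / (2 * sum(ok))
  min(p, 1 - p)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against Hardy-Weinberg expectations at the observed allele frequency.
#' Monomorphic SNPs return p = 1.
#'
#' @param counts integer vector `(n_AA, n_Aa, n_aa)` of genotype counts,
#'   where AA carries two copies of the coded allele.
#' @return the chi-square p-value.
#' @export
hwe_test <- function(counts) {
  if (length(counts) != 3L || any(counts < 0))
    stop("counts must be three non-negative genotype counts")
  n <- sum(counts)
  if (n < 1L) stop("at least one genotyped animal required")
  p <- (2 * counts[1L] + counts[2L]) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((counts - expected)^2 / expected)
  stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
}

hwe_test_matrix <- function(geno) {
  apply(geno, 2L, function(g) {
    g <- g[!is.na(g)]
    hwe_test(c(sum(g == 2L), sum(g == 1L), sum(g == 0L)))
  })
}

#' Greedy correlation pruning of SNPs
#'
#' Scans SNPs left-to-right in map order within each chromosome and removes
#' a SNP whose absolute Pearson dosage correlation with any retained SNP in
#' the preceding window reaches `corr_max`; the first SNP of a correlated
#' pair (in map order) is always the one kept.
#'
#' @param geno n x M dosage matrix (missing allowed; pairwise-complete
#'   correlations are used).
#' @param map data.frame (snp, chr, pos) aligned with the columns of `geno`.
#' @param corr_max correlation threshold.
#' @param window number of retained SNPs looked back at.
#' @return integer vector of kept column indices (ascending).
#' @export
prune_correlated <- function(geno, map, corr_max = 0.95, window = 50L) {
  keep <- integer(0)
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    idx <- idx[order(map$pos[idx])]
    kept_ch <- integer(0)
    for (j in idx) {
      recent <- utils::tail(kept_ch, window)
      drop_j <- FALSE
      if (length(recent) > 0L) {
        r <- suppressWarnings(
          stats::cor(geno[, j], geno[, recent, drop = FALSE],
                     use = "pairwise.complete.obs"))
        r[is.na(r)] <- 0
        drop_j <- any(abs(r) >= corr_max - 1e-12)
      }
      if (!drop_j) kept_ch <- c(kept_ch, j)
    }
    keep <- c(keep, kept_ch)
  }
  sort(keep)
}

#' Impute sporadically missing genotypes
#'
#' Each missing call is replaced by a Binomial(2, p-hat) draw at the SNP's
#' observed coded-allele frequency, which preserves allele frequencies in
#' expectation.  Observed calls are never changed.  Intended for the sporadic
#' (<1%) missingness left after the call-rate filter, not for low-density
#' panel imputation.
#'
#' @param geno n x M dosage matrix with `NA` for missing calls.
#' @param seed integer seed making the draws reproducible.
#' @return the completed matrix and the fraction of cells imputed, as a list
#'   `(genotypes, fraction_imputed)`.
#' @export
impute_sporadic <- function(geno, seed = 1L) {
  set.seed(seed)
  n_missing <- 0L
  for (j in seq_len(ncol(geno))) {
    miss <- which(is.na(geno[, j]))
    if (length(miss) == 0L) next
    obs <- geno[!is.na(geno[, j]), j]
    if (length(obs) == 0L)
      stop("SNP column ", j, " entirely missing; apply the call-rate filter first")
    p <- sum(obs) / (2 * length(obs))
    geno[miss, j] <- stats::rbinom(length(miss), 2L, p)
    n_missing <- n_missing + length(miss)
  }
  list(genotypes = geno,
       fraction_imputed = n_missing / length(geno))
}

#' Run the full SNP QC pipeline
#'
#' Applies, in fixed order: (1) call-rate filter, (2) minor-allele-frequency
#' filter, (3) Hardy-Weinberg filter, (4) within-chromosome correlation
#' pruning, then imputes the remaining sporadic missing calls.
#'
#' @param geno n x M dosage matrix with `NA` for missing.
#' @param map SNP map aligned with `geno` columns.
#' @param thresholds a [qc_thresholds()] object.
#' @param window look-back window for correlation pruning.
#' @param seed seed for the imputation draws.
#' @return list with `genotypes` (filtered, complete), `map` (filtered),
#'   `report` (a `qc_report`: n_input_snps, n_removed_by_filter, n_kept,
#'   fraction_imputed), and `kept` (original column indices retained).
#' @export
run_qc <- function(geno, map, thresholds = qc_thresholds(), window = 50L,
                   seed = 1L) {
  stopifnot(ncol(geno) == nrow(map))
  n_input <- ncol(geno)
  removed <- c(missingness = 0L, maf = 0L, hwe = 0L, correlation = 0L)

  miss_rate <- colMeans(is.na(geno))
  pass <- miss_rate <= thresholds$missing_max
  removed["missingness"] <- sum(!pass)
  idx <- which(pass)

  maf <- apply(geno[, idx, drop = FALSE], 2L, compute_maf)
  pass <- maf >= thresholds$maf_min
  removed["maf"] <- sum(!pass)
  idx <- idx[pass]

  hwe_p <- hwe_test_matrix(geno[, idx, drop = FALSE])
  pass <- hwe_p >= thresholds$hwe_p_min
  removed["hwe"] <- sum(!pass)
  idx <- idx[pass]

  sub_map <- map[idx, , drop = FALSE]
  kept_rel <- prune_correlated(geno[, idx, drop = FALSE], sub_map,
                               corr_max = thresholds$corr_max,
                               window = window)
  removed["correlation"] <- length(idx) - length(kept_rel)
  idx <- idx[kept_rel]

  imp <- impute_sporadic(geno[, idx, drop = FALSE], seed = seed)
  report <- structure(list(n_input_snps = n_input,
                           n_removed_by_filter = as.list(removed),
                           n_kept = length(idx),
                           fraction_imputed = imp$fraction_imputed),
                      class = "qc_report")
  list(genotypes = imp$genotypes, map = map[idx, , drop = FALSE],
       report = report, kept = idx)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP QC report\n")
  cat("  input SNPs:     ", x$n_input_snps, "\n")
  for (f in names(x$n_removed_by_filter))
    cat(sprintf("  removed (%s): %d\n", f, x$n_removed_by_filter[[f]]))
  cat("  kept:           ", x$n_kept, "\n")
  cat(sprintf("  cells imputed:   %.3f%%\n", 100 * x$fraction_imputed))
  invisible(x)
}
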