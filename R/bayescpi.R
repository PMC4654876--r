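#' Prior scale parameters for the BayesC-pi variance priors
#'
#' The scaled-inverse-chi-square priors on the common SNP-effect variance
#' and the residual variance are anchored to REML estimates of the additive
#' and residual variances:
#' `S2_a = sigma2_u_hat (v_a - 2) / [v_a (1 - pi) sum_j 2 p_j (1 - p_j)]`
#' and `S2_e = sigma2_0_hat (v_e - 2) / v_e`.  The `pi` entering `S2_a` is
#' the value at chain initialization; with a sampled `pi` the scale stays
#' frozen at that value.
#'
#' @param sigma2_u_hat,sigma2_0_hat REML additive and residual variances.
#' @param v_a,v_e prior degrees of freedom (defaults 4 and 10).
#' @param pi prior/initial exclusion probability.
#' @param allele_freqs per-SNP coded-allele frequencies `p_j`.
#' @return list(S2_a, S2_e).
#' @export
prior_scales <- function(sigma2_u_hat, sigma2_0_hat, v_a = 4, v_e = 10,
                         pi = 0.9, allele_freqs) {
  if (v_a <= 2 || v_e <= 2) stop("prior degrees of freedom must exceed 2")
  if (pi >= 1) stop("pi = 1 leaves no SNPs to carry variance (division by zero)")
  sum2pq <- sum(2 * allele_freqs * (1 - allele_freqs))
  if (sum2pq <= 0) stop("sum 2p(1-p) must be positive")
  list(S2_a = sigma2_u_hat * (v_a - 2) / (v_a * (1 - pi) * sum2pq),
       S2_e = sigma2_0_hat * (v_e - 2) / v_e)
}

#' Gibbs-chain configuration
#'
#' Defaults match a production whole-genome regression run: 45,000
#' iterations with the first 5000 discarded as burn-in, no thinning.
#'
#' @param n_iter total chain length.
#' @param burn_in iterations discarded before summarization.
#' @param thin keep every `thin`-th post-burn-in state.
#' @param seed integer seed.
#' @return a `chain_config` list.
#' @export
chain_config <- function(n_iter = 45000L, burn_in = 5000L, thin = 1L,
                         seed = 1L) {
  stopifnot(burn_in < n_iter, thin >= 1L)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "chain_config")
}

#' Run the BayesC-pi Gibbs sampler
#'
#' Whole-genome regression of adjusted phenotypes on SNP dosages under the
#' spike-and-slab mixture prior: each SNP effect is zero with probability
#' `pi` and Normal(0, sigma2_a) otherwise.  Per sweep the sampler updates
#' the general mean, every SNP's inclusion indicator and effect from their
#' full conditionals (likelihood ratios computed in log space), the two
#' variances from scaled-inverse-chi-square full conditionals, and - unless
#' `pi_fixed` is given - `pi` from its Beta full conditional under a uniform
#' prior.
#'
#' @param y_star numeric vector of adjusted phenotypes.
#' @param geno complete n x M dosage matrix in \{0, 1, 2\}.
#' @param config a [chain_config()].
#' @param sigma2_u_hat,sigma2_0_hat REML additive and residual variances
#'   anchoring the prior scales (see [prior_scales()]); defaults carve the
#'   phenotypic variance as half additive, half residual when no REML fit
#'   is supplied.
#' @param v_a,v_e prior degrees of freedom.
#' @param pi_init initial exclusion probability (also the value frozen into
#'   `S2_a`).
#' @param pi_fixed if non-NULL, `pi` is held at this value instead of being
#'   sampled (plain BayesC; used by the analytic oracle checks).
#' @param fix_variances hold `sigma2_a`/`sigma2_e` at their initial values
#'   (oracle mode).
#' @param sigma2_a_init,sigma2_e_init optional variance initializations;
#'   defaults `S2_a` and `sigma2_0_hat`.
#' @param sample_mu sample the general mean (flat prior); if FALSE the mean
#'   is held at 0 and `y_star` should be centered.
#' @param randomize_order permute the SNP update order each sweep instead of
#'   ascending map order.
#' @return a `posterior_summary`: effect_mean (unconditional posterior mean
#'   per SNP, zeros included), ppi (posterior inclusion probability), chains
#'   of mu/pi/sigma2_a/sigma2_e, n_samples, and the frozen prior scales.
#' @export
run_gibbs <- function(y_star, geno, config = chain_config(),
                      sigma2_u_hat = stats::var(y_star) / 2,
                      sigma2_0_hat = stats::var(y_star) / 2,
                      v_a = 4, v_e = 10, pi_init = 0.9,
                      pi_fixed = NULL, fix_variances = FALSE,
                      sigma2_a_init = NULL, sigma2_e_init = NULL,
                      sample_mu = TRUE, randomize_order = FALSE) {
  if (anyNA(geno)) stop("genotypes contain missing values; run QC/imputation first")
  n <- length(y_star)
  if (nrow(geno) != n) stop("phenotype and genotype dimensions disagree")
  if (n < 30L) stop("at least 30 records required")
  p <- colMeans(geno) / 2
  pi0 <- if (!is.null(pi_fixed)) pi_fixed else pi_init
  scales <- if (pi0 < 1)
    prior_scales(sigma2_u_hat, sigma2_0_hat, v_a, v_e, pi0, p)
  else list(S2_a = sigma2_u_hat * (v_a - 2) / (v_a * sum(2 * p * (1 - p))),
            S2_e = sigma2_0_hat * (v_e - 2) / v_e)
  s2a0 <- if (!is.null(sigma2_a_init)) sigma2_a_init else max(scales$S2_a, 1e-8)
  s2e0 <- if (!is.null(sigma2_e_init)) sigma2_e_init else sigma2_0_hat

  set.seed(config$seed)
  res <- .bayescpi_gibbs_cpp(as.numeric(y_star),
                             matrix(as.numeric(geno), nrow = n),
                             config$n_iter, config$burn_in, config$thin,
                             pi0, is.null(pi_fixed),
                             v_a, v_e, scales$S2_a, scales$S2_e,
                             s2a0, s2e0,
                             !fix_variances, !fix_variances,
                             if (sample_mu) mean(y_star) else 0, sample_mu,
                             randomize_order)
  res$snp_ids <- colnames(geno)
  res$allele_freqs <- p
  res$S2_a <- scales$S2_a
  res$S2_e <- scales$S2_e
  class(res) <- "posterior_summary"
  res
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("BayesC-pi posterior summary: %d SNPs, %d samples\n",
              length(x$effect_mean), x$n_samples))
  cat(sprintf("  mean pi = %.3f   max PPI = %.3f\n",
              mean(x$pi_chain), max(x$ppi)))
  invisible(x)
}

#' Genomic estimated breeding values from SNP effects
#'
#' `GEBV_i = sum_j x_ij a_j`: the per-animal dot product of dosages with
#' posterior-mean allele substitution effects.
#'
#' @param effect_mean named (by SNP ID) or plain vector of SNP effects.
#' @param geno dosage matrix for the target animals; when both carry SNP
#'   names the columns are aligned by name and a mismatch is an error.
#' @return numeric vector of GEBVs, one per row of `geno`.
#' @export
gebv_from_effects <- function(effect_mean, geno) {
  if (!is.null(names(effect_mean)) && !is.null(colnames(geno))) {
    if (!setequal(names(effect_mean), colnames(geno)))
      stop("SNP sets of effects and genotypes do not match")
    effect_mean <- effect_mean[colnames(geno)]
  } else if (length(effect_mean) != ncol(geno)) {
    stop("effect vector length does not match genotype columns")
  }
  drop(geno %*% effect_mean)
}
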