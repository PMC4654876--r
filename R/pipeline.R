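#' Pipeline run configuration
#'
#' Collects every stage's parameters with production defaults (45,000/5000
#' Gibbs chain, 1000 permutations, 10 CV folds) and a `"desk"` preset that
#' caps the chain at 5000 iterations and permutations at 100 for interactive
#' work on a single core.
#'
#' @param scale `"paper"` (production defaults) or `"desk"`.
#' @param sim a [sim_config()]; its seed is re-derived from `seed`.
#' @param qc a [qc_thresholds()].
#' @param n_perm permutations for the genome-wise threshold.
#' @param alpha genome-wise significance level.
#' @param chain_iter,chain_burnin Gibbs chain length and burn-in.
#' @param k_folds cross-validation folds.
#' @param methods prediction methods to run.
#' @param marbling include the marbling covariate in the adjustment model.
#' @param stages character vector of stages to execute, in pipeline order.
#' @param seed global seed; per-stage seeds are derived deterministically.
#' @return a `run_config` list.
#' @export
run_config <- function(scale = c("desk", "paper"),
                       sim = sim_config(),
                       qc = qc_thresholds(),
                       n_perm = NULL, alpha = 0.05,
                       chain_iter = NULL, chain_burnin = NULL,
                       k_folds = 10L,
                       methods = c("pblup", "gblup", "bayescpi"),
                       marbling = FALSE,
                       stages = c("simulate", "qc", "kinship", "varcomp",
                                  "gwas", "predict"),
                       seed = 1L) {
  scale <- match.arg(scale)
  if (is.null(chain_iter)) chain_iter <- if (scale == "paper") 45000L else 3000L
  if (is.null(chain_burnin)) chain_burnin <- if (scale == "paper") 5000L else 500L
  if (is.null(n_perm)) n_perm <- if (scale == "paper") 1000L else 50L
  if (scale == "desk") {
    if (n_perm > 100L) stop("desk preset caps n_perm at 100")
    if (chain_iter > 5000L) stop("desk preset caps chain length at 5000")
  }
  structure(list(scale = scale, sim = sim, qc = qc, n_perm = n_perm,
                 alpha = alpha, chain_iter = chain_iter,
                 chain_burnin = chain_burnin, k_folds = k_folds,
                 methods = methods, marbling = marbling, stages = stages,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `sim` and `qc`
#' sub-maps are passed to [sim_config()] and [qc_thresholds()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$sim)) args$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$qc)) args$qc <- do.call(qc_thresholds, raw$qc)
  do.call(run_config, args)
}

derive_seed <- function(seed, stage_index) {
  as.integer((seed + 7919L * stage_index) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data simulation, SNP QC, relationship matrices,
#' REML variance components with phenotype adjustment, BayesC-pi GWAS with
#' a permutation genome-wise threshold, and cross-validated prediction.
#' Each stage's seed derives deterministically from the global seed, so two
#' runs with the same configuration produce identical manifests and outputs.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, stage outputs (ped/map,
#'   trait CSV, GRM TSV, variance-component JSON, significant-SNP TSV,
#'   prediction TSV, manifest JSON) are written there (must not already
#'   contain a manifest: runs are write-once).
#' @param verbose print one line per stage.
#' @return a `pipeline_result` list with each stage's in-memory outputs and
#'   a `manifest` describing seeds and stage parameters.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir)) {
    if (file.exists(file.path(out_dir, "manifest.json")))
      stop("out_dir already holds a completed run (write-once)")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  res <- list()
  manifest <- list(seed = config$seed, scale = config$scale, stages = list())
  t_stage <- function(expr) system.time(expr)[["elapsed"]]

  cfg_sim <- config$sim
  cfg_sim$seed <- derive_seed(config$seed, 1L)
  el <- t_stage({
    sim <- simulate_genotypes(cfg_sim)
    ph <- simulate_phenotypes(sim, cfg_sim)
  })
  res$sim <- c(sim, ph)
  manifest$stages$simulate <- list(seed = cfg_sim$seed,
                                   n_animals = cfg_sim$n_animals,
                                   n_snps = cfg_sim$n_snps)
  say("simulate: %d animals x %d SNPs [%.1fs]",
      cfg_sim$n_animals, cfg_sim$n_snps, el)

  if ("qc" %in% config$stages) {
    el <- t_stage(qc <- run_qc(sim$genotypes, sim$map, config$qc,
                               seed = derive_seed(config$seed, 2L)))
    res$qc <- qc
    geno <- qc$genotypes
    map <- qc$map
    manifest$stages$qc <- list(n_kept = qc$report$n_kept,
                               removed = qc$report$n_removed_by_filter)
    say("qc: kept %d of %d SNPs [%.1fs]", qc$report$n_kept,
        qc$report$n_input_snps, el)
  } else {
    if (anyNA(sim$genotypes))
      stop("qc stage disabled but genotypes contain missing calls")
    geno <- sim$genotypes
    map <- sim$map
  }

  el <- t_stage({
    G <- grm_vanraden1(geno)
    A <- a_matrix(sim$pedigree)
    A <- subset_relationship(A, rownames(geno))
  })
  res$G <- G; res$A <- A
  manifest$stages$kinship <- list(mean_diag_G = mean(diag(G$values)))
  say("kinship: G and A built, mean diag(G) = %.3f [%.1fs]",
      mean(diag(G$values)), el)

  el <- t_stage({
    des <- adjustment_design(ph$traits, marbling = config$marbling)
    fit <- fit_reml(ph$traits$trait[des$keep], des$X,
                    G$values[des$keep, des$keep], des$Zcg)
    y_star <- adjust_phenotypes(ph$traits$trait[des$keep], des$X, des$Zcg, fit)
    names(y_star) <- ph$traits$animal_id[des$keep]
  })
  res$varcomp <- fit
  res$y_star <- y_star
  manifest$stages$varcomp <- list(sigma2_a = fit$sigma2_a,
                                  sigma2_cg = fit$sigma2_cg,
                                  sigma2_e = fit$sigma2_e, h2 = fit$h2)
  say("varcomp: h2 = %.3f (SE %.3f) [%.1fs]", fit$h2, fit$se_h2, el)

  if ("gwas" %in% config$stages) {
    cc <- chain_config(config$chain_iter, config$chain_burnin,
                       seed = derive_seed(config$seed, 3L))
    el <- t_stage({
      post <- run_gibbs(y_star, geno[names(y_star), ], cc,
                        sigma2_u_hat = fit$sigma2_a,
                        sigma2_0_hat = fit$sigma2_e)
      perm <- permutation_threshold(y_star, geno[names(y_star), ],
                                    alpha = config$alpha,
                                    n_perm = config$n_perm, config = cc,
                                    seed = derive_seed(config$seed, 4L),
                                    sigma2_u_hat = fit$sigma2_a,
                                    sigma2_0_hat = fit$sigma2_e)
      sig <- report_significant(post, map, perm$threshold,
                                sigma2_u_hat = fit$sigma2_a)
    })
    res$gwas <- list(posterior = post, permutation = perm, significant = sig)
    manifest$stages$gwas <- list(threshold = perm$threshold,
                                 n_significant = nrow(sig),
                                 n_perm = config$n_perm)
    say("gwas: threshold %.3f, %d significant SNPs [%.1fs]",
        perm$threshold, nrow(sig), el)
  }

  if ("predict" %in% config$stages) {
    el <- t_stage({
      folds <- make_folds(sim$pedigree[match(names(y_star),
                                             sim$pedigree$animal), ],
                          ph$traits$breed[des$keep], k = config$k_folds,
                          seed = derive_seed(config$seed, 5L))
      cv <- cross_validate(y_star, folds, methods = config$methods,
                           G = G, A = A, geno = geno[names(y_star), ],
                           sigma2_a = fit$sigma2_a, sigma2_e = fit$sigma2_e,
                           h2 = fit$h2,
                           chain = chain_config(config$chain_iter,
                                                config$chain_burnin,
                                                seed = derive_seed(config$seed, 6L)),
                           sigma2_u_hat = fit$sigma2_a,
                           sigma2_0_hat = fit$sigma2_e)
    })
    res$prediction <- cv
    manifest$stages$predict <- list(
      accuracy = stats::setNames(as.list(cv$summary$mean_accuracy),
                                 cv$summary$method),
      k_folds = config$k_folds)
    for (i in seq_len(nrow(cv$summary)))
      say("predict: %s accuracy %.3f +/- %.3f", cv$summary$method[i],
          cv$summary$mean_accuracy[i], cv$summary$se_accuracy[i])
  }

  res$manifest <- manifest
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(res, config, out_dir)
  res
}

write_pipeline_outputs <- function(res, config, out_dir) {
  write_ped_map(res$sim$genotypes, res$sim$map, res$sim$pedigree,
                file.path(out_dir, "genotypes"))
  utils::write.csv(res$sim$traits, file.path(out_dir, "traits.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_relationship(res$G, file.path(out_dir, "grm.tsv"))
  vc <- res$varcomp
  jsonlite::write_json(list(sigma2_a = vc$sigma2_a, sigma2_cg = vc$sigma2_cg,
                            sigma2_e = vc$sigma2_e, h2 = vc$h2,
                            se_h2 = vc$se_h2),
                       file.path(out_dir, "varcomp.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(animal_id = names(res$y_star),
                              y_star = res$y_star),
                   file.path(out_dir, "y_star.csv"), row.names = FALSE)
  if (!is.null(res$gwas))
    utils::write.table(res$gwas$significant,
                       file.path(out_dir, "significant_snps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$prediction)) {
    utils::write.table(res$prediction$per_fold,
                       file.path(out_dir, "prediction_folds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$prediction$summary,
                       file.path(out_dir, "prediction_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
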