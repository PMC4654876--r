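#' Simulation configuration for synthetic genotype/phenotype data
#'
#' Builds and validates the configuration object consumed by
#' [simulate_genotypes()] and [simulate_phenotypes()].  Defaults emulate a
#' commercial beef-cattle resource population: ~1400 animals in half-sib
#' families, five breed types, four production systems, contemporary groups
#' formed as feedlot location x year, and traits controlled by a handful of
#' large-effect QTL on top of a polygenic background.
#'
#' @param n_animals number of genotyped/phenotyped animals.
#' @param n_snps number of biallelic SNPs.
#' @param n_chromosomes autosomes over which SNPs are spread evenly.
#' @param n_sires number of sires; offspring are assigned in approximately
#'   equal half-sib families.  Dams are unrecorded.
#' @param allele_freq_range range (low, high) from which founder coded-allele
#'   frequencies are drawn uniformly; must lie within (0.01, 0.99).
#' @param ld_block_size SNPs per linkage block.  Gametes copy whole founder
#'   block haplotypes, and founder allele patterns persist along a block, so
#'   pairwise dosage correlation is strong nearby and decays with map
#'   distance; `1` gives independent SNPs.
#' @param n_founder_haplotypes size of the founder haplotype pool per block.
#'   Each SNP carries exactly `round(K p)` coded alleles in the pool, so
#'   founder frequencies are quantized to multiples of `1/K`.
#' @param hap_switch_prob per-SNP probability that the founder ancestry
#'   ranking is redrawn inside a block (larger values -> faster LD decay).
#' @param missing_rate proportion of genotype calls masked as missing.
#' @param n_large_qtl number of large-effect QTL.
#' @param large_qtl_var_fraction fraction of the additive genetic variance
#'   assigned (equally) to the large QTL.
#' @param n_poly_qtl number of small-effect (polygenic background) QTL.
#' @param h2 target narrow-sense heritability, in `[0, 1)`.
#' @param cg_var_fraction fraction of (adjusted) phenotypic variance due to
#'   contemporary groups.
#' @param n_cg number of contemporary groups (default 8 = 2 locations x
#'   4 years), assigned at random.
#' @param n_breeds,n_genders,n_systems numbers of levels for the categorical
#'   fixed effects breed type, gender and production system.
#' @param fixed_effect_sd range of categorical fixed-effect magnitudes, in
#'   phenotypic standard deviations.
#' @param covariate_coefs named numeric vector of linear-covariate
#'   coefficients (age at slaughter, days slaughter-to-extraction, diet
#'   metabolic energy, marbling score), per standardized covariate unit.
#' @param seed integer seed; the whole generator is deterministic given it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_animals = 1366L,
                       n_snps = 2000L,
                       n_chromosomes = 10L,
                       n_sires = 80L,
                       allele_freq_range = c(0.1, 0.9),
                       ld_block_size = 10L,
                       n_founder_haplotypes = 20L,
                       hap_switch_prob = 0.1,
                       missing_rate = 0.0014,
                       n_large_qtl = 2L,
                       large_qtl_var_fraction = 0.3,
                       n_poly_qtl = 200L,
                       h2 = 0.35,
                       cg_var_fraction = 0.1,
                       n_cg = 8L,
                       n_breeds = 5L,
                       n_genders = 2L,
                       n_systems = 4L,
                       fixed_effect_sd = c(0.25, 1.0),
                       covariate_coefs = c(age = 0.3, days_ext = 0.15,
                                           diet_me = 0.25, marbling = 0.3),
                       seed = 1L) {
  cfg <- list(n_animals = as.integer(n_animals),
              n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              n_sires = as.integer(n_sires),
              allele_freq_range = as.numeric(allele_freq_range),
              ld_block_size = as.integer(ld_block_size),
              n_founder_haplotypes = as.integer(n_founder_haplotypes),
              hap_switch_prob = hap_switch_prob,
              missing_rate = missing_rate,
              n_large_qtl = as.integer(n_large_qtl),
              large_qtl_var_fraction = large_qtl_var_fraction,
              n_poly_qtl = as.integer(n_poly_qtl),
              h2 = h2, cg_var_fraction = cg_var_fraction,
              n_cg = as.integer(n_cg),
              n_breeds = as.integer(n_breeds),
              n_genders = as.integer(n_genders),
              n_systems = as.integer(n_systems),
              fixed_effect_sd = fixed_effect_sd,
              covariate_coefs = covariate_coefs,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  if (cfg$h2 < 0 || cfg$h2 >= 1) stop_cfg("h2 must lie in [0, 1)")
  if (cfg$cg_var_fraction < 0) stop_cfg("cg_var_fraction must be >= 0")
  if (cfg$h2 + cfg$cg_var_fraction >= 1)
    stop_cfg("h2 + cg_var_fraction must be < 1")
  if (cfg$n_large_qtl + cfg$n_poly_qtl > cfg$n_snps)
    stop_cfg("n_large_qtl + n_poly_qtl must be <= n_snps")
  fr <- cfg$allele_freq_range
  if (length(fr) != 2 || fr[1] > fr[2] || fr[1] <= 0.01 || fr[2] >= 0.99)
    stop_cfg("allele_freq_range must lie within (0.01, 0.99)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop_cfg("missing_rate must lie in [0, 1)")
  if (cfg$n_animals < 2L) stop_cfg("n_animals must be >= 2")
  if (cfg$n_sires < 1L || cfg$n_sires > cfg$n_animals)
    stop_cfg("n_sires must lie in [1, n_animals]")
  if (cfg$ld_block_size < 1L) stop_cfg("ld_block_size must be >= 1")
  if (cfg$n_large_qtl > 0L && cfg$large_qtl_var_fraction <= 0)
    stop_cfg("n_large_qtl > 0 requires large_qtl_var_fraction > 0")
  invisible(cfg)
}

# Build one block's founder-haplotype pool as a K x L 0/1 matrix.  Each SNP
# carries exactly round(K * p) copies of the coded allele, assigned to the
# haplotypes ranked lowest on a latent ancestry score; the score is redrawn
# with probability switch_prob at each SNP, so allele patterns (and hence
# pairwise LD) persist over short distances and decay with map distance.
make_founder_block <- function(K, p_block, switch_prob) {
  L <- length(p_block)
  fb <- matrix(0L, K, L)
  u <- stats::runif(K)
  for (l in seq_len(L)) {
    if (l > 1L && stats::runif(1L) < switch_prob) u <- stats::runif(K)
    cnt <- round(K * p_block[l])
    if (cnt > 0L) fb[order(u)[seq_len(cnt)], l] <- 1L
  }
  fb
}

# Draw one gamete: copy one founder haplotype per block, independently.
draw_gamete <- function(founders) {
  unlist(lapply(founders, function(fb)
    fb[sample.int(nrow(fb), 1L), ]), use.names = FALSE)
}

#' Simulate genotypes and a one-generation half-sib pedigree
#'
#' Generates an n x M dosage matrix in \{0, 1, 2\} with block-structured
#' linkage disequilibrium, a SNP map, and a pedigree in which each animal has
#' a recorded sire and an unrecorded dam.  Each offspring inherits one
#' recombined gamete from its sire and one population gamete, so paternal
#' half-sibs show the expected genomic relationship of ~0.25.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements:
#'   \describe{
#'     \item{genotypes}{n x M integer matrix of dosages, `NA` where masked
#'       missing; rownames are animal IDs, colnames SNP IDs.}
#'     \item{true_genotypes}{the same matrix before missingness masking
#'       (used internally as simulation ground truth).}
#'     \item{map}{data.frame (snp, chr, pos) with ascending 1-based
#'       positions within chromosome.}
#'     \item{pedigree}{data.frame (animal, sire, dam); dam is `NA`.}
#'   }
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_animals; M <- config$n_snps
  bs <- min(config$ld_block_size, M)
  n_blocks <- ceiling(M / bs)
  block_len <- diff(unique(pmin(seq(0L, n_blocks * bs, by = bs), M)))
  p <- stats::runif(M, config$allele_freq_range[1], config$allele_freq_range[2])

  # founder haplotype pool per block
  K <- config$n_founder_haplotypes
  offsets <- cumsum(c(0L, block_len))
  founders <- lapply(seq_along(block_len), function(b) {
    cols <- (offsets[b] + 1L):(offsets[b] + block_len[b])
    make_founder_block(K, p[cols], config$hap_switch_prob)
  })

  sires <- sprintf("S%03d", seq_len(config$n_sires))
  sire_of <- sires[1L + (seq_len(n) - 1L) %% config$n_sires]
  sire_hap <- lapply(sires, function(s)
    list(draw_gamete(founders), draw_gamete(founders)))
  names(sire_hap) <- sires

  geno <- matrix(0L, n, M)
  for (i in seq_len(n)) {
    sh <- sire_hap[[sire_of[i]]]
    # paternal gamete: per block pick one of the sire's two haplotypes
    pick <- rep(sample.int(2L, n_blocks, replace = TRUE), times = block_len)
    paternal <- ifelse(pick == 1L, sh[[1L]], sh[[2L]])
    maternal <- draw_gamete(founders)
    geno[i, ] <- paternal + maternal
  }
  ids <- sprintf("A%05d", seq_len(n))
  snps <- sprintf("snp%05d", seq_len(M))
  dimnames(geno) <- list(ids, snps)

  per_chr <- ceiling(M / config$n_chromosomes)
  chr <- 1L + (seq_len(M) - 1L) %/% per_chr
  pos <- unlist(lapply(split(seq_len(M), chr), function(ix)
    seq_len(length(ix)) * 50000L), use.names = FALSE)
  map <- data.frame(snp = snps, chr = chr, pos = pos,
                    stringsAsFactors = FALSE)

  observed <- geno
  if (config$missing_rate > 0) {
    miss <- stats::runif(n * M) < config$missing_rate
    observed[miss] <- NA_integer_
  }
  pedigree <- data.frame(animal = ids, sire = sire_of, dam = NA_character_,
                         stringsAsFactors = FALSE)
  list(genotypes = observed, true_genotypes = geno, map = map,
       pedigree = pedigree)
}

#' Simulate phenotypes with known genetic architecture
#'
#' Phenotype = intercept + fixed effects + QTL breeding value +
#' contemporary-group effect + residual.  QTL effects are rescaled so the
#' empirical variance of true breeding values equals `h2` exactly (on the
#' scale where var(TBV) + var(cg) + var(residual) targets 1); large-effect
#' QTL are sized so that each contributes its share of
#' `large_qtl_var_fraction` of the genetic variance through `2p(1-p)a^2`.
#'
#' @param sim output of [simulate_genotypes()] (the complete
#'   `true_genotypes` matrix is used for the genetic values).
#' @param config the same [sim_config()] object.
#' @return a list with elements:
#'   \describe{
#'     \item{traits}{data.frame: animal_id, sire_id, trait, breed, gender,
#'       system, age, days_ext, diet_me, marbling, cg.}
#'     \item{truth}{list: qtl_indices, qtl_effects, true_breeding_values,
#'       true_h2_realized, fixed_effect_values, cg_effects, residuals.}
#'   }
#' @export
simulate_phenotypes <- function(sim, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1000L)
  X <- sim$true_genotypes
  n <- nrow(X); M <- ncol(X)
  p <- colMeans(X) / 2

  n_qtl <- config$n_large_qtl + config$n_poly_qtl
  polymorphic <- which(p > 0.05 & p < 0.95)
  if (length(polymorphic) < n_qtl)
    stop("not enough polymorphic SNPs for the requested QTL count")
  qtl_idx <- sort(sample(polymorphic, n_qtl))
  large_idx <- if (config$n_large_qtl > 0L)
    sample(qtl_idx, config$n_large_qtl) else integer(0)
  poly_idx <- setdiff(qtl_idx, large_idx)

  effects <- numeric(M)
  effects[poly_idx] <- stats::rnorm(length(poly_idx))
  f_large <- if (config$n_large_qtl > 0L) config$large_qtl_var_fraction else 0
  # expected genetic variances under linkage equilibrium: sum 2p(1-p)a^2
  v_poly <- sum(2 * p[poly_idx] * (1 - p[poly_idx]) * effects[poly_idx]^2)
  if (length(poly_idx) > 0L && v_poly > 0) {
    v_total <- v_poly / (1 - f_large)
  } else {
    v_total <- 1
    if (f_large > 0 && f_large < 1) f_large <- 1  # all variance on large QTL
  }
  if (config$n_large_qtl > 0L) {
    v_each <- v_total * f_large / config$n_large_qtl
    a_large <- sqrt(v_each / (2 * p[large_idx] * (1 - p[large_idx])))
    effects[large_idx] <- a_large * sample(c(-1, 1), length(large_idx),
                                           replace = TRUE)
  }

  Z <- sweep(X, 2L, 2 * p)          # centered dosages
  tbv <- drop(Z %*% effects)
  v_tbv <- stats::var(tbv)
  if (config$h2 > 0 && v_tbv > 0) {
    s <- sqrt(config$h2 / v_tbv)
    effects <- effects * s
    tbv <- tbv * s
  } else {
    effects[] <- 0
    tbv[] <- 0
  }

  sigma2_cg <- config$cg_var_fraction
  sigma2_e <- 1 - config$h2 - config$cg_var_fraction
  cg <- sample.int(config$n_cg, n, replace = TRUE)
  cg_eff <- stats::rnorm(config$n_cg, 0, sqrt(sigma2_cg))
  e <- stats::rnorm(n, 0, sqrt(sigma2_e))

  sire_levels <- sort(unique(sim$pedigree$sire))
  sire_breed <- 1L + (seq_along(sire_levels) - 1L) %% config$n_breeds
  breed <- factor(paste0("B", sire_breed[match(sim$pedigree$sire, sire_levels)]),
                  levels = paste0("B", seq_len(config$n_breeds)))
  g_lev <- if (config$n_genders == 2L) c("F", "M") else
    paste0("G", seq_len(config$n_genders))
  gender <- factor(g_lev[sample.int(config$n_genders, n, replace = TRUE)],
                   levels = g_lev)
  system <- factor(paste0("P", sample.int(config$n_systems, n, replace = TRUE)),
                   levels = paste0("P", seq_len(config$n_systems)))
  rng <- config$fixed_effect_sd
  breed_eff <- stats::runif(config$n_breeds, rng[1], rng[2]) *
    sample(c(-1, 1), config$n_breeds, replace = TRUE)
  gender_eff <- stats::runif(config$n_genders, rng[1], rng[2]) *
    sample(c(-1, 1), config$n_genders, replace = TRUE)
  system_eff <- stats::runif(config$n_systems, rng[1], rng[2]) *
    sample(c(-1, 1), config$n_systems, replace = TRUE)

  age <- stats::rnorm(n)       # standardized covariates
  days_ext <- stats::rnorm(n)
  diet_me <- stats::rnorm(n)
  marbling <- stats::rnorm(n)
  cc <- config$covariate_coefs
  fixed <- breed_eff[as.integer(breed)] + gender_eff[as.integer(gender)] +
    system_eff[as.integer(system)] +
    cc[["age"]] * age + cc[["days_ext"]] * days_ext +
    cc[["diet_me"]] * diet_me + cc[["marbling"]] * marbling

  y <- 10 + fixed + tbv + cg_eff[cg] + e
  vr <- stats::var(tbv) + stats::var(cg_eff[cg]) + stats::var(e)
  truth <- list(qtl_indices = qtl_idx,
                qtl_effects = effects[qtl_idx],
                large_qtl_indices = large_idx,
                true_breeding_values = tbv,
                true_h2_realized = if (vr > 0) stats::var(tbv) / vr else 0,
                fixed_effect_values = fixed,
                cg_effects = cg_eff[cg],
                residuals = e,
                allele_freqs = p)
  traits <- data.frame(animal_id = rownames(X),
                       sire_id = sim$pedigree$sire,
                       trait = y, breed = breed, gender = gender,
                       system = system, age = age, days_ext = days_ext,
                       diet_me = diet_me, marbling = marbling,
                       cg = factor(cg), stringsAsFactors = FALSE)
  list(traits = traits, truth = truth)
}

#' Simulate a complete study data set
#'
#' Convenience wrapper running [simulate_genotypes()] then
#' [simulate_phenotypes()].
#'
#' @inheritParams simulate_genotypes
#' @return a list combining both outputs: genotypes, true_genotypes, map,
#'   pedigree, traits, truth.
#' @export
simulate_study <- function(config) {
  sim <- simulate_genotypes(config)
  ph <- simulate_phenotypes(sim, config)
  c(sim, ph)
}
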