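#' Order statistic selected as the permutation threshold
#'
#' With `n_perm` permutation maxima sorted ascending, genome-wise
#' significance at level `alpha` uses the `ceiling((1 - alpha) * n_perm)`-th
#' value (the 950th of 1000 at alpha = 0.05).
#'
#' @param n_perm number of permutations.
#' @param alpha genome-wise significance level.
#' @return the 1-based ascending rank.
#' @export
threshold_rank <- function(n_perm, alpha = 0.05) {
  stopifnot(n_perm >= 1L, alpha > 0, alpha < 1)
  as.integer(ceiling((1 - alpha) * n_perm))
}

#' Genome-wise significance threshold by phenotype permutation
#'
#' Implements the Churchill-Doerge procedure on the posterior inclusion
#' probability: adjusted phenotypes are shuffled and reassigned to animals
#' while genotypes remain intact, the sampler is rerun, and the largest PPI
#' of each permutation is recorded.  The ascending
#' `ceiling((1 - alpha) n_perm)`-th maximum is the threshold (the 950th of
#' 1000 at alpha = 0.05).
#'
#' @param y_star adjusted phenotypes.
#' @param geno complete dosage matrix.
#' @param alpha genome-wise level.
#' @param n_perm number of permutations (>= 20).
#' @param config [chain_config()] used for every permutation run; each run
#'   gets a distinct seed derived from `seed`.
#' @param seed master seed driving the shuffles and the derived chain seeds.
#' @param ... further arguments passed to [run_gibbs()] (e.g. prior
#'   anchors).
#' @return a `permutation_result`: max_ppi_per_perm, threshold, rank, alpha,
#'   n_perm.
#' @export
permutation_threshold <- function(y_star, geno, alpha = 0.05, n_perm = 1000L,
                                  config = chain_config(), seed = 1L, ...) {
  if (n_perm < 20L) stop("n_perm must be at least 20")
  rank <- threshold_rank(n_perm, alpha)
  maxima <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(seed + b)
    y_perm <- sample(y_star)
    cfg <- config
    cfg$seed <- (seed + 104729L * b) %% .Machine$integer.max
    post <- run_gibbs(y_perm, geno, cfg, ...)
    maxima[b] <- max(post$ppi)
  }
  sorted <- sort(maxima, method = "radix")  # stable ascending
  structure(list(max_ppi_per_perm = maxima, threshold = sorted[rank],
                 rank = rank, alpha = alpha, n_perm = n_perm),
            class = "permutation_result")
}

#' Percentage of additive genetic variance explained by one SNP
#'
#' `100 * 2 p (1 - p) a^2 / sigma2_u_hat`, with `a` the (posterior-mean)
#' allele substitution effect and `sigma2_u_hat` the REML additive genetic
#' variance of the trait.
#'
#' @param effect_mean allele substitution effect.
#' @param allele_freq coded-allele frequency `p`.
#' @param sigma2_u_hat additive genetic variance (> 0).
#' @return percentage (vectorized over SNPs).
#' @export
variance_explained <- function(effect_mean, allele_freq, sigma2_u_hat) {
  if (any(sigma2_u_hat <= 0))
    stop("variance explained undefined: additive genetic variance is zero")
  100 * 2 * allele_freq * (1 - allele_freq) * effect_mean^2 / sigma2_u_hat
}

#' Report genome-wise significant SNPs with candidate windows
#'
#' SNPs whose PPI reaches the threshold, with allele substitution effect,
#' PPI and percentage of genetic variance explained; optionally joined to
#' annotation features overlapping a 1-Mb window centered on each SNP.
#'
#' @param posterior a `posterior_summary` from [run_gibbs()].
#' @param map SNP map (snp, chr, pos) aligned with the posterior.
#' @param threshold PPI threshold in `[0, 1]` (values above 1 simply yield
#'   an empty report).
#' @param sigma2_u_hat additive genetic variance for the
#'   variance-explained column.
#' @param annotation optional annotation data.frame (chr, start, end, name;
#'   1-based inclusive coordinates) as returned by [read_annotation()].
#' @param window_bp total window width: features whose interval overlaps
#'   `[pos - window_bp/2, pos + window_bp/2]` on the same chromosome are
#'   reported (default 1 Mb).
#' @return data.frame: snp, chr, pos, effect_mean, ppi,
#'   pct_genetic_variance, genes (comma-separated or NA).
#' @export
report_significant <- function(posterior, map, threshold,
                               sigma2_u_hat = NULL, annotation = NULL,
                               window_bp = 1e6) {
  stopifnot(threshold >= 0)
  hit <- which(posterior$ppi >= threshold)
  out <- data.frame(snp = map$snp[hit], chr = map$chr[hit],
                    pos = map$pos[hit],
                    effect_mean = posterior$effect_mean[hit],
                    ppi = posterior$ppi[hit],
                    stringsAsFactors = FALSE)
  out$pct_genetic_variance <- if (!is.null(sigma2_u_hat) && length(hit) > 0)
    variance_explained(posterior$effect_mean[hit],
                       posterior$allele_freqs[hit], sigma2_u_hat)
  else rep(NA_real_, length(hit))
  out$genes <- rep(NA_character_, length(hit))
  if (!is.null(annotation) && length(hit) > 0) {
    half <- window_bp / 2
    for (k in seq_along(hit)) {
      lo <- out$pos[k] - half
      hi <- out$pos[k] + half
      ov <- annotation$chr == out$chr[k] &
        annotation$start <= hi & annotation$end >= lo
      if (any(ov)) out$genes[k] <- paste(annotation$name[ov], collapse = ",")
    }
  }
  out[order(out$chr, out$pos), , drop = FALSE]
}

#' Read a feature annotation from BED or GFF3
#'
#' Parses the file with `rtracklayer` and returns 1-based inclusive
#' intervals (BED's 0-based half-open coordinates are converted).
#'
#' @param path path to a `.bed`, `.gff`/`.gff3` file.
#' @param feature_type optional GFF3 type filter (e.g. "gene").
#' @return data.frame (chr, start, end, name).
#' @export
read_annotation <- function(path, feature_type = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading BED/GFF3 annotation requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (!is.null(feature_type) && "type" %in% names(df))
    df <- df[df$type %in% feature_type, , drop = FALSE]
  nm <- if ("Name" %in% names(df)) df$Name
        else if ("name" %in% names(df)) df$name
        else if ("ID" %in% names(df)) df$ID
        else paste0("feature", seq_len(nrow(df)))
  out <- data.frame(chr = as.character(df$seqnames),
                    start = df$start, end = df$end,
                    name = as.character(nm), stringsAsFactors = FALSE)
  if (any(out$end < out$start)) stop("annotation has end < start coordinates")
  out
}

#' Manhattan-style plot of posterior inclusion probabilities
#'
#' Genome-wide PPI against cumulative position, chromosomes alternating
#' color, with a horizontal line at the permutation threshold.
#'
#' @param posterior a `posterior_summary`.
#' @param map SNP map aligned with the posterior.
#' @param threshold optional genome-wise threshold drawn as a dashed line.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot_ppi <- function(posterior, map, threshold = NULL, ...) {
  chr_off <- c(0, cumsum(tapply(map$pos, map$chr, max)))
  x <- map$pos + chr_off[match(map$chr, sort(unique(map$chr)))]
  col <- c("grey30", "steelblue")[1 + map$chr %% 2]
  graphics::plot(x, posterior$ppi, pch = 20, col = col,
                 xlab = "genome position", ylab = "posterior inclusion probability",
                 ylim = c(0, 1), ...)
  if (!is.null(threshold))
    graphics::abline(h = threshold, lty = 2, col = "red")
  invisible(NULL)
}
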