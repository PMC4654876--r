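#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / sum_j 2 p_j (1 - p_j)` with `Z = X - 2p` the
#' allele-frequency-centered dosage matrix and `p_j` the coded-allele
#' frequency observed in the analyzed sample.  With sample frequencies the
#' rows of G sum to zero exactly, and the mean diagonal is close to 1 for a
#' sample in Hardy-Weinberg proportions.
#'
#' @param geno complete n x M dosage matrix (no missing values; impute
#'   first), rownames taken as animal IDs.
#' @param allele_freqs optional vector of coded-allele frequencies; defaults
#'   to the observed column means / 2.
#' @return a `relationship_matrix` object: list(values, kind = "genomic",
#'   animal_ids).
#' @export
grm_vanraden1 <- function(geno, allele_freqs = NULL) {
  if (anyNA(geno)) stop("genotype matrix contains missing values; impute first")
  p <- if (is.null(allele_freqs)) colMeans(geno) / 2 else allele_freqs
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0)
    stop("all SNPs monomorphic: VanRaden denominator sum 2p(1-p) is zero")
  Z <- sweep(geno, 2L, 2 * p)
  G <- tcrossprod(Z) / denom
  ids <- rownames(geno)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(geno)))
  dimnames(G) <- list(ids, ids)
  structure(list(values = G, kind = "genomic", animal_ids = ids),
            class = "relationship_matrix")
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' method.  Unknown parents are treated as unrelated non-inbred founders.
#' With a one-generation pedigree (recorded sires, unrecorded dams) paternal
#' half-sibs get a_ij = 0.25 and parent-offspring 0.5.
#'
#' @param pedigree data.frame with columns animal, sire, dam (IDs or `NA`).
#'   Parents that never appear as animals are added as founders.
#' @return a `relationship_matrix` object (`kind = "pedigree"`) ordered
#'   parents-first over all animals including added founders; use
#'   [subset_relationship()] to restrict/reorder to the phenotyped set.
#' @export
a_matrix <- function(pedigree) {
  ped <- data.frame(animal = as.character(pedigree$animal),
                    sire = as.character(pedigree$sire),
                    dam = as.character(pedigree$dam),
                    stringsAsFactors = FALSE)
  if (any(!is.na(ped$sire) & ped$sire == ped$animal) ||
      any(!is.na(ped$dam) & ped$dam == ped$animal))
    stop("cyclic pedigree: an animal is its own parent")
  founders <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$animal)
  if (length(founders) > 0L)
    ped <- rbind(data.frame(animal = founders, sire = NA_character_,
                            dam = NA_character_, stringsAsFactors = FALSE),
                 ped)
  ids <- ped$animal
  if (anyDuplicated(ids)) stop("duplicated animal IDs in pedigree")
  ord <- order_pedigree(ped)
  ped <- ped[ord, , drop = FALSE]
  ids <- ped$animal
  n <- length(ids)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) +
                    (if (!is.na(d)) A[j, d] else 0))
      A[i, j] <- aij
      A[j, i] <- aij
    }
  }
  structure(list(values = A, kind = "pedigree", animal_ids = ids),
            class = "relationship_matrix")
}

# topological sort: parents before offspring; error on cycles
order_pedigree <- function(ped) {
  n <- nrow(ped)
  ids <- ped$animal
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed & vapply(seq_len(n), function(i) {
      (is.na(si[i]) || placed[si[i]]) && (is.na(di[i]) || placed[di[i]])
    }, logical(1)))
    if (length(ready) == 0L) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) < n) stop("cyclic pedigree: no valid parent ordering exists")
  ord
}

#' Subset a relationship matrix to a set of animals
#'
#' @param rel a `relationship_matrix`.
#' @param ids animal IDs to keep, in the requested order.
#' @return a `relationship_matrix` over `ids`.
#' @export
subset_relationship <- function(rel, ids) {
  missing <- setdiff(ids, rel$animal_ids)
  if (length(missing) > 0L)
    stop("animals absent from relationship matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  V <- rel$values[ids, ids, drop = FALSE]
  structure(list(values = V, kind = rel$kind, animal_ids = ids),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("%s relationship matrix: %d animals, mean diagonal %.3f\n",
              x$kind, length(x$animal_ids), mean(diag(x$values))))
  invisible(x)
}
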