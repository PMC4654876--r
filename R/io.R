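#' Write genotypes as PLINK-style .ped/.map text files
#'
#' Dosages are expanded to two-letter genotypes (A = reference allele,
#' B = coded allele, so dosage counts B); missing calls become `0 0`.
#' The .map file has columns chromosome, SNP ID, genetic distance (0) and
#' physical position.
#'
#' @param geno n x M dosage matrix (`NA` = missing), rows named by animal.
#' @param map SNP map (snp, chr, pos).
#' @param pedigree data.frame (animal, sire, dam) supplying parent columns.
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return invisibly, the two file paths.
#' @export
write_ped_map <- function(geno, map, pedigree, prefix) {
  stopifnot(ncol(geno) == nrow(map))
  alleles <- c("A A", "A B", "B B")
  gchar <- matrix("0 0", nrow(geno), ncol(geno))
  ok <- !is.na(geno)
  gchar[ok] <- alleles[geno[ok] + 1L]
  sire <- pedigree$sire[match(rownames(geno), pedigree$animal)]
  sire[is.na(sire)] <- "0"
  lines <- paste("FAM", rownames(geno), sire, "0", "0", "-9",
                 apply(gchar, 1L, paste, collapse = " "))
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  writeLines(lines, ped_path)
  utils::write.table(data.frame(map$chr, map$snp, 0L, map$pos),
                     map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read PLINK-style .ped/.map text files into a dosage matrix
#'
#' Counts copies of the `B` allele per genotype; `0 0` becomes `NA`.
#'
#' @param prefix path prefix of the `.ped` / `.map` pair.
#' @return list(genotypes, map, pedigree) matching the
#'   [simulate_genotypes()] layout.
#' @export
read_ped_map <- function(prefix) {
  map_raw <- utils::read.table(paste0(prefix, ".map"),
                               col.names = c("chr", "snp", "cm", "pos"),
                               stringsAsFactors = FALSE)
  map <- data.frame(snp = map_raw$snp, chr = map_raw$chr, pos = map_raw$pos,
                    stringsAsFactors = FALSE)
  ped_raw <- utils::read.table(paste0(prefix, ".ped"),
                               stringsAsFactors = FALSE)
  M <- nrow(map)
  stopifnot(ncol(ped_raw) == 6L + 2L * M)
  ids <- as.character(ped_raw[[2L]])
  al <- as.matrix(ped_raw[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1L, 2L * M, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * M, by = 2L), drop = FALSE]
  geno <- (a1 == "B") + (a2 == "B")
  geno[a1 == "0" | a2 == "0"] <- NA_integer_
  dimnames(geno) <- list(ids, map$snp)
  sire <- as.character(ped_raw[[3L]])
  sire[sire == "0"] <- NA_character_
  pedigree <- data.frame(animal = ids, sire = sire, dam = NA_character_,
                         stringsAsFactors = FALSE)
  list(genotypes = geno, map = map, pedigree = pedigree)
}

#' Write a relationship matrix as TSV with an animal-ID header
#'
#' @param rel a `relationship_matrix`.
#' @param path output path.
#' @export
write_relationship <- function(rel, path) {
  utils::write.table(rel$values, path, quote = FALSE, sep = "\t",
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a relationship matrix TSV written by [write_relationship()]
#'
#' @param path input path.
#' @param kind `"genomic"` or `"pedigree"`.
#' @return a `relationship_matrix`.
#' @export
read_relationship <- function(path, kind = "genomic") {
  m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1L,
                                   sep = "\t", check.names = FALSE))
  structure(list(values = m, kind = kind, animal_ids = rownames(m)),
            class = "relationship_matrix")
}
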