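# Plain-text readers and writers for the pipeline's data formats. All files
# are tab-delimited with a header row unless stated otherwise.

#' Read a pedigree file
#'
#' Expects columns `id`, `sire`, `dam` ("0" or empty = unknown parent), in
#' an order where parents precede offspring.
#'
#' @param path TSV file.
#' @return an [pedigree()].
#' @export
read_pedigree_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character")
  pedigree(d$id, d$sire, d$dam,
           sex = if ("sex" %in% names(d)) d$sex else NULL)
}

#' Read a litter record table
#'
#' Expects columns `sow`, `parity`, `hys`, `tnb`.
#'
#' @param path TSV file.
#' @return data.frame of records.
#' @export
read_records_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  req <- c("sow", "parity", "hys", "tnb")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  d$sow <- as.character(d$sow)
  d
}

#' Read genotypes from a dosage matrix TSV plus map TSV
#'
#' The dosage file has one row per animal (first column `id`) and one
#' column per SNP with 0/1/2/NA entries; the map file has `snp`, `chrom`,
#' `pos_bp`.
#'
#' @param geno_path,map_path file paths.
#' @return `lv_genotypes`.
#' @export
read_genotypes_tsv <- function(geno_path, map_path) {
  d <- utils::read.table(geno_path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  genotypes(m, map)
}

#' Read genotypes from a PLINK-style .ped/.map pair
#'
#' Text formats only: the .map has 4 columns (chrom, snp, cM, bp); the .ped
#' has 6 leading columns (family, id, sire, dam, sex, phenotype) followed
#' by two allele columns per SNP (A/C/G/T or 0 for missing). Dosages count
#' the alphabetically later allele at each SNP.
#'
#' @param ped_path,map_path file paths.
#' @return `lv_genotypes`.
#' @export
read_genotypes_ped <- function(ped_path, map_path) {
  map0 <- utils::read.table(map_path, header = FALSE, sep = "",
                            stringsAsFactors = FALSE)
  names(map0)[1:4] <- c("chrom", "snp", "cm", "pos_bp")
  ped <- utils::read.table(ped_path, header = FALSE, sep = "",
                           colClasses = "character")
  m <- nrow(map0)
  stopifnot(ncol(ped) == 6 + 2 * m)
  ids <- ped[[2]]
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  geno <- matrix(NA_integer_, nrow(ped), m)
  for (j in seq_len(m)) {
    alleles <- sort(setdiff(unique(c(a1[, j], a2[, j])), "0"))
    counted <- alleles[length(alleles)]
    ok <- a1[, j] != "0" & a2[, j] != "0"
    geno[ok, j] <- (a1[ok, j] == counted) + (a2[ok, j] == counted)
  }
  rownames(geno) <- ids
  genotypes(geno, data.frame(snp = map0$snp, chrom = map0$chrom,
                             pos_bp = map0$pos_bp))
}

#' Write a GWAS result table
#'
#' Columns mirror the usual mixed-linear-model association layout
#' (Chr, SNP, bp, freq, b, se, p) plus the variance-explained columns.
#'
#' @param results `lv_gwas` table.
#' @param path output TSV.
#' @export
write_gwas_results <- function(results, path) {
  out <- data.frame(Chr = results$chrom, SNP = results$snp,
                    bp = results$pos_bp, freq = results$freq,
                    b = results$beta, se = results$se, p = results$p,
                    sigma2_snp = results$sigma2_snp,
                    share_genetic = results$share_genetic,
                    share_phenotypic = results$share_phenotypic,
                    class = results$class)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
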