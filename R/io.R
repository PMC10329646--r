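#' Write / read the package's file dialects
#'
#' Plain-text interchange formats: dosage TSV (variants x samples), protein
#' TSV (samples x aptamers), covariate TSV, GWAS summary TSV (SNP, CHR,
#' POS, A1, A2, FREQ, BETA, SE, P, N), minimal GT-only VCF v4.2, and a
#' truth-ledger JSON.
#'
#' @name proteopheno-io
NULL

#' @rdname proteopheno-io
#' @param genotypes a \code{genotype_matrix}.
#' @param path output file path.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  m <- t(genotypes$dosage)                    # variants x samples
  df <- cbind(genotypes$variants[, c("id", "chrom", "pos", "ref", "alt")],
              as.data.frame(m, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname proteopheno-io
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = NA)
  meta <- df[, c("id", "chrom", "pos", "ref", "alt")]
  meta$chrom <- as.character(meta$chrom)
  dos <- t(as.matrix(df[, setdiff(names(df), names(meta)), drop = FALSE]))
  colnames(dos) <- meta$id
  storage.mode(dos) <- "integer"
  meta$maf <- NA_real_
  meta$block <- NA_integer_
  structure(list(dosage = dos, variants = meta,
                 samples = data.frame(sample_id = rownames(dos),
                                      cohort = NA_character_,
                                      stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' @rdname proteopheno-io
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_codes[genotypes$dosage + 1L], nrow = nrow(genotypes$dosage))
  gt[is.na(genotypes$dosage)] <- "./."
  body <- cbind(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                t(gt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(genotypes$dosage)),
                     collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname proteopheno-io
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")        # variants x samples
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  fix <- vcfR::getFIX(v)
  dos <- t(dos)
  colnames(dos) <- fix[, "ID"]
  structure(list(
    dosage = dos,
    variants = data.frame(id = fix[, "ID"], chrom = as.character(fix[, "CHROM"]),
                          pos = as.numeric(fix[, "POS"]), ref = fix[, "REF"],
                          alt = fix[, "ALT"], maf = NA_real_,
                          block = NA_integer_, stringsAsFactors = FALSE),
    samples = data.frame(sample_id = rownames(dos), cohort = NA_character_,
                         stringsAsFactors = FALSE)
  ), class = "genotype_matrix")
}

#' @rdname proteopheno-io
#' @param m samples x aptamers matrix.
#' @export
write_protein_tsv <- function(m, path) {
  df <- cbind(data.frame(sample_id = rownames(m), stringsAsFactors = FALSE),
              as.data.frame(m, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname proteopheno-io
#' @export
read_protein_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  m
}

#' @rdname proteopheno-io
#' @param gwas GWAS summary data.frame.
#' @export
write_gwas_tsv <- function(gwas, path) {
  utils::write.table(gwas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname proteopheno-io
#' @export
read_gwas_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  df$CHR <- as.character(df$CHR)
  df
}

#' @rdname proteopheno-io
#' @param truth a \code{truth_ledger}.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname proteopheno-io
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "truth_ledger")
}
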