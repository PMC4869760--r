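## plain-text interchange formats: genotype TSV (lines x markers, codes
## -1/0/1, NA missing), kinship CSV, and a minimal unphased biallelic VCF.

#' Read and write the genotype TSV dialect
#'
#' The TSV has a `line` id column followed by one column per marker with
#' codes -1/0/1 and `NA` for missing calls.
#'
#' @param path File path.
#' @return `read_genotypes_tsv()` returns a [marker_matrix()].
#' @export
read_genotypes_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "line") stop("expected first column 'line'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$line
  marker_matrix(m)
}

#' Read and write a kinship matrix as square CSV
#'
#' @param K A `kinship_matrix` (or square matrix with line-id dimnames).
#' @param path File path.
#' @return `read_kinship_csv()` returns a `kinship_matrix`.
#' @export
write_kinship_csv <- function(K, path) {
  df <- data.frame(line = rownames(K), as.data.frame(unclass(K)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kinship_csv
#' @export
read_kinship_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df$line
  structure(K, class = c("kinship_matrix", class(matrix())))
}

#' Write genotypes as a minimal VCF
#'
#' Emits a VCF 4.2 file with unphased GT calls on a dummy chromosome, mapping
#' codes -1/0/+1 to 0/0, 0/1, 1/1 and missing to ./.. Continuous (imputed)
#' codes are rounded to the nearest hard call first.
#'
#' @param geno A [marker_matrix()].
#' @param path Output path (plain text).
#' @return The path, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path) {
  X <- round(unclass(geno))
  gt <- matrix("./.", nrow(X), ncol(X))
  gt[!is.na(X) & X == -1] <- "0/0"
  gt[!is.na(X) & X == 0] <- "0/1"
  gt[!is.na(X) & X == 1] <- "1/1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(X)), collapse = "\t")), con)
  for (k in seq_len(ncol(X))) {
    writeLines(paste(c("1", k, colnames(X)[k], "A", "T", ".", "PASS", ".",
                       "GT", gt[, k]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Biallelic records are mapped GT 0/0 -> -1, 0/1 or 1/0 -> 0, 1/1 -> +1 and
#' ./. -> missing; multiallelic records are skipped with a warning. Requires
#' the suggested package \pkg{vcfR}.
#'
#' @param path Path to a VCF file.
#' @return A [marker_matrix()] (lines x markers).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning(sum(multi), " multiallelic records skipped")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  norm <- gsub("\\|", "/", gt)
  code[norm %in% c("0/0")] <- -1
  code[norm %in% c("0/1", "1/0")] <- 0
  code[norm %in% c("1/1")] <- 1
  ids <- vcfR::getID(v)
  ids[is.na(ids) | ids == "."] <- paste0("var", which(is.na(ids) | ids == "."))
  rownames(code) <- ids
  marker_matrix(t(code))
}
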