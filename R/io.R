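# Plain-text input/output: genotype and phenotype TSV, optional VCF import.

#' Write / read a genotype matrix as TSV
#'
#' The layout is variants as rows (columns `id`, `chrom`, `pos`, then one
#' column per sample holding the 0/1/2 dosage), the transposed-dosage
#' convention most scan tooling expects.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output file.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  tab <- cbind(genotypes$map[, c("id", "chrom", "pos")],
               as.data.frame(t(genotypes$dosages)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @param cross Optional per-sample cross labels to attach on read.
#' @export
read_genotypes_tsv <- function(path, cross = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  meta <- tab[, c("id", "chrom", "pos")]
  dos <- t(as.matrix(tab[, setdiff(names(tab), c("id", "chrom", "pos"))]))
  colnames(dos) <- meta$id
  genotype_matrix(dos, meta, cross = cross)
}

#' Write / read a phenotype table as TSV
#'
#' @param pheno A `phenotype_table`.
#' @param path Output file.
#' @export
write_phenotypes_tsv <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Import genotypes from a VCF file
#'
#' Converts the GT field of a VCF into a dosage `genotype_matrix` (alternate
#' allele copies). Requires the `vcfR` package; multi-allelic sites and
#' missing genotypes are dropped with a message.
#'
#' @param path VCF file (plain or bgzipped).
#' @return A `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_config("VCF import requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  dos <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_integer_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]))
  })
  keep <- stats::complete.cases(dos) & apply(dos, 1, function(r) all(r %in% 0:2))
  if (any(!keep)) {
    message("read_genotypes_vcf: dropping ", sum(!keep),
            " multi-allelic or incomplete site(s)")
  }
  fix <- vcfR::getFIX(v)
  map <- data.frame(id = ifelse(is.na(fix[keep, "ID"]) | fix[keep, "ID"] == ".",
                                paste0(fix[keep, "CHROM"], "_", fix[keep, "POS"]),
                                fix[keep, "ID"]),
                    chrom = fix[keep, "CHROM"],
                    pos = as.integer(fix[keep, "POS"]),
                    stringsAsFactors = FALSE)
  genotype_matrix(t(dos[keep, , drop = FALSE]), map)
}

#' Write a scan result as Manhattan-plot-compatible TSV
#'
#' Columns `CHR`, `BP`, `P` plus the remaining scan fields.
#'
#' @param scan A `scan_result`.
#' @param path Output file.
#' @export
write_scan_tsv <- function(scan, path) {
  out <- data.frame(CHR = scan$chrom, BP = scan$pos, P = scan$p,
                    SNP = scan$id, CHI2 = scan$chi2,
                    BETA_G = scan$beta_g, BETA_D = scan$beta_d,
                    FLAG = scan$flag)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
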