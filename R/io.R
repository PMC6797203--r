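## Readers and writers for the study's file dialects.
##
## Phenotypes: long-format delimited text with header family, env, rep,
## value (comma or tab, auto-detected). Genotypes: families x markers
## table, first column = family ID, header = "chrN_pos" marker IDs, codes
## -1/0/1 with "NA" as the missing sentinel (+1 = homozygous recurrent
## parent PH4CV, -1 = homozygous donor Zheng58). VCF import/export encodes
## the same codes in GT (unphased; missing = "./."), counting
## recurrent-parent (REF) alleles.

detectDelim <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (lengths(regmatches(hdr, gregexpr("\t", hdr))) > 0) "\t" else ","
}

#' Read a long-format phenotype file
#'
#' @param path delimited text file with header columns family, env, rep,
#'   value (comma- or tab-separated, auto-detected). Empty cells are
#'   treated as missing and dropped.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
readPhenotypes <- function(path) {
  d <- read.table(path, header = TRUE, sep = detectDelim(path),
    stringsAsFactors = FALSE, colClasses = "character")
  names(d) <- tolower(names(d))
  need <- c("family", "env", "rep", "value")
  if (!all(need %in% names(d)))
    stop("phenotype file needs header columns family, env, rep, value")
  d <- d[, need]
  d$value[d$value == ""] <- NA
  vals <- suppressWarnings(as.numeric(d$value))
  bad <- which(!is.na(d$value) & is.na(vals))
  if (length(bad))
    stop(sprintf("non-numeric trait value at data row %d: '%s'",
      bad[1], d$value[bad[1]]))
  d$value <- vals
  d <- d[!is.na(d$value), , drop = FALSE]
  PhenotypeTable(d)
}

#' Write a phenotype table as CSV
#'
#' @param pheno a \linkS4class{PhenotypeTable}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writePhenotypes <- function(pheno, path) {
  write.table(phenoRecords(pheno), path, sep = ",", row.names = FALSE,
    quote = FALSE)
  invisible(path)
}

#' Read a families-by-markers genotype file
#'
#' @param path delimited text (comma or tab, auto-detected): first column
#'   family IDs, remaining header entries "chrN_pos" marker IDs, codes
#'   -1/0/1 with NA for missing.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readGenotypes <- function(path) {
  d <- read.table(path, header = TRUE, sep = detectDelim(path),
    stringsAsFactors = FALSE, check.names = FALSE)
  fam <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- fam
  bad <- which(!is.na(m) & !(m %in% c(-1, 0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(m))
    stop(sprintf("invalid genotype code %s at row %s, marker %s",
      m[bad[1]], fam[rc[1]], colnames(m)[rc[2]]))
  }
  GenotypeMatrix(m)
}

#' Write a genotype matrix as TSV
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param path output path; missing codes are written as NA.
#' @return Invisibly, the path.
#' @export
writeGenotypes <- function(G, path) {
  m <- genotypeCodes(G)
  d <- data.frame(family = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import genotypes from a VCF file
#'
#' GT fields are converted to -1/0/+1 by counting REF (recurrent-parent)
#' alleles: 0/0 -> +1, 0/1 -> 0, 1/1 -> -1, ./. -> NA. Marker IDs are
#' rebuilt as "chr<CHROM>_<POS>".
#'
#' @param path VCF path (requires the vcfR package).
#' @return A \linkS4class{GenotypeMatrix} (samples as rows).
#' @export
readGenotypesVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF import requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_real_, length(g))
    out[g == "0/0"] <- 1
    out[g %in% c("0/1", "1/0")] <- 0
    out[g == "1/1"] <- -1
    out
  }
  m <- t(matrix(code(gt), nrow(gt), ncol(gt), dimnames = dimnames(gt)))
  colnames(m) <- sprintf("chr%s_%s", sub("^[Cc]hr", "", fix[, "CHROM"]),
    fix[, "POS"])
  GenotypeMatrix(m)
}

#' Export a genotype matrix as an uncompressed VCF
#'
#' Inverse of \code{\link{readGenotypesVcf}}: +1 -> 0/0, 0 -> 0/1,
#' -1 -> 1/1, NA -> "./." (unphased). REF/ALT are written as the
#' recurrent- and donor-parent alleles A/B.
#'
#' @param G a raw-coded \linkS4class{GenotypeMatrix}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeGenotypesVcf <- function(G, path) {
  m <- genotypeCodes(G)
  if (G@imputed) stop("VCF export needs raw -1/0/1 codes")
  info <- markerInfo(G)
  gtChar <- matrix("./.", nrow(m), ncol(m))
  gtChar[!is.na(m) & m == 1] <- "0/0"
  gtChar[!is.na(m) & m == 0] <- "0/1"
  gtChar[!is.na(m) & m == -1] <- "1/1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", rownames(m)), collapse = "\t")), con)
  body <- vapply(seq_len(ncol(m)), function(j) {
    paste(c(info$chr[j], format(info$pos[j], scientific = FALSE),
      colnames(m)[j], "A", "B", ".", "PASS", ".", "GT", gtChar[, j]),
      collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}
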