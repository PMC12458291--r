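#' Write a genotype matrix as an all-sites VCF
#'
#' Emits VCF v4.2 with one record per site, invariant records included
#' (ALT "."). Diploid genotypes are written `0/0`, `0/1`, `1/1` or `./.`;
#' haploid genotypes `0`, `1` or `.`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (plain-text `.vcf`).
#' @param source_tag value of the `##source` header line.
#' @return `path`, invisibly.
#' @export
write_allsites_vcf <- function(gm, path, source_tag = "divergescan") {
  if (anyDuplicated(gm$samples)) stop("sample names must be unique")
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  lens <- tapply(gm$sites$pos, gm$sites$chrom, max)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=", source_tag),
    if (length(lens))
      sprintf("##contig=<ID=%s,length=%d>", names(lens), as.integer(lens)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"))
  writeLines(header, con)
  if (nrow(gm$sites) > 0) {
    if (gm$ploidy == 2L) {
      gt <- matrix(paste(gm$a1, gm$a2, sep = "/"), nrow = nrow(gm$a1))
      gt[is.na(gm$a1)] <- "./."
    } else {
      gt <- matrix(as.character(gm$a1), nrow = nrow(gm$a1))
      gt[is.na(gm$a1)] <- "."
    }
    alt <- ifelse(is.na(gm$sites$alt), ".", gm$sites$alt)
    fixed <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, alt,
                   ".", "PASS", ".", "GT", sep = "\t")
    writeLines(paste(fixed, apply(gt, 1, paste, collapse = "\t"), sep = "\t"),
               con)
  }
  invisible(path)
}

#' Read an all-sites VCF into a genotype matrix
#'
#' Parsing is delegated to `vcfR`; this function converts the parsed
#' records into the package's [genotype_matrix()], keeping invariant
#' records (ALT ".") and the written allele order of heterozygotes.
#' Phased separators (`|`) are accepted and treated like `/`.
#'
#' @param path a VCF file (plain or gzipped).
#' @param ploidy 1 or 2; must match the GT fields in the file.
#' @return A [genotype_matrix()].
#' @export
read_allsites_vcf <- function(path, ploidy = 2L) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  alt <- fix[, "ALT"]
  alt[alt %in% c(".", "")] <- NA_character_
  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = alt, stringsAsFactors = FALSE)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  if (ploidy == 2L) {
    a1 <- suppressWarnings(matrix(as.integer(sub("/.*", "", gt)), nrow = nrow(gt)))
    a2 <- suppressWarnings(matrix(as.integer(sub(".*/", "", gt)), nrow = nrow(gt)))
    a1[is.na(a2)] <- NA_integer_; a2[is.na(a1)] <- NA_integer_
    genotype_matrix(sites, a1, a2, samples = colnames(gt), ploidy = 2L)
  } else {
    a1 <- suppressWarnings(matrix(as.integer(gt), nrow = nrow(gt)))
    genotype_matrix(sites, a1, NULL, samples = colnames(gt), ploidy = 1L)
  }
}

#' Read a BED file of intervals
#'
#' @param path BED path (0-based half-open; first three columns used, an
#'   optional fourth is kept as `name`).
#' @return data.frame `chrom`, `start`, `end`[, `name`].
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  names(bed) <- c("chrom", "start", "end", "name")[seq_len(min(4, ncol(bed)))]
  bed[seq_len(min(4, ncol(bed)))]
}
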