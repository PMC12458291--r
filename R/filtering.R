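#' Site and sample filters
#'
#' These reproduce the hard filters a divergence-scan pipeline applies
#' between variant calling and statistics: biallelic-SNP retention,
#' per-sample then per-site missingness thresholds, a minimum ALT-allele
#' occurrence count for CNV callsets, and Y-chromosome haploidization.
#' GATK-style variant-quality hard filters are assumed pre-applied
#' upstream and are not re-implemented.
#'
#' @name filters
NULL

filter_report <- function(sites_in, sites_out, samples_removed = character(),
                          tallies = c()) {
  structure(list(sites_in = sites_in, sites_out = sites_out,
                 samples_removed = samples_removed, tallies = tallies),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d sites in, %d out (%d removed)",
              x$sites_in, x$sites_out, x$sites_in - x$sites_out))
  if (length(x$samples_removed))
    cat(sprintf("; samples removed: %s",
                paste(x$samples_removed, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Retain biallelic SNP records (invariant records pass through)
#'
#' Variant records whose REF or ALT is not a single nucleotide, or which
#' carry more than one ALT allele, are removed. Invariant records (no ALT)
#' are retained untouched: they carry the pi/dXY denominators.
#'
#' @param gm a [genotype_matrix()].
#' @return list with `gm` (filtered) and `report` (a `filter_report`).
#' @export
filter_biallelic_snps <- function(gm) {
  s <- gm$sites
  invariant <- is.na(s$alt)
  snp_ok <- !invariant &
    nchar(s$ref) == 1 & s$ref %in% c("A", "C", "G", "T") &
    nchar(s$alt) == 1 & s$alt %in% c("A", "C", "G", "T") &
    !grepl(",", s$alt)
  keep <- invariant | snp_ok
  list(gm = gm_subset(gm, sites = keep),
       report = filter_report(nrow(s), sum(keep),
                              tallies = c(non_biallelic_snp = sum(!keep))))
}

#' Drop high-missingness samples, then incomplete sites
#'
#' Two-stage filter with a fixed order: samples whose fraction of missing
#' calls over variant sites exceeds `max_sample_missing` are removed first;
#' then sites whose called fraction among the remaining samples falls below
#' `min_site_completeness` are removed. The site stage applies to variant
#' sites; invariant records are subjected to the same completeness rule so
#' that downstream denominators stay honest.
#'
#' @param gm a [genotype_matrix()].
#' @param max_sample_missing per-sample missingness threshold (default 0.1,
#'   strictly-greater removal).
#' @param min_site_completeness minimum called fraction per site
#'   (default 0.95; sites strictly below are dropped).
#' @return list with `gm` and `report`.
#' @export
apply_missingness_filters <- function(gm, max_sample_missing = 0.1,
                                      min_site_completeness = 0.95) {
  stopifnot(max_sample_missing >= 0, max_sample_missing <= 1,
            min_site_completeness >= 0, min_site_completeness <= 1)
  var_rows <- is_variant(gm)
  miss <- is.na(gm$a1)
  # sample missingness over variant sites only: invariant records in real
  # all-sites VCFs are often sparsely genotyped and would dominate the rate
  samp_miss <- if (any(var_rows))
    colMeans(miss[var_rows, , drop = FALSE]) else rep(0, ncol(miss))
  drop_samples <- gm$samples[samp_miss > max_sample_missing]
  if (length(drop_samples) == length(gm$samples))
    stop("all samples exceed the missingness threshold")
  gm2 <- gm_subset(gm, samples = setdiff(gm$samples, drop_samples))
  called_frac <- rowMeans(!is.na(gm2$a1))
  keep_sites <- called_frac >= min_site_completeness
  list(gm = gm_subset(gm2, sites = keep_sites),
       report = filter_report(nrow(gm$sites), sum(keep_sites),
                              samples_removed = drop_samples,
                              tallies = c(low_completeness = sum(!keep_sites))))
}

#' Require a minimum ALT-allele occurrence count in a CNV callset
#'
#' A CNV record is retained only when its ALT (carrier) allele occurs at
#' least `min_count` times summed across all samples — the `--non-ref-ac`
#' convention. Heterozygous carriers contribute 1, homozygous carriers 2.
#'
#' @param callset a [cnv_callset()] with genotypes.
#' @param min_count minimum total ALT allele count (default 8).
#' @return filtered [cnv_callset()].
#' @export
enforce_min_alt_occurrences <- function(callset, min_count = 8L) {
  if (is.null(callset$genotypes)) stop("callset has no genotypes")
  ac <- rowSums(callset$genotypes, na.rm = TRUE)
  keep <- ac >= min_count
  cnv_callset(callset$calls[keep, , drop = FALSE],
              callset$genotypes[keep, , drop = FALSE])
}

#' Haploidize Y-chromosome calls
#'
#' Restricts a diploid genotype matrix (assumed Y-only) to male samples,
#' sets heterozygous calls to missing (heterozygosity on a haploid
#' chromosome is a genotyping artifact) and collapses homozygous calls to
#' single alleles. Already-haploid input is returned subset to males.
#'
#' @param gm a [genotype_matrix()] restricted to the Y chromosome.
#' @param males character vector of male sample names.
#' @return A haploid [genotype_matrix()] with male samples only.
#' @export
haploidize_y <- function(gm, males) {
  males <- intersect(males, gm$samples)
  if (length(males) == 0L) stop("no male samples present")
  gm <- gm_subset(gm, samples = males)
  if (gm$ploidy == 1L) return(gm)
  a1 <- gm$a1
  het <- !is.na(gm$a1) & gm$a1 != gm$a2
  a1[het] <- NA_integer_
  genotype_matrix(gm$sites, a1, NULL, samples = gm$samples, ploidy = 1L)
}
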