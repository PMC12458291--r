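#' CNV population genetics
#'
#' Copy-number variants are analyzed on two complementary axes: presence
#' of the carrier allele (a biallelic locus, amenable to the same
#' Weir-Cockerham FST as a SNP) and the integer copy number itself, whose
#' between-population variance fraction is VST = (V_T - V_S) / V_T —
#' the CNV analogue of FST. Calls are cross-validated between two
#' independent callsets by length overlap before outlier scanning.
#'
#' @name cnv_divergence
NULL

#' Per-locus Weir-Cockerham FST of CNV carrier alleles
#'
#' Each CNV record is treated as a biallelic locus whose ALT allele is
#' "carrier"; per-locus FST is the Weir-Cockerham ratio a / (a + b + c)
#' on the dosage-coded genotypes, negatives clamped to 0. This runs the
#' same code path as SNP FST, so the two are exactly exchangeable on
#' equivalently coded input.
#'
#' @param callset a [cnv_callset()] with genotypes (dosage 0/1/2).
#' @param popmap data.frame `sample`/`population` (exactly 2 populations
#'   among the genotyped samples).
#' @return numeric per-locus FST; NA where a population is fully missing.
#' @export
cnv_fst <- function(callset, popmap) {
  g <- callset$genotypes
  if (is.null(g)) stop("callset has no genotypes")
  pops <- unique(popmap$population[popmap$sample %in% colnames(g)])
  if (length(pops) != 2) stop("cnv_fst compares exactly two populations")
  # recode dosage as a diploid genotype matrix and reuse the SNP machinery
  a1 <- ifelse(g >= 1, 1L, 0L); a1[is.na(g)] <- NA_integer_
  a2 <- ifelse(g >= 2, 1L, 0L); a2[is.na(g)] <- NA_integer_
  sites <- data.frame(chrom = callset$calls$chrom,
                      pos = seq_len(nrow(g)),   # synthetic unique positions
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  gm <- genotype_matrix(sites, a1, a2, samples = colnames(g), ploidy = 2L)
  cA <- site_counts(gm, pop_cols(gm, popmap, pops[1]))
  cB <- site_counts(gm, pop_cols(gm, popmap, pops[2]))
  wc <- site_wc_components(cA, cB, 2L)
  denom <- wc$a + wc$b + wc$c
  fst <- ifelse(!is.na(denom) & denom != 0, wc$a / denom, NA_real_)
  pmin(pmax(fst, 0), 1)
}

#' VST: between-population fraction of copy-number variance
#'
#' V_T is the variance of copy numbers pooled over populations; V_S is the
#' size-weighted mean within-population variance, sum_p (n_p / N) Var_p;
#' VST = (V_T - V_S) / V_T. VST is 1 exactly when populations are
#' internally invariant but differ; it is undefined (NA) when V_T = 0 or
#' any population has fewer than 2 called samples. Negative values are
#' reported as-is.
#'
#' @param copies integer copy numbers for one locus, named by sample, NA
#'   allowed.
#' @param popmap data.frame `sample`/`population`.
#' @return list: `v_total`, `v_within`, `vst` (NA when undefined).
#' @export
vst <- function(copies, popmap) {
  pop <- popmap$population[match(names(copies), popmap$sample)]
  ok <- !is.na(copies) & !is.na(pop)
  x <- copies[ok]; pop <- pop[ok]
  n_p <- table(pop)
  if (length(n_p) < 2 || any(n_p < 2))
    return(list(v_total = NA_real_, v_within = NA_real_, vst = NA_real_))
  v_total <- stats::var(x)
  v_within <- sum(vapply(names(n_p), function(p)
    (n_p[[p]] / length(x)) * stats::var(x[pop == p]), numeric(1)))
  if (v_total == 0)
    return(list(v_total = 0, v_within = v_within, vst = NA_real_))
  list(v_total = v_total, v_within = v_within,
       vst = (v_total - v_within) / v_total)
}

#' VST for every locus of a copy-number matrix
#'
#' @param copies integer matrix (loci x samples, columns named).
#' @param popmap data.frame `sample`/`population`.
#' @return data.frame `v_total`, `v_within`, `vst`, one row per locus.
#' @export
vst_matrix <- function(copies, popmap) {
  rows <- lapply(seq_len(nrow(copies)), function(i)
    as.data.frame(vst(copies[i, ], popmap)))
  do.call(rbind, rows)
}

#' Cross-validate a primary callset against a secondary one
#'
#' A primary call is retained iff some secondary call of the same svtype
#' overlaps it with intersection length STRICTLY greater than
#' `min_overlap` times the primary call's length (half-open interval
#' arithmetic). With `reciprocal = TRUE` the same fraction of the
#' secondary call's length must also be covered.
#'
#' @param primary,secondary [cnv_callset()] objects.
#' @param min_overlap overlap fraction threshold (default 0.5).
#' @param reciprocal require the fraction in both directions.
#' @return list: `retained` (filtered primary [cnv_callset()]), `keep`
#'   (logical over primary calls), `report` (per-svtype retention counts).
#' @export
cross_validate_calls <- function(primary, secondary, min_overlap = 0.5,
                                 reciprocal = FALSE) {
  p <- primary$calls; s <- secondary$calls
  keep <- logical(nrow(p))
  if (nrow(p) > 0 && nrow(s) > 0) {
    gp <- GenomicRanges::GRanges(p$chrom,
            IRanges::IRanges(p$start + 1, p$end))   # to 1-based closed
    gs <- GenomicRanges::GRanges(s$chrom,
            IRanges::IRanges(s$start + 1, s$end))
    hits <- GenomicRanges::findOverlaps(gp, gs)
    if (length(hits) > 0) {
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      inter <- pmin(p$end[qi], s$end[si]) - pmax(p$start[qi], s$start[si])
      lenp <- p$end[qi] - p$start[qi]
      lens <- s$end[si] - s$start[si]
      good <- p$svtype[qi] == s$svtype[si] & inter > min_overlap * lenp
      if (reciprocal) good <- good & inter > min_overlap * lens
      keep[unique(qi[good])] <- TRUE
    }
  }
  report <- as.data.frame(table(svtype = p$svtype, retained = keep))
  list(retained = cnv_callset(p[keep, , drop = FALSE],
                              if (is.null(primary$genotypes)) NULL
                              else primary$genotypes[keep, , drop = FALSE]),
       keep = keep, report = report)
}

#' Quantile outliers of per-locus CNV FST
#'
#' Same rule as the windowed scan: threshold at the type-7 empirical
#' quantile, members strictly above.
#'
#' @param fst_values per-locus FST.
#' @param q quantile (default 0.99).
#' @return an `outlier_set` (see [outlier_windows()]).
#' @export
cnv_outliers <- function(fst_values, q = 0.99) outlier_windows(fst_values, q)

#' Lengths and nearest-gene geometry of outlier CNVs
#'
#' @param callset outlier calls as a [cnv_callset()] (0-based half-open).
#' @param genes data.frame `chrom`, `start`, `end` of gene intervals
#'   (0-based half-open), or an empty/NULL set (distances then NA).
#' @return list with `per_call` (length, `nearest_gene_bp` distance — 0
#'   when overlapping —, `overlaps_gene`) and `aggregate` (per-svtype mean
#'   length, min/max, count and genes-overlapped count).
#' @export
summarize_outlier_geometry <- function(callset, genes) {
  p <- callset$calls
  per <- data.frame(chrom = p$chrom, start = p$start, end = p$end,
                    svtype = p$svtype, length = p$end - p$start,
                    stringsAsFactors = FALSE)
  if (is.null(genes) || nrow(genes) == 0) {
    per$nearest_gene_bp <- NA_real_
    per$overlaps_gene <- NA
  } else if (nrow(p) > 0) {
    gp <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start + 1, p$end))
    gg <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1, genes$end))
    d <- GenomicRanges::distanceToNearest(gp, gg)
    per$nearest_gene_bp <- NA_real_
    per$nearest_gene_bp[S4Vectors::queryHits(d)] <-
      as.numeric(S4Vectors::mcols(d)$distance)
    per$overlaps_gene <- !is.na(per$nearest_gene_bp) & per$nearest_gene_bp == 0
  } else {
    per$nearest_gene_bp <- numeric(0)
    per$overlaps_gene <- logical(0)
  }
  agg <- do.call(rbind, lapply(split(per, per$svtype), function(d)
    data.frame(svtype = d$svtype[1], n = nrow(d),
               mean_length = mean(d$length), min_length = min(d$length),
               max_length = max(d$length),
               n_overlapping_genes = sum(d$overlaps_gene, na.rm = TRUE),
               mean_gene_distance = mean(d$nearest_gene_bp, na.rm = TRUE),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  list(per_call = per, aggregate = agg)
}

#' Rank correlation between per-locus FST and VST
#'
#' The two axes of CNV differentiation share the latent signal when
#' copy-number differences track carrier-frequency differences; Spearman's
#' rho over loci defined on both axes quantifies that agreement.
#'
#' @param fst,vst per-locus values (matched order).
#' @return list: `rho`, `p_value`, `n` (paired loci used).
#' @export
fst_vst_association <- function(fst, vst) {
  ok <- !is.na(fst) & !is.na(vst)
  if (sum(ok) < 10) stop("need at least 10 loci with both FST and VST defined")
  ct <- suppressWarnings(
    stats::cor.test(fst[ok], vst[ok], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
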