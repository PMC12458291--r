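#' Windowed diversity and differentiation statistics
#'
#' Nucleotide diversity (pi) and absolute divergence (dXY) are computed as
#' ratios of sums over sites — per-site pairwise-difference counts over
#' per-site pairwise-comparison counts — so that invariant sites and
#' missing genotypes enter the denominator honestly (the estimator
#' popularized by pixy). Differentiation uses the Weir & Cockerham (1984)
#' variance-components FST, window-aggregated as sum(a) / sum(a + b + c),
#' with negative window values clamped to 0 as is conventional in genome
#' scans.
#'
#' @name windowed_divergence
NULL

# Per-site allele counts for a set of sample columns.
# Returns per-site vectors: n1 (ALT copies), k (called copies),
# n_ind (called individuals), het (observed heterozygote count; 0 haploid).
site_counts <- function(gm, cols) {
  A1 <- gm$a1[, cols, drop = FALSE]
  called <- !is.na(A1)
  if (gm$ploidy == 2L) {
    A2 <- gm$a2[, cols, drop = FALSE]
    n1 <- rowSums(A1 == 1L, na.rm = TRUE) + rowSums(A2 == 1L, na.rm = TRUE)
    n_ind <- rowSums(called)
    k <- 2L * n_ind
    het <- rowSums(A1 != A2, na.rm = TRUE)
  } else {
    n1 <- rowSums(A1 == 1L, na.rm = TRUE)
    n_ind <- rowSums(called)
    k <- n_ind
    het <- rep(0L, nrow(A1))
  }
  list(n1 = n1, n0 = k - n1, k = k, n_ind = n_ind, het = het)
}

#' Per-site pi components for one population
#'
#' With n0 REF and n1 ALT called allele copies (k = n0 + n1), the number of
#' differing pairs is n0 * n1 and the number of compared pairs k(k-1)/2.
#' Invariant sites contribute (0, k(k-1)/2); all-missing sites (0, 0).
#'
#' @param n0,n1 called REF/ALT allele copy counts (vectors allowed).
#' @return list with `diff` and `comp` counts.
#' @export
site_pi_components <- function(n0, n1) {
  k <- n0 + n1
  list(diff = n0 * n1, comp = k * (k - 1) / 2)
}

#' Per-site dXY components for a population pair
#'
#' Differing cross-population pairs nA0*nB1 + nA1*nB0 over kA*kB compared
#' pairs; either side all-missing gives (0, 0).
#'
#' @param nA0,nA1 called REF/ALT copies in population A.
#' @param nB0,nB1 called REF/ALT copies in population B.
#' @return list with `diff` and `comp` counts.
#' @export
site_dxy_components <- function(nA0, nA1, nB0, nB1) {
  list(diff = nA0 * nB1 + nA1 * nB0, comp = (nA0 + nA1) * (nB0 + nB1))
}

#' Per-site Weir-Cockerham variance components for two populations
#'
#' Diploid data use the full Weir & Cockerham (1984) decomposition into
#' a (among populations), b (among individuals within populations) and
#' c (within individuals), from sample sizes, ALT frequencies and observed
#' heterozygosities. Haploid data use the haploid reduction — a one-level
#' ANOVA of allele frequencies with the finite-sample correction n_c; b
#' holds the within-population mean squares and c is structurally 0, so
#' the windowed ratio sum(a)/sum(a+b+c) applies unchanged.
#'
#' Sites where either population has no called individuals (diploid: fewer
#' than one; haploid: where the pooled called copies do not exceed 2) are
#' returned as NA and must be excluded from window sums.
#'
#' @param cntA,cntB per-site count lists from `site_counts()`.
#' @param ploidy 1 or 2.
#' @return list of per-site vectors `a`, `b`, `c` (NA where undefined).
#' @export
site_wc_components <- function(cntA, cntB, ploidy = 2L) {
  if (ploidy == 2L) {
    n1 <- cntA$n_ind; n2 <- cntB$n_ind
    ok <- n1 >= 1 & n2 >= 1 & (n1 + n2) > 2
    p1 <- cntA$n1 / pmax(cntA$k, 1L); p2 <- cntB$n1 / pmax(cntB$k, 1L)
    h1 <- cntA$het / pmax(n1, 1L);    h2 <- cntB$het / pmax(n2, 1L)
    nbar <- (n1 + n2) / 2
    nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
    pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
    hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
  } else {
    n1 <- cntA$k; n2 <- cntB$k          # haploid: allele copies are the units
    ok <- n1 >= 1 & n2 >= 1 & (n1 + n2) > 2
    p1 <- cntA$n1 / pmax(n1, 1L); p2 <- cntB$n1 / pmax(n2, 1L)
    nbar <- (n1 + n2) / 2
    nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
    pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
    msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
    msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / pmax(n1 + n2 - 2, 1L)
    a <- (msp - msg) / nc
    b <- msg
    cc <- rep(0, length(a))
  }
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  list(a = a, b = b, c = cc)
}

#' Tile windows over sites
#'
#' Windows tile each chromosome from coordinate 0 in steps of `width`
#' (0-based half-open); a site at 1-based position p falls in window
#' floor((p-1)/width). The terminal window of each chromosome is flagged
#' partial since sequence may extend beyond the last site.
#'
#' @param sites data.frame with `chrom`, `pos`.
#' @param width window width in bp (default 50000).
#' @return integer vector of window ids (one per site), with a `windows`
#'   attribute: data.frame `chrom`, `start`, `end`, `partial`.
#' @export
assign_windows <- function(sites, width = 50000) {
  idx <- (sites$pos - 1) %/% width
  key <- paste(sites$chrom, idx, sep = ":")
  u <- !duplicated(key)
  wins <- data.frame(chrom = sites$chrom[u], start = idx[u] * width,
                     end = (idx[u] + 1) * width, stringsAsFactors = FALSE)
  last <- stats::ave(wins$start, wins$chrom, FUN = max)
  wins$partial <- wins$start == last
  id <- match(key, key[u])
  attr(id, "windows") <- wins
  id
}

#' Windowed pi, dXY and FST for a population pair
#'
#' @param gm a [genotype_matrix()] including invariant sites.
#' @param popmap data.frame `sample`/`population`.
#' @param pops length-2 character: the two populations to compare
#'   (default: the populations present, which must number exactly 2).
#' @param width window width in bp (default 50000, the conventional scan
#'   resolution).
#' @return data.frame, one row per window: `chrom`, `start`, `end`,
#'   `partial`, `n_sites`, per-population `pi_*` with `_num`/`_den`,
#'   `dxy` (+ components), `fst_a`, `fst_abc`, `fst_raw`, `fst`
#'   (clamped to [0, 1]), `n_fst_sites`. Statistics with zero denominators
#'   are NA (missing), never 0.
#' @export
windowed_stats <- function(gm, popmap, pops = NULL, width = 50000) {
  if (is.null(pops)) pops <- unique(popmap$population[popmap$sample %in% gm$samples])
  if (length(pops) != 2) stop("windowed_stats compares exactly two populations")
  cA <- site_counts(gm, pop_cols(gm, popmap, pops[1]))
  cB <- site_counts(gm, pop_cols(gm, popmap, pops[2]))
  piA <- site_pi_components(cA$n0, cA$n1)
  piB <- site_pi_components(cB$n0, cB$n1)
  dxy <- site_dxy_components(cA$n0, cA$n1, cB$n0, cB$n1)
  wc <- site_wc_components(cA, cB, gm$ploidy)
  # FST is defined over variant sites only
  varsite <- is_variant(gm)
  wc$a[!varsite] <- NA_real_; wc$b[!varsite] <- NA_real_; wc$c[!varsite] <- NA_real_
  id <- assign_windows(gm$sites, width)
  wins <- attr(id, "windows")
  g <- factor(id, levels = seq_len(nrow(wins)))
  agg <- function(x) as.numeric(rowsum(ifelse(is.na(x), 0, x), g))
  cnt <- function(x) as.numeric(rowsum(as.numeric(!is.na(x)), g))
  out <- wins
  out$n_sites <- as.numeric(rowsum(rep(1, length(id)), g))
  out[[paste0("pi_", pops[1], "_num")]] <- agg(piA$diff)
  out[[paste0("pi_", pops[1], "_den")]] <- agg(piA$comp)
  out[[paste0("pi_", pops[2], "_num")]] <- agg(piB$diff)
  out[[paste0("pi_", pops[2], "_den")]] <- agg(piB$comp)
  out$dxy_num <- agg(dxy$diff); out$dxy_den <- agg(dxy$comp)
  out$fst_a <- agg(wc$a)
  out$fst_abc <- agg(wc$a) + agg(wc$b) + agg(wc$c)
  out$n_fst_sites <- cnt(wc$a)
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out[[paste0("pi_", pops[1])]] <-
    safe_div(out[[paste0("pi_", pops[1], "_num")]],
             out[[paste0("pi_", pops[1], "_den")]])
  out[[paste0("pi_", pops[2])]] <-
    safe_div(out[[paste0("pi_", pops[2], "_num")]],
             out[[paste0("pi_", pops[2], "_den")]])
  out$dxy <- safe_div(out$dxy_num, out$dxy_den)
  out$fst_raw <- ifelse(out$n_fst_sites > 0 & out$fst_abc != 0,
                        out$fst_a / out$fst_abc, NA_real_)
  out$fst <- pmin(pmax(out$fst_raw, 0), 1)
  attr(out, "pops") <- pops
  out
}

#' Genome-wide mean with percentile bootstrap CI
#'
#' The resampling unit is the window: genome-wide means are means over
#' windows, and the 95% CI comes from `n_boot` resamples of the window set
#' with replacement (percentile method). The half-width `(hi - lo) / 2`
#' mirrors the "mean +/-" presentation of summary tables.
#'
#' @param values per-window statistic values (NAs dropped).
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed integer seed for the resampling.
#' @param conf confidence level (default 0.95).
#' @return list: `mean`, `ci_low`, `ci_high`, `half_width`, `n_windows`,
#'   `n_boot`.
#' @export
genome_summary <- function(values, n_boot = 10000, seed = 1L, conf = 0.95) {
  v <- values[!is.na(values)]
  if (length(v) == 0) stop("all values are missing")
  if (length(v) < 2) stop("need at least two defined windows")
  m <- mean(v)
  boots <- withr::with_seed(seed, {
    idx <- matrix(sample.int(length(v), length(v) * n_boot, replace = TRUE),
                  nrow = n_boot)
    rowMeans(matrix(v[idx], nrow = n_boot))
  })
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(mean = m, ci_low = qs[1], ci_high = qs[2],
       half_width = (qs[2] - qs[1]) / 2,
       n_windows = length(v), n_boot = n_boot)
}

#' Partition X-chromosome windows into PAR and nonPAR summaries
#'
#' A window belongs to the pseudoautosomal region when its midpoint lies
#' inside the PAR interval (0-based half-open).
#'
#' @param stats a [windowed_stats()] table restricted to the X.
#' @param par length-2 numeric PAR interval, 0-based half-open.
#' @param value_col name of the statistic column to summarize.
#' @param n_boot,seed passed to [genome_summary()].
#' @return list with `par` and `nonpar` [genome_summary()] results (`par`
#'   is `NULL`, i.e. marked missing, when no window falls inside it), and
#'   `n_par`/`n_nonpar` window counts.
#' @export
partition_par <- function(stats, par, value_col, n_boot = 10000, seed = 1L) {
  stopifnot(length(par) == 2, value_col %in% names(stats))
  mid <- (stats$start + stats$end) / 2
  in_par <- mid >= par[1] & mid < par[2]
  summ <- function(keep) {
    v <- stats[[value_col]][keep]
    if (sum(!is.na(v)) < 2) NULL else genome_summary(v, n_boot, seed)
  }
  list(par = summ(in_par), nonpar = summ(!in_par),
       n_par = sum(in_par), n_nonpar = sum(!in_par))
}

#' Y : autosome diversity ratio
#'
#' Under neutrality with equal sex ratios the Y carries 1/4 of the
#' autosomal effective population size, so pi(Y)/pi(A) near 0.25 is the
#' neutral expectation; departures indicate sex-biased demography or
#' selection on the Y. The displayed value truncates (floors) the ratio to
#' two decimals; the raw ratio is always returned alongside.
#'
#' @param pi_y mean nucleotide diversity on the Y (males).
#' @param pi_auto mean autosomal nucleotide diversity.
#' @return list: `raw`, `truncated` (floored to 2 decimals), `display`
#'   (formatted string).
#' @export
ya_diversity_ratio <- function(pi_y, pi_auto) {
  if (pi_auto <= 0) stop("pi_auto must be positive")
  raw <- pi_y / pi_auto
  tr <- floor(round(raw * 100, 9)) / 100
  list(raw = raw, truncated = tr, display = sprintf("%.2f", tr))
}
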