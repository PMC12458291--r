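# Independent oracles, written as literal brute-force / textbook
# transcriptions so they share no code path with the package internals.

# All called allele copies (0/1) of one population at one site.
called_alleles <- function(gm, cols, site) {
  a <- gm$a1[site, cols]
  if (!is.null(gm$a2)) a <- c(a, gm$a2[site, cols])
  a[!is.na(a)]
}

# pi over a set of sites by O(n^2) enumeration of allele pairs.
oracle_pi <- function(gm, cols, sites) {
  diff <- 0; comp <- 0
  for (s in sites) {
    al <- called_alleles(gm, cols, s)
    n <- length(al)
    if (n < 2) next
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      comp <- comp + 1
      if (al[i] != al[j]) diff <- diff + 1
    }
  }
  if (comp == 0) NA_real_ else diff / comp
}

# dXY by enumeration of cross-population allele pairs.
oracle_dxy <- function(gm, colsA, colsB, sites) {
  diff <- 0; comp <- 0
  for (s in sites) {
    a <- called_alleles(gm, colsA, s)
    b <- called_alleles(gm, colsB, s)
    for (x in a) for (y in b) {
      comp <- comp + 1
      if (x != y) diff <- diff + 1
    }
  }
  if (comp == 0) NA_real_ else diff / comp
}

# Weir & Cockerham (1984) variance components, general-r textbook form,
# from per-individual ALT dosages (0/1/2, NA = missing) per population.
oracle_wc_site <- function(dosage_by_pop) {
  r <- length(dosage_by_pop)
  n <- vapply(dosage_by_pop, function(d) sum(!is.na(d)), numeric(1))
  if (any(n < 1)) return(c(a = NA, b = NA, c = NA))
  p <- vapply(dosage_by_pop, function(d) mean(d, na.rm = TRUE) / 2, numeric(1))
  h <- vapply(dosage_by_pop, function(d) mean(d == 1, na.rm = TRUE), numeric(1))
  nbar <- sum(n) / r
  if (nbar <= 1) return(c(a = NA, b = NA, c = NA))
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Hudson-style FST from per-population ALT frequencies and allele-copy
# counts (ratio of averages over sites).
oracle_hudson_fst <- function(p1, p2, k1, k2) {
  hw <- (k1 / (k1 - 1)) * 2 * p1 * (1 - p1) / 2 +
        (k2 / (k2 - 1)) * 2 * p2 * (1 - p2) / 2
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  1 - mean(hw) / mean(hb)
}

# Brute-force variance decomposition for VST.
oracle_vst <- function(copies, pop) {
  ok <- !is.na(copies)
  x <- copies[ok]; pop <- pop[ok]
  vt <- var(x)
  vs <- 0
  for (p in unique(pop)) {
    xp <- x[pop == p]
    vs <- vs + (length(xp) / length(x)) * var(xp)
  }
  (vt - vs) / vt
}

# Quadratic-time interval cross-validation: retain primary call i iff some
# same-svtype secondary call overlaps it > frac * len_i (half-open).
oracle_retained <- function(p, s, frac = 0.5, reciprocal = FALSE) {
  keep <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(nrow(s))) {
      if (p$chrom[i] != s$chrom[j] || p$svtype[i] != s$svtype[j]) next
      inter <- min(p$end[i], s$end[j]) - max(p$start[i], s$start[j])
      ok <- inter > frac * (p$end[i] - p$start[i])
      if (reciprocal) ok <- ok && inter > frac * (s$end[j] - s$start[j])
      if (ok) { keep[i] <- TRUE; break }
    }
  }
  keep
}

# Small hand-built diploid genotype matrix from per-site genotype strings,
# e.g. list(c("0/0","0/1","1/1"), ...); "./." missing; alt = NA invariant.
toy_gm <- function(geno, alt = NULL, chrom = "chr1", pos = NULL,
                   samples = NULL) {
  n_site <- length(geno); n_smp <- length(geno[[1]])
  a1 <- matrix(NA_integer_, n_site, n_smp)
  a2 <- matrix(NA_integer_, n_site, n_smp)
  for (i in seq_len(n_site)) {
    parts <- strsplit(geno[[i]], "/")
    a1[i, ] <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1)))
    a2[i, ] <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  }
  if (is.null(alt)) alt <- rep("T", n_site)
  if (is.null(pos)) pos <- seq_len(n_site)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(n_smp))
  genotype_matrix(
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = alt,
               stringsAsFactors = FALSE),
    a1, a2, samples = samples, ploidy = 2L)
}

toy_popmap <- function(gm, split = length(gm$samples) / 2,
                       pops = c("popA", "popB")) {
  data.frame(sample = gm$samples,
             population = rep(pops, c(split, length(gm$samples) - split)),
             stringsAsFactors = FALSE)
}
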