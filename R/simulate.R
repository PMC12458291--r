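#' Simulation parameters for diverged populations
#'
#' Populations are simulated under the Balding-Nichols model: an ancestral
#' allele frequency p is drawn per polymorphic site (uniform on
#' [0.05, 0.95], keeping minor-allele-frequency filters non-degenerate) and
#' each population's frequency is drawn from a Beta distribution with mean p
#' and variance F p (1 - p), where F is the per-population drift parameter.
#' The expected Weir-Cockerham FST between two populations simulated at the
#' same F is close to F, which makes estimator-recovery tests possible.
#'
#' @param n_pops number of populations (2 or 3).
#' @param n_diploids_per_pop diploid individuals per population (>= 2).
#' @param n_sites number of emitted sites (variant + invariant).
#' @param seq_length chromosome length in bp; `n_sites <= seq_length`.
#' @param divergence_F drift parameter in [0, 1); scalar or one value per
#'   population. F = 0 degenerates to a point mass at p.
#' @param prop_variant fraction of sites polymorphic in the ancestor.
#' @param missing_rate i.i.d. per-genotype missingness fraction in [0, 1).
#' @param seed integer seed; identical parameters and seed give
#'   bit-identical output.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_pops = 2L, n_diploids_per_pop = 20L,
                       n_sites = 10000L, seq_length = 1e6,
                       divergence_F = 0.1, prop_variant = 0.2,
                       missing_rate = 0, seed = 1L) {
  stopifnot(n_pops >= 1, n_sites <= seq_length,
            all(divergence_F >= 0), all(divergence_F < 1),
            prop_variant >= 0, prop_variant <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (n_diploids_per_pop < 2)
    stop("n_diploids_per_pop must be >= 2: pairwise statistics are undefined otherwise")
  F <- rep_len(divergence_F, n_pops)
  structure(list(n_pops = as.integer(n_pops),
                 n_diploids_per_pop = as.integer(n_diploids_per_pop),
                 n_sites = as.integer(n_sites), seq_length = seq_length,
                 divergence_F = F, prop_variant = prop_variant,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_params")
}

# Balding-Nichols population frequency: Beta with mean p, variance F p(1-p).
# F = 0 is a point mass at p.
bn_pop_freq <- function(p, F) {
  out <- p
  pos <- F > 0
  if (any(pos)) {
    lambda <- (1 - F[pos]) / F[pos]
    out[pos] <- stats::rbeta(sum(pos), lambda * p[pos], lambda * (1 - p[pos]))
  }
  out
}

# Draw a (sites x samples) pair of allele matrices for one population given
# per-site ALT frequencies; haploid draws only a1.
draw_genotypes <- function(freq, n_ind, ploidy) {
  n <- length(freq)
  a1 <- matrix(stats::rbinom(n * n_ind, 1L, rep(freq, n_ind)), nrow = n)
  a2 <- if (ploidy == 2L)
    matrix(stats::rbinom(n * n_ind, 1L, rep(freq, n_ind)), nrow = n)
  else NULL
  list(a1 = a1, a2 = a2)
}

apply_missingness <- function(a1, a2, rate) {
  if (rate <= 0) return(list(a1 = a1, a2 = a2))
  miss <- matrix(stats::runif(length(a1)) < rate, nrow = nrow(a1))
  a1[miss] <- NA_integer_
  if (!is.null(a2)) a2[miss] <- NA_integer_
  list(a1 = a1, a2 = a2)
}

sample_names <- function(n_pops, n_per, prefix = "pop") {
  unlist(lapply(seq_len(n_pops), function(k)
    sprintf("%s%d_ind%02d", prefix, k, seq_len(n_per))))
}

random_bases <- function(n) {
  b <- c("A", "C", "G", "T")
  ref <- sample(b, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(b, r), 1L), character(1))
  list(ref = ref, alt = alt)
}

#' Simulate diverged populations with invariant sites and known truth
#'
#' Emits an all-sites genotype matrix: polymorphic sites follow the
#' Balding-Nichols model described in [sim_params()]; invariant sites are
#' emitted as records with all-reference genotypes (so that windowed pi and
#' dXY have honest denominators); missingness is applied i.i.d. per
#' genotype. The returned truth record carries the realized per-population
#' allele frequencies, sufficient to compute expected FST and pi
#' analytically.
#'
#' @param params a [sim_params()].
#' @param chrom chromosome name for the emitted sites.
#' @return list with elements `gm` (a [genotype_matrix()]), `popmap`
#'   (sample/population/sex data.frame; sexes alternate M/F) and `truth`
#'   (list: `freq` sites x pops matrix, `p_anc`, `variant`, `divergence_F`,
#'   `params`).
#' @export
simulate_split_populations <- function(params, chrom = "chr1") {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, {
    n <- params$n_sites
    pos <- sort(sample.int(params$seq_length, n))
    variant <- stats::runif(n) < params$prop_variant
    p_anc <- ifelse(variant, stats::runif(n, 0.05, 0.95), 0)
    freq <- matrix(0, n, params$n_pops)
    for (k in seq_len(params$n_pops)) {
      fk <- rep(params$divergence_F[k], sum(variant))
      freq[variant, k] <- bn_pop_freq(p_anc[variant], fk)
    }
    a1 <- NULL; a2 <- NULL
    for (k in seq_len(params$n_pops)) {
      g <- draw_genotypes(freq[, k], params$n_diploids_per_pop, 2L)
      a1 <- cbind(a1, g$a1); a2 <- cbind(a2, g$a2)
    }
    m <- apply_missingness(a1, a2, params$missing_rate)
    bases <- random_bases(n)
    alt <- ifelse(variant, bases$alt, NA_character_)
    smp <- sample_names(params$n_pops, params$n_diploids_per_pop)
    sites <- data.frame(chrom = chrom, pos = pos, ref = bases$ref, alt = alt,
                        stringsAsFactors = FALSE)
    gm <- genotype_matrix(sites, m$a1, m$a2, samples = smp, ploidy = 2L)
    popmap <- data.frame(
      sample = smp,
      population = rep(sprintf("pop%d", seq_len(params$n_pops)),
                       each = params$n_diploids_per_pop),
      sex = rep_len(c("M", "F"), length(smp)),
      stringsAsFactors = FALSE)
    truth <- list(freq = freq, p_anc = p_anc, variant = variant,
                  divergence_F = params$divergence_F, params = params)
    list(gm = gm, popmap = popmap, truth = truth)
  })
}

#' Sex-chromosome simulation parameters
#'
#' @param par_interval length-2 numeric, 0-based half-open PAR interval on
#'   the X; must lie within `[0, seq_length)` of the X.
#' @param par_pi_multiplier factor (>= 1) by which mean diversity in the PAR
#'   exceeds the rest of the X. Implemented by scaling the fraction of
#'   polymorphic sites inside the PAR, since expected pi is linear in that
#'   fraction.
#' @param n_males,n_females sample counts per population.
#' @return list of class `sexchrom_params`.
#' @export
sexchrom_params <- function(par_interval = c(0, 2.5e6),
                            par_pi_multiplier = 3.5,
                            n_males = 10L, n_females = 10L) {
  stopifnot(length(par_interval) == 2, par_interval[1] < par_interval[2],
            par_pi_multiplier >= 1, n_males >= 0, n_females >= 0)
  structure(list(par_interval = par_interval,
                 par_pi_multiplier = par_pi_multiplier,
                 n_males = as.integer(n_males),
                 n_females = as.integer(n_females)),
            class = "sexchrom_params")
}

#' Simulate an X chromosome with a high-diversity PAR, and a haploid male Y
#'
#' X genotypes are diploid and emitted for females; sites falling inside
#' the PAR interval are polymorphic at `par_pi_multiplier` times the base
#' rate (the spec of real sex chromosomes this emulates: the recombining
#' pseudoautosomal region retains markedly higher diversity than the
#' non-recombining X). The Y is haploid and carries male samples only; its
#' sites reuse the non-PAR polymorphism rate.
#'
#' @param params a [sim_params()] (its `n_pops`, `divergence_F`, `n_sites`,
#'   `seq_length`, `prop_variant`, `missing_rate`, `seed` are used; the
#'   per-population sample sizes come from `sex`).
#' @param sex a [sexchrom_params()]. Y output requires `n_males >= 2`;
#'   `n_males = 0` yields an empty Y matrix without error.
#' @return list with `gm_x`, `gm_y` (a [genotype_matrix()] each; `gm_y` has
#'   zero samples when `n_males < 2`), `popmap` covering all X/Y samples,
#'   and `truth` (with `par_interval` and per-chromosome frequency tables).
#' @export
simulate_sex_chromosomes <- function(params, sex) {
  stopifnot(inherits(params, "sim_params"), inherits(sex, "sexchrom_params"))
  if (sex$par_interval[2] > params$seq_length)
    stop("par_interval extends beyond the simulated X length")
  withr::with_seed(params$seed, {
    n <- params$n_sites
    ## --- X: females, diploid, PAR with boosted polymorphism rate
    pos_x <- sort(sample.int(params$seq_length, n))
    in_par <- pos_x - 1 >= sex$par_interval[1] & pos_x - 1 < sex$par_interval[2]
    p_var <- ifelse(in_par, pmin(1, params$prop_variant * sex$par_pi_multiplier),
                    params$prop_variant)
    variant_x <- stats::runif(n) < p_var
    p_anc_x <- ifelse(variant_x, stats::runif(n, 0.05, 0.95), 0)
    freq_x <- matrix(0, n, params$n_pops)
    a1 <- NULL; a2 <- NULL
    for (k in seq_len(params$n_pops)) {
      fk <- rep(params$divergence_F[k], sum(variant_x))
      freq_x[variant_x, k] <- bn_pop_freq(p_anc_x[variant_x], fk)
      g <- draw_genotypes(freq_x[, k], sex$n_females, 2L)
      a1 <- cbind(a1, g$a1); a2 <- cbind(a2, g$a2)
    }
    mx <- apply_missingness(a1, a2, params$missing_rate)
    bx <- random_bases(n)
    females <- sample_names(params$n_pops, sex$n_females, prefix = "F_pop")
    gm_x <- genotype_matrix(
      data.frame(chrom = "chrX", pos = pos_x, ref = bx$ref,
                 alt = ifelse(variant_x, bx$alt, NA_character_),
                 stringsAsFactors = FALSE),
      mx$a1, mx$a2, samples = females, ploidy = 2L)

    ## --- Y: males, haploid
    males <- sample_names(params$n_pops, sex$n_males, prefix = "M_pop")
    if (sex$n_males >= 2) {
      pos_y <- sort(sample.int(params$seq_length, n))
      variant_y <- stats::runif(n) < params$prop_variant
      p_anc_y <- ifelse(variant_y, stats::runif(n, 0.05, 0.95), 0)
      freq_y <- matrix(0, n, params$n_pops)
      y1 <- NULL
      for (k in seq_len(params$n_pops)) {
        fk <- rep(params$divergence_F[k], sum(variant_y))
        freq_y[variant_y, k] <- bn_pop_freq(p_anc_y[variant_y], fk)
        g <- draw_genotypes(freq_y[, k], sex$n_males, 1L)
        y1 <- cbind(y1, g$a1)
      }
      my <- apply_missingness(y1, NULL, params$missing_rate)
      by <- random_bases(n)
      gm_y <- genotype_matrix(
        data.frame(chrom = "chrY", pos = pos_y, ref = by$ref,
                   alt = ifelse(variant_y, by$alt, NA_character_),
                   stringsAsFactors = FALSE),
        my$a1, NULL, samples = males, ploidy = 1L)
    } else {
      freq_y <- NULL
      gm_y <- genotype_matrix(
        data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), stringsAsFactors = FALSE),
        matrix(integer(), 0, sex$n_males,
               dimnames = list(NULL, males[seq_len(sex$n_males)])),
        NULL, samples = males[seq_len(sex$n_males)], ploidy = 1L)
    }
    pops <- sprintf("pop%d", seq_len(params$n_pops))
    popmap <- rbind(
      data.frame(sample = females, population = rep(pops, each = sex$n_females),
                 sex = "F", stringsAsFactors = FALSE),
      if (sex$n_males > 0)
        data.frame(sample = males, population = rep(pops, each = sex$n_males),
                   sex = "M", stringsAsFactors = FALSE))
    truth <- list(par_interval = sex$par_interval,
                  par_pi_multiplier = sex$par_pi_multiplier,
                  freq_x = freq_x, freq_y = freq_y,
                  variant_x = variant_x, in_par = in_par)
    list(gm_x = gm_x, gm_y = gm_y, popmap = popmap, truth = truth)
  })
}

#' Latent CNV truth loci
#'
#' Generates disjoint deletion/duplication loci with per-population carrier
#' allele frequencies. Copy numbers follow the carrier genotype: baseline 2
#' copies, +1 per duplication allele, -1 per deletion allele, so that
#' presence-allele FST and copy-number VST share the same latent signal.
#'
#' @param n_loci number of CNV loci.
#' @param seq_length chromosome length in bp.
#' @param pop_freqs numeric matrix (loci x populations) of carrier allele
#'   frequencies, or `NULL` to draw them uniform on [0.1, 0.6].
#' @param n_pops used when `pop_freqs` is `NULL`.
#' @param len_range CNV length range in bp.
#' @param seed integer seed.
#' @return data.frame of class `cnv_truth`: `chrom`, `start`, `end`
#'   (0-based half-open), `svtype`, plus `freq_pop1 ...` columns.
#' @export
simulate_cnv_truth <- function(n_loci = 50L, seq_length = 1e7,
                               pop_freqs = NULL, n_pops = 2L,
                               len_range = c(500, 20000), seed = 1L) {
  withr::with_seed(seed, {
    if (is.null(pop_freqs))
      pop_freqs <- matrix(stats::runif(n_loci * n_pops, 0.1, 0.6),
                          n_loci, n_pops)
    n_pops <- ncol(pop_freqs)
    len <- round(stats::runif(n_loci, len_range[1], len_range[2]))
    # place loci in disjoint evenly spaced slots
    slot <- floor(seq_length / n_loci)
    if (any(len >= slot)) stop("seq_length too short for n_loci disjoint CNVs")
    start <- (seq_len(n_loci) - 1L) * slot +
      floor(stats::runif(n_loci) * (slot - len))
    truth <- data.frame(chrom = "chr1", start = start, end = start + len,
                        svtype = sample(c("DEL", "DUP"), n_loci, replace = TRUE),
                        stringsAsFactors = FALSE)
    colnames(pop_freqs) <- sprintf("freq_pop%d", seq_len(n_pops))
    truth <- cbind(truth, as.data.frame(pop_freqs))
    class(truth) <- c("cnv_truth", "data.frame")
    truth
  })
}

#' A CNV callset container
#'
#' @param calls data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `svtype` (`DEL`/`DUP`/`INV`), `quality`, `is_true` flag and an
#'   attached genotype matrix.
#' @param genotypes integer matrix (calls x samples): ALT-carrier dosage
#'   0/1/2, `NA` missing; `NULL` for ungenotyped callsets.
#' @return object of class `cnv_callset`.
#' @export
cnv_callset <- function(calls, genotypes = NULL) {
  stopifnot(all(c("chrom", "start", "end", "svtype") %in% names(calls)),
            all(calls$end > calls$start))
  if (!is.null(genotypes)) stopifnot(nrow(genotypes) == nrow(calls))
  rownames(calls) <- NULL
  structure(list(calls = calls, genotypes = genotypes), class = "cnv_callset")
}

#' @export
print.cnv_callset <- function(x, ...) {
  cat(sprintf("cnv_callset: %d calls (%s)%s\n", nrow(x$calls),
              paste(sprintf("%s=%d", names(table(x$calls$svtype)),
                            table(x$calls$svtype)), collapse = ", "),
              if (is.null(x$genotypes)) "" else
                sprintf(", %d genotyped samples", ncol(x$genotypes))))
  invisible(x)
}

# spurious calls: uniform over CNV-free sequence, lengths resampled from
# the true calls (preserves the length distribution for overlap tests)
place_spurious <- function(n_spur, truth, seq_length) {
  if (n_spur == 0L) return(NULL)
  len <- sample(truth$end - truth$start, n_spur, replace = TRUE)
  out <- vector("list", n_spur)
  for (i in seq_len(n_spur)) {
    repeat {
      s <- floor(stats::runif(1) * (seq_length - len[i]))
      e <- s + len[i]
      if (!any(pmax(s, truth$start) < pmin(e, truth$end))) break
    }
    out[[i]] <- data.frame(chrom = truth$chrom[1], start = s, end = e,
                           svtype = sample(c("DEL", "DUP"), 1),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate two jittered CNV callsets over shared latent loci
#'
#' Emulates cross-validation between two independent CNV callers: both
#' callsets contain every true locus with endpoints perturbed uniformly
#' within `+/- jitter_bp`, plus spurious calls (placed on CNV-free sequence,
#' lengths resampled from the true calls) at the given false-discovery
#' rates. Per-sample carrier genotypes are binomial draws from the
#' per-population truth frequencies; the copy-number matrix is baseline 2
#' plus/minus the carrier dosage for duplications/deletions.
#'
#' @param truth_cnvs a [simulate_cnv_truth()] table; loci must be disjoint.
#' @param popmap data.frame `sample`/`population`; populations must match
#'   the `freq_pop*` columns in order.
#' @param jitter_bp maximum endpoint perturbation, bp (>= 0).
#' @param fdr_a,fdr_b fraction of calls in callset A/B that are spurious,
#'   each in [0, 1).
#' @param seed integer seed.
#' @return list with `callset_a`, `callset_b` (class `cnv_callset`; A is
#'   genotyped), `copies` (integer matrix loci x samples for the TRUE loci
#'   of callset A) and `truth_index_a` (row index of true calls in A).
#' @export
simulate_cnv_callsets <- function(truth_cnvs, popmap, jitter_bp = 0,
                                  fdr_a = 0, fdr_b = 0, seed = 1L) {
  stopifnot(jitter_bp >= 0, fdr_a >= 0, fdr_a < 1, fdr_b >= 0, fdr_b < 1)
  o <- order(truth_cnvs$start)
  truth_cnvs <- truth_cnvs[o, , drop = FALSE]
  if (any(utils::head(truth_cnvs$end, -1) > utils::tail(truth_cnvs$start, -1)))
    stop("latent CNV loci must be disjoint")
  freq_cols <- grep("^freq_pop", names(truth_cnvs), value = TRUE)
  pops <- unique(popmap$population)
  stopifnot(length(freq_cols) >= length(pops))
  seq_length <- max(truth_cnvs$end) + max(truth_cnvs$end - truth_cnvs$start) * 4
  withr::with_seed(seed, {
    n_true <- nrow(truth_cnvs)
    jit <- function(x) {
      if (jitter_bp == 0) return(x)
      x + floor(stats::runif(length(x), -jitter_bp, jitter_bp + 1))
    }
    make_set <- function(fdr) {
      calls <- data.frame(chrom = truth_cnvs$chrom,
                          start = pmax(0, jit(truth_cnvs$start)),
                          end = jit(truth_cnvs$end),
                          svtype = truth_cnvs$svtype, stringsAsFactors = FALSE)
      calls$end <- pmax(calls$end, calls$start + 1)
      calls$is_true <- TRUE
      n_spur <- round(fdr * n_true / (1 - fdr))
      spur <- place_spurious(n_spur, truth_cnvs, seq_length)
      if (!is.null(spur)) { spur$is_true <- FALSE; calls <- rbind(calls, spur) }
      calls$quality <- round(stats::runif(nrow(calls), 20, 99), 1)
      idx <- order(calls$start)
      list(calls = calls[idx, , drop = FALSE],
           truth_index = match(seq_len(n_true), idx))
    }
    set_a <- make_set(fdr_a)
    set_b <- make_set(fdr_b)

    # genotypes for callset A: true loci from truth frequencies, spurious
    # loci at low uniform carrier frequency
    n_smp <- nrow(popmap)
    geno <- matrix(0L, nrow(set_a$calls), n_smp,
                   dimnames = list(NULL, popmap$sample))
    for (i in seq_len(nrow(set_a$calls))) {
      ti <- which(set_a$truth_index == i)
      for (p in seq_along(pops)) {
        j <- which(popmap$population == pops[p])
        f <- if (length(ti) == 1) truth_cnvs[[freq_cols[p]]][ti]
             else stats::runif(1, 0.05, 0.15)
        geno[i, j] <- stats::rbinom(length(j), 2L, f)
      }
    }
    callset_a <- cnv_callset(set_a$calls, geno)
    callset_b <- cnv_callset(set_b$calls, NULL)

    sign_cn <- ifelse(truth_cnvs$svtype == "DUP", 1L, -1L)
    copies <- 2L + geno[set_a$truth_index, , drop = FALSE] * sign_cn
    list(callset_a = callset_a, callset_b = callset_b,
         copies = copies, truth_index_a = set_a$truth_index)
  })
}
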