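#' Genotype matrix container
#'
#' The central data structure of the pipeline: per-site, per-sample allele
#' calls (diploid or haploid) with explicit missingness, carrying both
#' variant and invariant records so that pi and dXY denominators are
#' unbiased.
#'
#' Coordinates are 1-based in the `sites` table (VCF convention). All
#' interval arithmetic elsewhere in the package (windows, PAR, CNV overlap)
#' uses 0-based half-open coordinates; conversion happens at the boundary.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (`NA` for invariant records).
#' @param a1,a2 integer matrices (sites x samples) of allele codes (0 = REF,
#'   1 = ALT, `NA` = missing). For haploid data `a2` is `NULL`. A missing
#'   diploid genotype has both alleles `NA`.
#' @param samples character vector of unique sample names (column names).
#' @param ploidy 1 or 2.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, a1, a2 = NULL, samples = colnames(a1),
                            ploidy = if (is.null(a2)) 1L else 2L) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            nrow(a1) == nrow(sites))
  if (anyDuplicated(samples)) stop("sample names must be unique")
  if (ploidy == 2L) {
    stopifnot(!is.null(a2), identical(dim(a1), dim(a2)))
    bad <- is.na(a1) != is.na(a2)
    if (any(bad)) stop("diploid calls must have both alleles present or both missing")
  } else {
    a2 <- NULL
  }
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within a chromosome")
  }
  a1 <- as.matrix(a1); storage.mode(a1) <- "integer"
  colnames(a1) <- samples
  if (!is.null(a2)) {
    a2 <- as.matrix(a2); storage.mode(a2) <- "integer"
    colnames(a2) <- samples
  }
  rownames(sites) <- NULL
  structure(list(sites = sites, a1 = a1, a2 = a2,
                 samples = as.character(samples), ploidy = as.integer(ploidy)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nv <- sum(!is.na(x$sites$alt))
  cat(sprintf("genotype_matrix: %d sites (%d variant, %d invariant), %d samples, ploidy %d\n",
              nrow(x$sites), nv, nrow(x$sites) - nv, length(x$samples), x$ploidy))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$sites), length(x$samples))

is_variant <- function(gm) !is.na(gm$sites$alt)

#' Subset a genotype matrix by sites and/or samples
#'
#' @param gm a [genotype_matrix()].
#' @param sites logical or integer index over rows (sites).
#' @param samples character names, or logical/integer index over samples.
#' @return A `genotype_matrix`.
#' @export
gm_subset <- function(gm, sites = NULL, samples = NULL) {
  a1 <- gm$a1; a2 <- gm$a2; tab <- gm$sites; smp <- gm$samples
  if (!is.null(samples)) {
    j <- if (is.character(samples)) match(samples, smp) else seq_along(smp)[samples]
    if (anyNA(j)) stop("unknown sample(s): ",
                       paste(samples[is.na(j)], collapse = ", "))
    a1 <- a1[, j, drop = FALSE]
    if (!is.null(a2)) a2 <- a2[, j, drop = FALSE]
    smp <- smp[j]
  }
  if (!is.null(sites)) {
    a1 <- a1[sites, , drop = FALSE]
    if (!is.null(a2)) a2 <- a2[sites, , drop = FALSE]
    tab <- tab[sites, , drop = FALSE]
  }
  genotype_matrix(tab, a1, a2, samples = smp, ploidy = gm$ploidy)
}

#' Per-sample ALT dosage matrix
#'
#' Dosage is 0/1/2 for diploids, 0/1 for haploids, `NA` when missing.
#' Returned as samples x sites (the orientation PCA wants).
#'
#' @param gm a [genotype_matrix()].
#' @param variant_only drop invariant records first (default `TRUE`).
#' @return numeric matrix, samples in rows.
#' @export
gm_dosage <- function(gm, variant_only = TRUE) {
  if (variant_only) gm <- gm_subset(gm, sites = is_variant(gm))
  d <- gm$a1
  if (!is.null(gm$a2)) d <- d + gm$a2
  t(d)
}

#' Read a population map
#'
#' A population map is a headerless TSV `sample<TAB>population[<TAB>sex]`.
#'
#' @param path file path.
#' @return data.frame with columns `sample`, `population` and, when present,
#'   `sex` ("M"/"F").
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(pm) <- c("sample", "population", "sex")[seq_len(ncol(pm))]
  pm
}

#' Write a population map
#' @param popmap data.frame with `sample`, `population` and optionally `sex`.
#' @param path file path.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(popmap, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Column indices of one population's samples; errors on unknown samples.
pop_cols <- function(gm, popmap, population) {
  s <- popmap$sample[popmap$population == population]
  j <- match(intersect(s, gm$samples), gm$samples)
  if (length(j) == 0L) stop("no samples of population '", population,
                            "' present in the genotype matrix")
  j
}
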