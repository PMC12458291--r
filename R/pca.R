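#' Genotype principal component analysis
#'
#' Population structure from a genotype matrix, following the standard
#' SNP-PCA recipe: per-site ALT dosage (0/1/2 diploid, 0/1 haploid),
#' missing calls imputed with the site mean, columns centered and scaled by
#' the binomial standard deviation sqrt(p(1-p)) under the site's observed
#' allele frequency, then an eigendecomposition of the sample-by-sample
#' covariance. Mean imputation pulls high-missingness samples toward the
#' origin — the familiar "grouping towards zero" of sparse samples.
#'
#' Monomorphic sites carry no information and are dropped; sign convention
#' orients each component so its largest-magnitude coordinate is positive.
#'
#' @param gm a [genotype_matrix()] (variant sites are used).
#' @param n_components number of components to return (default 10, capped
#'   at the available rank).
#' @return list of class `pca_result`: `coordinates` (samples x
#'   components), `pct_variance` (per component, percent of total),
#'   `n_variants_used`.
#' @export
genotype_pca <- function(gm, n_components = 10) {
  d <- gm_dosage(gm, variant_only = TRUE)
  if (nrow(d) < 2 || ncol(d) < 2)
    stop("PCA needs at least 2 samples and 2 variant sites")
  ploidy <- gm$ploidy
  col_mean <- colMeans(d, na.rm = TRUE)
  p <- col_mean / ploidy
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic sites after dosage coding")
  d <- d[, poly, drop = FALSE]
  col_mean <- col_mean[poly]; p <- p[poly]
  # mean-impute, center, scale
  idx <- which(is.na(d))
  if (length(idx)) d[idx] <- col_mean[((idx - 1) %/% nrow(d)) + 1]
  x <- sweep(d, 2, col_mean, "-")
  x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  cv <- tcrossprod(x) / ncol(x)
  eg <- eigen(cv, symmetric = TRUE)
  pos <- pmax(eg$values, 0)
  k <- min(n_components, sum(pos > 1e-12))
  coords <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- gm$samples
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coordinates = coords,
                 pct_variance = 100 * pos[seq_len(k)] / sum(pos),
                 n_variants_used = ncol(x)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples x %d components over %d variants\n",
              nrow(x$coordinates), ncol(x$coordinates), x$n_variants_used))
  cat("  % variance:", paste(sprintf("%.2f", x$pct_variance), collapse = " "),
      "\n")
  invisible(x)
}
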