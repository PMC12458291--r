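#' Population branch statistic (PBS) scan
#'
#' The three-population selection scan: pairwise windowed FST between a
#' focal population A and two references B, C is transformed into branch
#' lengths T = -ln(1 - FST), and the focal branch is
#' PBS_A = ((T_AB + T_AC) - T_BC) / 2. Elevated PBS marks windows where
#' differentiation accumulated specifically on the focal lineage — the
#' signature of recent local selection. Clamping order follows genome-scan
#' convention: FST is clamped to [0, 1] before the log transform, PBS is
#' clamped at 0 after.
#'
#' @name pbs_scan_module
NULL

#' FST to branch length
#'
#' T = -ln(1 - FST), natural log. FST equal to 1 is capped at 1 - 1e-6
#' (and flagged via attribute "capped") so downstream arithmetic stays
#' finite.
#'
#' @param fst numeric in [0, 1] (already clamped).
#' @return branch length(s) T >= 0, with attribute `capped` (logical
#'   vector) when any input was 1.
#' @export
branch_length <- function(fst) {
  stopifnot(all(fst >= 0 & fst <= 1, na.rm = TRUE))
  capped <- !is.na(fst) & fst >= 1
  f <- ifelse(capped, 1 - 1e-6, fst)
  t <- -log(1 - f)
  if (any(capped)) attr(t, "capped") <- capped
  t
}

#' Focal-branch PBS from three branch lengths
#'
#' @param t_ab,t_ac branch lengths from the focal population A to B and C.
#' @param t_bc branch length between the two reference populations.
#' @return ((t_ab + t_ac) - t_bc) / 2, clamped below at 0.
#' @export
pbs <- function(t_ab, t_ac, t_bc) {
  stopifnot(all(t_ab >= 0, na.rm = TRUE), all(t_ac >= 0, na.rm = TRUE),
            all(t_bc >= 0, na.rm = TRUE))
  pmax(((t_ab + t_ac) - t_bc) / 2, 0)
}

#' Windowed PBS scan from three pairwise FST tracks
#'
#' The three tracks must share a window grid (chrom/start/end). Windows
#' where any pairwise FST is undefined are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @param fst_ab,fst_ac,fst_bc [windowed_stats()] tables (or any data.frame
#'   with `chrom`, `start`, `end`, `fst`) for pairs focal-B, focal-C, B-C.
#' @param focal label of the focal population, recorded in the output.
#' @return data.frame: `chrom`, `start`, `end`, `fst_ab`, `fst_ac`,
#'   `fst_bc`, `t_ab`, `t_ac`, `t_bc`, `pbs`, `focal`; attribute
#'   `n_skipped`.
#' @export
pbs_scan <- function(fst_ab, fst_ac, fst_bc, focal = "focal") {
  key <- function(d) paste(d$chrom, d$start, d$end, sep = ":")
  fst_ab <- fst_ab[order(fst_ab$chrom, fst_ab$start), ]
  ka <- key(fst_ab)
  if (!setequal(ka, key(fst_ac)) || !setequal(ka, key(fst_bc)))
    stop("the three FST tracks must share one window grid")
  m_ac <- fst_ac$fst[match(ka, key(fst_ac))]
  m_bc <- fst_bc$fst[match(ka, key(fst_bc))]
  ok <- !is.na(fst_ab$fst) & !is.na(m_ac) & !is.na(m_bc)
  out <- data.frame(chrom = fst_ab$chrom, start = fst_ab$start,
                    end = fst_ab$end, fst_ab = fst_ab$fst, fst_ac = m_ac,
                    fst_bc = m_bc, stringsAsFactors = FALSE)[ok, ]
  out$t_ab <- as.numeric(branch_length(out$fst_ab))
  out$t_ac <- as.numeric(branch_length(out$fst_ac))
  out$t_bc <- as.numeric(branch_length(out$fst_bc))
  out$pbs <- pbs(out$t_ab, out$t_ac, out$t_bc)
  out$focal <- focal
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Empirical-quantile outliers
#'
#' The threshold is the empirical quantile (linear interpolation, type 7)
#' of the defined values; members lie strictly above it, so a constant
#' vector yields an empty set.
#'
#' @param values numeric statistic values (NAs dropped).
#' @param q quantile (default 0.99).
#' @return list of class `outlier_set`: `threshold`, `q`, `index`
#'   (positions in `values` strictly above the threshold), `values`.
#' @export
outlier_windows <- function(values, q = 0.99) {
  v <- values
  defined <- which(!is.na(v))
  if (length(defined) == 0) stop("no defined values")
  thr <- stats::quantile(v[defined], q, names = FALSE, type = 7)
  idx <- defined[v[defined] > thr]
  structure(list(threshold = thr, q = q, index = idx, values = v[idx]),
            class = "outlier_set")
}

#' @export
print.outlier_set <- function(x, ...) {
  cat(sprintf("outlier_set: %d values above the %.2f quantile (threshold %.6g)\n",
              length(x$index), x$q, x$threshold))
  invisible(x)
}
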