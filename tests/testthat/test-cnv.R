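make_pm <- function(n_per = 20) {
  data.frame(sample = sprintf("s%02d", seq_len(2 * n_per)),
             population = rep(c("A", "B"), each = n_per),
             stringsAsFactors = FALSE)
}

test_that("CNV FST behaves like SNP FST on carrier alleles", {
  pm <- make_pm(20)
  calls <- data.frame(chrom = "chr1", start = c(0, 1000, 2000),
                      end = c(500, 1500, 2500), svtype = "DUP")
  g <- rbind(c(rep(2, 20), rep(0, 20)),   # fixed difference
             rep(1, 40),                  # identical frequencies
             c(rep(c(0, 2), 10), rep(c(2, 0), 10)))
  colnames(g) <- pm$sample
  f <- cnv_fst(cnv_callset(calls, g), pm)
  expect_gte(f[1], 0.97)
  expect_identical(f[2], 0)
  # code-path equivalence with the SNP estimator on the same coding
  gm <- toy_gm(list(c(rep("1/1", 20), rep("0/0", 20))))
  cA <- divergescan:::site_counts(gm, 1:20)
  cB <- divergescan:::site_counts(gm, 21:40)
  wc <- site_wc_components(cA, cB, 2L)
  expect_identical(f[1], wc$a / (wc$a + wc$b + wc$c))
})

test_that("VST matches brute-force variance decomposition", {
  pm <- make_pm(2)
  copies <- c(2, 2, 4, 4); names(copies) <- pm$sample
  v <- vst(copies, pm)
  expect_equal(v$vst, 1)          # perfect between-population partition
  expect_equal(v$v_within, 0)
  copies2 <- c(2, 3, 4, 5); names(copies2) <- pm$sample
  v2 <- vst(copies2, pm)
  expect_equal(v2$vst, oracle_vst(copies2, pm$population), tolerance = 1e-12)
  # {2,2,3,3} vs {4,4,5,5}
  pm4 <- make_pm(4)
  copies3 <- c(2, 2, 3, 3, 4, 4, 5, 5); names(copies3) <- pm4$sample
  expect_equal(vst(copies3, pm4)$vst, oracle_vst(copies3, pm4$population),
               tolerance = 1e-12)
})

test_that("VST is near zero when both populations share a distribution", {
  pm <- make_pm(200)
  set.seed(2)
  copies <- rpois(400, 2); names(copies) <- pm$sample
  expect_lt(abs(vst(copies, pm)$vst), 0.05)
})

test_that("VST is undefined without variance or with tiny populations", {
  pm <- make_pm(3)
  cst <- rep(2, 6); names(cst) <- pm$sample
  expect_true(is.na(vst(cst, pm)$vst))
  few <- c(2, NA, NA, 4, 4, 4); names(few) <- pm$sample
  expect_true(is.na(vst(few, pm)$vst))
  # vst <= 1 always; negatives reported as-is
  set.seed(9)
  for (i in 1:20) {
    x <- rpois(12, 2); names(x) <- make_pm(6)$sample
    v <- vst(x, make_pm(6))$vst
    if (!is.na(v)) expect_lte(v, 1)
  }
})

test_that("cross-validation boundary: exactly 50% overlap is dropped", {
  mk <- function(df) cnv_callset(cbind(df, svtype = "DEL"))
  p <- mk(data.frame(chrom = "c", start = 0, end = 100))
  expect_false(cross_validate_calls(
    p, mk(data.frame(chrom = "c", start = 50, end = 100)))$keep)
  expect_true(cross_validate_calls(
    p, mk(data.frame(chrom = "c", start = 49, end = 100)))$keep)
  # identical call retained; disjoint dropped; svtype mismatch dropped
  expect_true(cross_validate_calls(
    p, mk(data.frame(chrom = "c", start = 0, end = 100)))$keep)
  expect_false(cross_validate_calls(
    p, mk(data.frame(chrom = "c", start = 200, end = 300)))$keep)
  q <- cnv_callset(data.frame(chrom = "c", start = 0, end = 100,
                              svtype = "DUP"))
  expect_false(cross_validate_calls(p, q)$keep)
})

test_that("cross-validation agrees with a quadratic brute-force oracle", {
  set.seed(17)
  truth <- simulate_cnv_truth(n_loci = 60, seq_length = 1e7, seed = 4)
  pm <- make_pm(10)
  cs <- simulate_cnv_callsets(truth, pm, jitter_bp = 500, fdr_a = 0.3,
                              fdr_b = 0.2, seed = 14)
  for (frac in c(0.3, 0.5, 0.8)) {
    cv <- cross_validate_calls(cs$callset_a, cs$callset_b, min_overlap = frac)
    expect_identical(cv$keep,
                     oracle_retained(cs$callset_a$calls, cs$callset_b$calls,
                                     frac))
  }
  # monotone in min_overlap
  k1 <- sum(cross_validate_calls(cs$callset_a, cs$callset_b, 0.3)$keep)
  k2 <- sum(cross_validate_calls(cs$callset_a, cs$callset_b, 0.6)$keep)
  k3 <- sum(cross_validate_calls(cs$callset_a, cs$callset_b, 0.9)$keep)
  expect_true(k1 >= k2 && k2 >= k3)
})

test_that("jitter-free validation keeps everything; FDR lowers retention", {
  truth <- simulate_cnv_truth(n_loci = 40, seq_length = 1e7, seed = 5)
  pm <- make_pm(10)
  clean <- simulate_cnv_callsets(truth, pm, jitter_bp = 0, fdr_a = 0,
                                 fdr_b = 0, seed = 15)
  cv <- cross_validate_calls(clean$callset_a, clean$callset_b)
  expect_true(all(cv$keep))
  # fdr_a = 0.5, jitter ~10% of length: retained fraction tracks the
  # true-call fraction of callset A (+-0.1 over ~200 primary calls)
  truth2 <- simulate_cnv_truth(n_loci = 100, seq_length = 4e7,
                               len_range = c(2000, 10000), seed = 6)
  noisy <- simulate_cnv_callsets(truth2, pm, jitter_bp = 300, fdr_a = 0.5,
                                 fdr_b = 0, seed = 16)
  cv2 <- cross_validate_calls(noisy$callset_a, noisy$callset_b)
  true_frac <- mean(noisy$callset_a$calls$is_true)
  expect_lt(abs(mean(cv2$keep) - true_frac), 0.1)
})

test_that("planted fixed differences are flagged as CNV outliers", {
  pm <- make_pm(20)
  set.seed(23)
  n <- 1000
  g <- matrix(rbinom(n * 40, 2, 0.3), n, 40)
  planted <- sample(n, 10)
  g[planted, ] <- rep(c(2, 0), each = 20)[col(g[planted, , drop = FALSE])]
  colnames(g) <- pm$sample
  calls <- data.frame(chrom = "chr1", start = (1:n - 1) * 1e4,
                      end = (1:n - 1) * 1e4 + 5000, svtype = "DEL")
  f <- cnv_fst(cnv_callset(calls, g), pm)
  o <- cnv_outliers(f, q = 0.99)
  expect_true(all(planted %in% o$index))
  expect_identical(length(cnv_outliers(rep(0.2, 100))$index), 0L)
})

test_that("outlier geometry: lengths and nearest-gene distances", {
  calls <- cnv_callset(data.frame(
    chrom = "c", start = c(1000, 2500, 5000, 8000, 20000),
    end = c(1100, 2600, 6000, 8400, 21000),
    svtype = c("DEL", "DEL", "DUP", "DUP", "DEL")))
  genes <- data.frame(chrom = "c", start = c(2000, 6500, 9000),
                      end = c(3000, 7000, 10000))
  geo <- summarize_outlier_geometry(calls, genes)
  # hand-enumerated: [1000,1100) to [2000,3000) -> gap 900
  expect_equal(geo$per_call$nearest_gene_bp,
               c(900, 0, 500, 600, 10000))
  expect_identical(geo$per_call$overlaps_gene, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  del <- geo$aggregate[geo$aggregate$svtype == "DEL", ]
  expect_equal(del$mean_length, mean(c(100, 100, 1000)))
  expect_equal(del$n_overlapping_genes, 1)
  # empty gene set: undefined distances
  geo0 <- summarize_outlier_geometry(calls, NULL)
  expect_true(all(is.na(geo0$per_call$nearest_gene_bp)))
})

test_that("FST-VST association: monotone, null, and planted-signal cases", {
  f <- seq(0.01, 0.5, length.out = 50)
  expect_equal(fst_vst_association(f, f^2)$rho, 1)
  set.seed(31)
  null <- fst_vst_association(runif(1000), runif(1000))
  expect_lt(abs(null$rho), 0.1)
  expect_error(fst_vst_association(runif(5), runif(5)), "at least 10")
  # shared latent signal in the simulator
  truth <- simulate_cnv_truth(n_loci = 80, seq_length = 2e7,
                              pop_freqs = cbind(runif(80, 0.05, 0.9),
                                                runif(80, 0.05, 0.9)),
                              seed = 7)
  pm <- make_pm(20)
  cs <- simulate_cnv_callsets(truth, pm, seed = 18)
  f2 <- cnv_fst(cs$callset_a, pm)[cs$truth_index_a]
  v2 <- vst_matrix(cs$copies, pm)$vst
  assoc <- fst_vst_association(f2, v2)
  expect_gt(assoc$rho, 0)
  expect_lt(assoc$p_value, 0.01)
})
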