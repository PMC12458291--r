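test_that("undiverged populations show near-zero genome-wide FST", {
  p <- sim_params(n_diploids_per_pop = 20, n_sites = 10000, seq_length = 1e6,
                  divergence_F = 0, prop_variant = 0.5, seed = 11)
  sim <- simulate_split_populations(p)
  ws <- windowed_stats(sim$gm, sim$popmap)
  genome_fst <- sum(ws$fst_a, na.rm = TRUE) / sum(ws$fst_abc, na.rm = TRUE)
  expect_lt(abs(genome_fst), 0.01)
})

test_that("Balding-Nichols drift parameter is recovered by the W-C estimator", {
  for (F in c(0.05, 0.1, 0.25)) {
    p <- sim_params(n_diploids_per_pop = 20, n_sites = 10000, seq_length = 1e6,
                    divergence_F = F, prop_variant = 0.5, seed = 101 + F * 100)
    sim <- simulate_split_populations(p)
    ws <- windowed_stats(sim$gm, sim$popmap)
    genome_fst <- sum(ws$fst_a, na.rm = TRUE) / sum(ws$fst_abc, na.rm = TRUE)
    expect_lt(abs(genome_fst - F), 0.02)
    # independent Hudson-style check on the emitted truth frequencies
    v <- sim$truth$variant
    hud <- oracle_hudson_fst(sim$truth$freq[v, 1], sim$truth$freq[v, 2],
                             k1 = 40, k2 = 40)
    expect_lt(abs(genome_fst - hud), 0.03)
  }
})

test_that("simulation is bit-identical under a fixed seed", {
  p <- sim_params(n_sites = 500, seq_length = 1e5, missing_rate = 0.1, seed = 9)
  s1 <- simulate_split_populations(p)
  s2 <- simulate_split_populations(p)
  expect_identical(s1$gm, s2$gm)
  expect_identical(s1$truth$freq, s2$truth$freq)
})

test_that("invariant-site fraction and missingness match their parameters", {
  p <- sim_params(n_sites = 10000, seq_length = 1e6, prop_variant = 0.3,
                  missing_rate = 0.07, seed = 21)
  sim <- simulate_split_populations(p)
  prop_inv <- mean(is.na(sim$gm$sites$alt))
  expect_lt(abs(prop_inv - 0.7), 3 * sqrt(0.3 * 0.7 / 10000) + 0.01)
  expect_lt(max(abs(colMeans(is.na(sim$gm$a1)) - 0.07)), 0.01)
})

test_that("too-small populations are rejected", {
  expect_error(sim_params(n_diploids_per_pop = 1), "pairwise")
})

test_that("PAR diversity multiplier of 1 leaves PAR and nonPAR comparable", {
  p <- sim_params(n_sites = 10000, seq_length = 1e7, divergence_F = 0.02,
                  prop_variant = 0.2, seed = 31)
  sx <- sexchrom_params(par_interval = c(0, 2.5e6), par_pi_multiplier = 1,
                        n_males = 5, n_females = 10)
  sim <- simulate_sex_chromosomes(p, sx)
  ws <- windowed_stats(sim$gm_x, sim$popmap, width = 1e5)
  pp <- partition_par(ws, c(0, 2.5e6), value_col = "pi_pop1",
                      n_boot = 200, seed = 1)
  ratio <- pp$par$mean / pp$nonpar$mean
  expect_gt(ratio, 0.8); expect_lt(ratio, 1.25)
})

test_that("PAR diversity multiplier is recovered downstream", {
  p <- sim_params(n_sites = 10000, seq_length = 1e7, divergence_F = 0.02,
                  prop_variant = 0.15, seed = 33)
  sx <- sexchrom_params(par_interval = c(0, 2.5e6), par_pi_multiplier = 3.5,
                        n_males = 5, n_females = 10)
  sim <- simulate_sex_chromosomes(p, sx)
  ws <- windowed_stats(sim$gm_x, sim$popmap, width = 1e5)
  pp <- partition_par(ws, c(0, 2.5e6), value_col = "pi_pop1",
                      n_boot = 200, seed = 1)
  ratio <- pp$par$mean / pp$nonpar$mean
  expect_lt(abs(ratio - 3.5) / 3.5, 0.2)
})

test_that("Y output is haploid, males only, and empty when no males", {
  p <- sim_params(n_sites = 1000, seq_length = 1e7, seed = 5)
  sx <- sexchrom_params(n_males = 4, n_females = 6)
  sim <- simulate_sex_chromosomes(p, sx)
  expect_identical(sim$gm_y$ploidy, 1L)
  expect_true(is.null(sim$gm_y$a2))
  expect_identical(ncol(sim$gm_y$a1), 2L * 4L)
  expect_true(all(grepl("^M_", sim$gm_y$samples)))
  sim0 <- simulate_sex_chromosomes(p, sexchrom_params(n_males = 0,
                                                      n_females = 6))
  expect_identical(length(sim0$gm_y$samples), 0L)
  expect_gt(nrow(sim0$gm_x$sites), 0)
})

test_that("a PAR outside the X is rejected", {
  p <- sim_params(n_sites = 100, seq_length = 1e5, seed = 1)
  expect_error(
    simulate_sex_chromosomes(p, sexchrom_params(par_interval = c(0, 2.5e6))),
    "par_interval")
})

test_that("CNV callsets are deterministic and track their truth", {
  truth <- simulate_cnv_truth(n_loci = 30, seq_length = 5e6, seed = 2)
  pm <- data.frame(sample = sprintf("s%02d", 1:40),
                   population = rep(c("A", "B"), each = 20))
  c1 <- simulate_cnv_callsets(truth, pm, jitter_bp = 100, fdr_a = 0.2,
                              fdr_b = 0.1, seed = 6)
  c2 <- simulate_cnv_callsets(truth, pm, jitter_bp = 100, fdr_a = 0.2,
                              fdr_b = 0.1, seed = 6)
  expect_identical(c1$callset_a$calls, c2$callset_a$calls)
  expect_identical(c1$copies, c2$copies)
  expect_identical(sum(c1$callset_a$calls$is_true), nrow(truth))
})

test_that("overlapping latent CNV loci are rejected", {
  truth <- simulate_cnv_truth(n_loci = 5, seq_length = 1e6, seed = 3)
  truth$start[2] <- truth$start[1]; truth$end[2] <- truth$end[1] + 10
  pm <- data.frame(sample = "s1", population = "A")
  expect_error(simulate_cnv_callsets(truth, pm, seed = 1), "disjoint")
})
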