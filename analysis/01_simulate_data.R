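#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system with known truth.
#
# Two diverged ecotype-like populations (20 diploids each) on an autosome,
# an X chromosome (females; high-diversity 2.5 Mb PAR) and a haploid male
# Y, plus dual CNV callsets over shared latent loci. Drift and diversity
# levels follow the divergence the downstream stages are designed to
# measure: autosomal differentiation near FST 0.035 with pi near 0.036,
# and a strongly differentiated, low-diversity Y (F 0.25, pi below 0.01).
# Everything is written under results/sim/ as plain text (all-sites VCFs,
# popmap TSV, truth JSON, copy-number TSV).

suppressPackageStartupMessages({
  library(divergescan)
  library(jsonlite)
})

dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)
seed <- 20260922

## autosome: 10 Mb, 20k emitted sites, F = 0.035, pi ~ 0.1 * 0.365 ~ 0.036
auto <- simulate_split_populations(
  sim_params(n_pops = 2, n_diploids_per_pop = 20, n_sites = 20000,
             seq_length = 1e7, divergence_F = 0.035, prop_variant = 0.1,
             missing_rate = 0.02, seed = seed),
  chrom = "chr1")
write_allsites_vcf(auto$gm, "results/sim/autosome_allsites.vcf")
write_popmap(auto$popmap, "results/sim/popmap_autosome.tsv")

## sex chromosomes: X with 2.5 Mb PAR at 3.5x diversity, haploid male Y
sex <- simulate_sex_chromosomes(
  sim_params(n_pops = 2, n_sites = 12000, seq_length = 1.2e7,
             divergence_F = 0.026, prop_variant = 0.06, missing_rate = 0.02,
             seed = seed + 1),
  sexchrom_params(par_interval = c(0, 2.5e6), par_pi_multiplier = 3.5,
                  n_males = 10, n_females = 10))
write_allsites_vcf(sex$gm_x, "results/sim/chrX_allsites.vcf")
write_popmap(sex$popmap, "results/sim/popmap_sex.tsv")
writeLines("chrX\t0\t2500000\tPAR", "results/sim/par.bed")

## Y: simulated directly at high drift and low diversity (males, haploid)
ysim <- simulate_sex_chromosomes(
  sim_params(n_pops = 2, n_sites = 8000, seq_length = 1.2e7,
             divergence_F = 0.25, prop_variant = 0.02, missing_rate = 0.02,
             seed = seed + 2),
  sexchrom_params(par_interval = c(0, 2.5e6), par_pi_multiplier = 1,
                  n_males = 10, n_females = 2))
write_allsites_vcf(ysim$gm_y, "results/sim/chrY_allsites.vcf")
write_popmap(ysim$popmap, "results/sim/popmap_y.tsv")

## dual CNV callsets over 120 latent loci with population-differentiated
## carrier frequencies; 10% endpoint jitter, FDR 0.3 / 0.15
cnv_truth <- simulate_cnv_truth(
  n_loci = 120, seq_length = 4e7, len_range = c(1000, 20000),
  pop_freqs = withr::with_seed(seed + 3,
    cbind(runif(120, 0.05, 0.8), runif(120, 0.05, 0.8))),
  seed = seed + 3)
cnv <- simulate_cnv_callsets(cnv_truth, auto$popmap, jitter_bp = 800,
                             fdr_a = 0.3, fdr_b = 0.15, seed = seed + 4)
write.table(cbind(cnv$callset_a$calls,
                  as.data.frame(cnv$callset_a$genotypes)),
            "results/sim/cnv_callset_a.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cnv$callset_b$calls, "results/sim/cnv_callset_b.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cbind(cnv_truth[, c("chrom", "start", "end", "svtype")],
                  as.data.frame(cnv$copies)),
            "results/sim/cnv_copy_number.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## truth record for downstream recovery checks
write_json(list(
  autosome = list(divergence_F = 0.035, prop_variant = 0.1, seed = seed),
  chrX = list(divergence_F = 0.026, par_interval = c(0, 2.5e6),
              par_pi_multiplier = 3.5),
  chrY = list(divergence_F = 0.25, prop_variant = 0.02),
  cnv = list(n_loci = 120, jitter_bp = 800, fdr_a = 0.3, fdr_b = 0.15,
             truth_index_a = cnv$truth_index_a)),
  "results/sim/truth.json", auto_unbox = TRUE, digits = NA)

message("simulated: ", nrow(auto$gm$sites), " autosomal sites, ",
        nrow(sex$gm_x$sites), " X sites, ", nrow(ysim$gm_y$sites),
        " Y sites, ", nrow(cnv$callset_a$calls), " CNV calls (A) / ",
        nrow(cnv$callset_b$calls), " (B) over ", nrow(cnv_truth),
        " latent loci -> results/sim/")
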