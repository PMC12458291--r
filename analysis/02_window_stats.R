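#!/usr/bin/env Rscript
# Stage 2: windowed pi, dXY and Weir-Cockerham FST in 50 kb windows, with
# 10,000-replicate bootstrap CIs, the PAR/nonPAR partition of the X, and
# the Y:autosome diversity ratio. Consumes the all-sites VCFs written by
# 01_simulate_data.R.

suppressPackageStartupMessages(library(divergescan))
if (!file.exists("results/sim/autosome_allsites.vcf"))
  stop("run analysis/01_simulate_data.R first")
dir.create("results/window_stats", recursive = TRUE, showWarnings = FALSE)

summarize <- function(ws, label, cols) {
  rows <- lapply(cols, function(cl) {
    gs <- genome_summary(ws[[cl]], n_boot = 10000, seed = 99)
    data.frame(dataset = label, stat = cl, mean = gs$mean,
               ci_low = gs$ci_low, ci_high = gs$ci_high,
               half_width = gs$half_width, n_windows = gs$n_windows)
  })
  do.call(rbind, rows)
}

## autosomes
gm_a <- read_allsites_vcf("results/sim/autosome_allsites.vcf")
pm_a <- read_popmap("results/sim/popmap_autosome.tsv")
gm_a <- filter_biallelic_snps(gm_a)$gm
ws_a <- windowed_stats(gm_a, pm_a, width = 50000)
write.table(ws_a, "results/window_stats/autosome_windows.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sum_a <- summarize(ws_a, "autosomes", c("fst", "dxy", "pi_pop1", "pi_pop2"))

## X chromosome, females only; PAR vs nonPAR pi
gm_x <- read_allsites_vcf("results/sim/chrX_allsites.vcf")
pm_x <- read_popmap("results/sim/popmap_sex.tsv")
ws_x <- windowed_stats(gm_x, pm_x, width = 50000)
write.table(ws_x, "results/window_stats/chrX_windows.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sum_x <- summarize(ws_x, "chrX", c("fst", "dxy", "pi_pop1", "pi_pop2"))
par_bed <- read_bed("results/sim/par.bed")
pp <- partition_par(ws_x, c(par_bed$start[1], par_bed$end[1]),
                    value_col = "pi_pop1", n_boot = 10000, seed = 99)
message(sprintf("X pi PAR %.4f vs nonPAR %.4f (ratio %.2f; simulated 3.5)",
                pp$par$mean, pp$nonpar$mean, pp$par$mean / pp$nonpar$mean))

## Y chromosome, males only, haploid
gm_y <- read_allsites_vcf("results/sim/chrY_allsites.vcf", ploidy = 1)
pm_y <- read_popmap("results/sim/popmap_y.tsv")
ws_y <- windowed_stats(gm_y, pm_y, width = 50000)
write.table(ws_y, "results/window_stats/chrY_windows.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sum_y <- summarize(ws_y, "chrY", c("fst", "dxy", "pi_pop1", "pi_pop2"))

summary_tab <- rbind(sum_a, sum_x, sum_y)
write.table(summary_tab, "results/window_stats/genome_summaries.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(summary_tab, digits = 3)

## Y:autosome diversity ratios, simulated and published worked values
pi_auto <- sum_a$mean[sum_a$stat == "pi_pop1"]
pi_y <- sum_y$mean[sum_y$stat == "pi_pop1"]
sim_ratio <- ya_diversity_ratio(pi_y, pi_auto)
message(sprintf("simulated Y:A diversity ratio (pop1): %s (raw %.4f)",
                sim_ratio$display, sim_ratio$raw))
message(sprintf("published worked values: common %s, white %s",
                ya_diversity_ratio(0.006, 0.0363)$display,
                ya_diversity_ratio(0.0106, 0.0358)$display))
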