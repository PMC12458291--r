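#!/usr/bin/env Rscript
# Stage 5: genotype PCA of the simulated SNP and CNV data. Expect tight
# ecotype clusters on PC1 for the autosomal SNPs, and the CNV PCA to
# mirror the SNP structure on the shared latent differentiation.

suppressPackageStartupMessages(library(divergescan))
if (!file.exists("results/sim/autosome_allsites.vcf"))
  stop("run analysis/01_simulate_data.R first")
dir.create("results/pca", recursive = TRUE, showWarnings = FALSE)

gm <- read_allsites_vcf("results/sim/autosome_allsites.vcf")
pm <- read_popmap("results/sim/popmap_autosome.tsv")
snp_pca <- genotype_pca(gm, n_components = 10)
coords <- data.frame(sample = rownames(snp_pca$coordinates),
                     population = pm$population[match(
                       rownames(snp_pca$coordinates), pm$sample)],
                     snp_pca$coordinates)
write.table(coords, "results/pca/snp_coordinates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(component = seq_along(snp_pca$pct_variance),
                       pct_variance = snp_pca$pct_variance),
            "results/pca/snp_scree.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
pc1 <- snp_pca$coordinates[, 1]
sep <- max(pc1[coords$population == "pop1"]) < min(pc1[coords$population == "pop2"]) ||
       max(pc1[coords$population == "pop2"]) < min(pc1[coords$population == "pop1"])
message(sprintf("SNP PCA: PC1 %.2f%%, PC2 %.2f%% of variance; PC1 separates populations: %s",
                snp_pca$pct_variance[1], snp_pca$pct_variance[2], sep))

## CNV PCA from the carrier-dosage genotypes
raw_a <- read.table("results/sim/cnv_callset_a.tsv", sep = "\t", header = TRUE)
meta <- c("chrom", "start", "end", "svtype", "is_true", "quality")
g <- as.matrix(raw_a[setdiff(names(raw_a), meta)])
gm_cnv <- genotype_matrix(
  data.frame(chrom = raw_a$chrom, pos = seq_len(nrow(g)), ref = "A",
             alt = "T", stringsAsFactors = FALSE),
  ifelse(g >= 1, 1L, 0L), ifelse(g >= 2, 1L, 0L),
  samples = colnames(g), ploidy = 2L)
cnv_pca <- genotype_pca(gm_cnv, n_components = 5)
write.table(data.frame(sample = rownames(cnv_pca$coordinates),
                       cnv_pca$coordinates),
            "results/pca/cnv_coordinates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("CNV PCA: PC1 %.2f%% of variance over %d loci",
                cnv_pca$pct_variance[1], cnv_pca$n_variants_used))
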