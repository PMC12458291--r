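#!/usr/bin/env Rscript
# Stage 4: CNV population genetics on the dual callsets from stage 1:
# minimum ALT-occurrence filter (carrier allele at least 8 times across
# all individuals), cross-validation by > 50% length overlap against the
# second callset, carrier-allele Weir-Cockerham FST, copy-number VST,
# 0.99-quantile outliers, nearest-gene geometry, and the FST-VST rank
# correlation.

suppressPackageStartupMessages({
  library(divergescan)
  library(jsonlite)
})
if (!file.exists("results/sim/cnv_callset_a.tsv"))
  stop("run analysis/01_simulate_data.R first")
dir.create("results/cnv", recursive = TRUE, showWarnings = FALSE)

pm <- read_popmap("results/sim/popmap_autosome.tsv")
raw_a <- read.table("results/sim/cnv_callset_a.tsv", sep = "\t", header = TRUE)
meta <- c("chrom", "start", "end", "svtype", "is_true", "quality")
callset_a <- cnv_callset(raw_a[meta],
                         as.matrix(raw_a[setdiff(names(raw_a), meta)]))
callset_b <- cnv_callset(read.table("results/sim/cnv_callset_b.tsv",
                                    sep = "\t", header = TRUE))
cn <- read.table("results/sim/cnv_copy_number.tsv", sep = "\t", header = TRUE)
copies <- as.matrix(cn[setdiff(names(cn), c("chrom", "start", "end", "svtype"))])
truth <- fromJSON("results/sim/truth.json")

## allele-count filter, then dual-caller cross-validation
flt <- enforce_min_alt_occurrences(callset_a, min_count = 8)
message(sprintf("ALT-occurrence filter (>= 8): %d -> %d calls",
                nrow(callset_a$calls), nrow(flt$calls)))
cv <- cross_validate_calls(flt, callset_b, min_overlap = 0.5)
message(sprintf("cross-validated (> 50%% length overlap): %d of %d retained; true-call precision %.2f",
                sum(cv$keep), length(cv$keep),
                mean(cv$retained$calls$is_true)))

## differentiation: carrier-allele FST and copy-number VST
fst <- cnv_fst(flt, pm)
vst_tab <- vst_matrix(copies, pm)
o <- cnv_outliers(fst, q = 0.99)
message(sprintf("CNV FST: mean %.3f; %d outliers above the 0.99 quantile",
                mean(fst, na.rm = TRUE), length(o$index)))

## geometry of the outliers against a synthetic gene annotation
genes <- withr::with_seed(7, {
  s <- sort(sample.int(4e7 - 5e4, 300))
  data.frame(chrom = "chr1", start = s, end = s + round(runif(300, 2e3, 3e4)))
})
out_calls <- cnv_callset(flt$calls[o$index, , drop = FALSE])
geo <- summarize_outlier_geometry(out_calls, genes)
message(sprintf("outlier CNVs: mean distance to nearest gene %.0f bp; %d overlap genes",
                mean(geo$per_call$nearest_gene_bp, na.rm = TRUE),
                sum(geo$per_call$overlaps_gene, na.rm = TRUE)))

## FST-VST association over the true loci (shared latent signal)
fst_true <- cnv_fst(callset_a, pm)[truth$cnv$truth_index_a]
assoc <- fst_vst_association(fst_true, vst_tab$vst)
message(sprintf("FST-VST Spearman rho = %.3f (p = %.3g, n = %d)",
                assoc$rho, assoc$p_value, assoc$n))

per_locus <- cbind(flt$calls[c("chrom", "start", "end", "svtype")],
                   fst = fst, outlier = seq_along(fst) %in% o$index,
                   cross_validated = cv$keep,
                   length = flt$calls$end - flt$calls$start)
write.table(per_locus, "results/cnv/per_locus.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cbind(cn[c("chrom", "start", "end", "svtype")], vst_tab),
            "results/cnv/vst.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cv$report, "results/cnv/cross_validation_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(geo$aggregate, "results/cnv/outlier_geometry.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
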