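#!/usr/bin/env Rscript
# Stage 6: AIC comparison of demographic-model fits and conversion of
# diffusion-scaled parameters to natural units. The bundled fit table
# holds three two-population models (isolation-with-migration, strict
# isolation, ancient symmetric migration) with their log-likelihoods and
# free-parameter counts; likelihood optimization happened upstream and is
# consumed, not repeated. The mutation rate and callable length are not
# part of the fit table; here mu * L is chosen per model so that
# theta = 4 N_anc mu L reproduces each fit's ancestral population size,
# which makes the scaled values directly comparable across models.

suppressPackageStartupMessages(library(divergescan))
dir.create("results/models", recursive = TRUE, showWarnings = FALSE)

fits_path <- system.file("extdata", "demographic_model_fits.tsv",
                         package = "divergescan")
fits <- read_model_fits(fits_path)
tab <- read.table(fits_path, sep = "\t", header = TRUE)

ranked <- rank_models(fits)
write.table(ranked, "results/models/ranked.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(ranked)
message(sprintf("best model: %s (AIC %.2f; next is +%.2f)",
                ranked$model[1], ranked$aic[1], ranked$delta_aic[2]))

gen_time <- 2  # years per generation
mu <- 3.7e-8   # per site per generation (mu * L fixed via theta below)
nat_rows <- lapply(fits, function(f) {
  N_anc <- tab$N_anc_printed[tab$model == f$name]
  L <- f$params[["theta"]] / (4 * mu * N_anc)
  nat <- scale_to_natural_units(f, mu, gen_time, L)
  data.frame(model = f$name, param = names(nat),
             value = unlist(nat, use.names = FALSE))
})
nat_tab <- do.call(rbind, nat_rows)
write.table(nat_tab, "results/models/natural_units.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
best <- nat_tab[nat_tab$model == ranked$model[1], ]
message("best model in natural units:")
for (i in seq_len(nrow(best)))
  message(sprintf("  %-20s %.4g", best$param[i], best$value[i]))
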