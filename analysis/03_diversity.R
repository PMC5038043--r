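# Alpha diversity: richness and Shannon index averaged over 100
# rarefactions to 5000 reads per sample, then backward stepwise linear
# models relating each index to the clinical and technical covariates.
source("analysis/00_settings.R")

counts <- read_count_table(file.path(DATA_DIR, "counts.tsv"))
meta <- read_metadata(file.path(DATA_DIR, "metadata.tsv"))
al <- align_samples(counts, meta)

div <- alpha_diversity(al$counts, depth = 5000, iterations = 100,
                       seed = SEEDS$diversity)
write.table(div, file.path(OUT_DIR, "diversity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d/%d samples had >= 5000 reads and were estimated.\n",
            sum(!div$excluded), nrow(div)))

covars <- al$meta[, c("bop", "periodontitis", "site", "intervention", "hiv",
                      "seqrun", "age", "bmi", "education", "ses", "anemia",
                      "malaria")]
models <- list()
for (resp in c("richness", "shannon")) {
  fit <- backward_stepwise_lm(div[[resp]][!div$excluded],
                              covars[!div$excluded, ])
  models[[resp]] <- list(retained = fit$retained,
                         coefficients = fit$coefficients,
                         aic_trace = fit$aic_trace)
  cat(sprintf("\n%s ~ retained terms after backward AIC: %s\n", resp,
              paste(fit$retained, collapse = ", ")))
  b <- fit$coefficients
  if ("bop" %in% b$term)
    cat(sprintf("  per-sextant change in %s: %+.3f (SE %.3f)\n", resp,
                b$estimate[b$term == "bop"], b$se[b$term == "bop"]))
}
jsonlite::write_json(models, file.path(OUT_DIR, "diversity_models.json"),
                     auto_unbox = TRUE, digits = NA)
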