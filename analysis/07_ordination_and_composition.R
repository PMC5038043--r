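# Community-level views: Bray-Curtis PCoA of all samples, and the summed
# relative abundance of the gingivitis-associated taxa per disease
# stratum with Kruskal-Wallis comparisons between periodontitis groups.
source("analysis/00_settings.R")

counts <- read_count_table(file.path(DATA_DIR, "counts.tsv"))
meta <- read_metadata(file.path(DATA_DIR, "metadata.tsv"))
truth <- jsonlite::read_json(file.path(DATA_DIR, "truth.json"),
                             simplifyVector = TRUE)
al <- align_samples(counts, meta)

d <- bray_curtis(al$counts)
ord <- pcoa_ordination(d)
coords <- data.frame(sample_id = rownames(ord$coordinates),
                     ord$coordinates[, 1:2],
                     bop = al$meta$bop,
                     periodontitis = al$meta$periodontitis)
write.table(coords, file.path(OUT_DIR, "pcoa_coordinates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("PCoA: first two axes explain %.1f%% and %.1f%% of the positive inertia (%d negative eigenvalues dropped).\n",
            100 * ord$prop_var[1], 100 * ord$prop_var[2], ord$n_negative))

eff <- truth$effect_table
ging_up <- eff$taxon_id[eff$beta_bop > 0]
res <- group_summed_abundance(al$counts, ging_up, al$meta, depth = 10000,
                              seed = SEEDS$summed)
write.table(res, file.path(OUT_DIR, "summed_gingivitis_taxa.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d samples rarefied to 10000 reads (%d excluded).\n",
            nrow(res), length(attr(res, "excluded"))))
med <- tapply(res$summed_pct, res$bop, median)
cat("Median summed % of gingivitis-associated taxa by BoP:",
    paste(sprintf("%d:%.2f", as.integer(names(med)), med), collapse = " "),
    "\n")

# within each severity, compare women with and without periodontitis
for (b in sort(unique(res$bop))) {
  sub <- res[res$bop == b, ]
  if (length(unique(sub$periodontitis)) < 2 ||
      min(table(sub$periodontitis)) < 5) next
  kw <- kruskal_wallis_test(split(sub$summed_pct, sub$periodontitis))
  cat(sprintf("BoP %d: Kruskal-Wallis H = %.2f, p = %.3f (n = %d)\n",
              b, kw$statistic, kw$p_value, nrow(sub)))
}
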