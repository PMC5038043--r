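# Joint negative-binomial differential abundance: BoP as continuous
# gingivitis severity and periodontitis as a binary factor, adjusted for
# site, intervention, HIV and sequencing run, with BH correction; checked
# against the generator's ground truth.
source("analysis/00_settings.R")

counts <- read_count_table(file.path(DATA_DIR, "counts.tsv"))
meta <- read_metadata(file.path(DATA_DIR, "metadata.tsv"))
truth <- jsonlite::read_json(file.path(DATA_DIR, "truth.json"),
                             simplifyVector = TRUE)

da <- run_differential_abundance(counts, meta)
print(da)

for (tab in c("bop", "periodontitis", "intersection"))
  write.table(da[[tab]], file.path(OUT_DIR, sprintf("diffabund_%s.tsv", tab)),
              sep = "\t", quote = FALSE, row.names = FALSE)

eff <- truth$effect_table
true_bop <- eff$taxon_id[eff$beta_bop != 0]
true_perio <- eff$taxon_id[eff$beta_perio_effective != 0]
bop_hits <- da$bop$taxon_id[da$bop$significant]
perio_hits <- da$periodontitis$taxon_id[da$periodontitis$significant]
cat(sprintf("\nBoP: %d/%d truly affected taxa recovered (plus %d other hits).\n",
            length(intersect(true_bop, bop_hits)), length(true_bop),
            length(setdiff(bop_hits, true_bop))))
cat(sprintf("Periodontitis: %d/%d truly affected taxa recovered (plus %d other hits).\n",
            length(intersect(true_perio, perio_hits)), length(true_perio),
            length(setdiff(perio_hits, true_perio))))
strongest <- da$bop[which.max(abs(da$bop$wald_z) * da$bop$significant), ]
cat(sprintf("Strongest gingivitis association: %s, %.2f-fold per sextant (true fold for the strongest planted taxon: 1.45).\n",
            strongest$taxon_id, strongest$fold_change))
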