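# Simulate the synthetic study cohort: 500 women sampled with the
# published severity/periodontitis marginals, 100 taxa with a stable
# abundant core, disease-associated effect blocks, and latent
# cooccurrence modules (periodontitis-active and health-active). All
# downstream drivers consume the files written here.
source("analysis/00_settings.R")

cfg <- generator_config(n_samples = 500, n_taxa = 100)
meta <- sample_cohort_metadata(cfg, seed = SEEDS$metadata)
gen <- generate_counts(meta, cfg, seed = SEEDS$counts)
ref <- random_reference_sequence(cfg$seq_length, seed = SEEDS$sequences)
seqs <- generate_sequences(cfg$n_taxa, ref, cfg$seq_identity_targets,
                           seed = SEEDS$sequences, taxon_ids = cfg$taxon_ids)

write_count_table(gen$counts, file.path(DATA_DIR, "counts.tsv"))
write_metadata(meta, file.path(DATA_DIR, "metadata.tsv"))
write_fasta(seqs, file.path(DATA_DIR, "seqs.fasta"))
jsonlite::write_json(
  list(effect_table = gen$truth$effect_table,
       module_membership = gen$truth$module_membership),
  file.path(DATA_DIR, "truth.json"), auto_unbox = TRUE, digits = NA)

ls <- gen$truth$libsize
cat(sprintf("Simulated %d samples x %d taxa.\n", ncol(gen$counts),
            nrow(gen$counts)))
cat(sprintf("Drawn library sizes: mean %.0f reads (target 13565), SD %.0f (target 6833).\n",
            mean(ls), sd(ls)))
cat(sprintf("Periodontitis prevalence: %.1f%% (cohort value 31.9%%).\n",
            100 * mean(meta$periodontitis)))
cat(sprintf("Gingivitis (BoP >= 1): %.1f%% (cohort value 85.4%%).\n",
            100 * mean(meta$bop >= 1)))
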