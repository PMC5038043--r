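# Select the phylotypes whose representative sequences lie strictly above
# 98.5% global identity to any periodontitis-associated taxon (the
# network node set), mirroring species-level reference clustering.
source("analysis/00_settings.R")

seqs <- read_fasta(file.path(DATA_DIR, "seqs.fasta"))
perio <- read.delim(file.path(OUT_DIR, "diffabund_periodontitis.tsv"))
hits <- perio$taxon_id[perio$significant & perio$beta > 0]
cat(sprintf("%d periodontitis-associated taxa at q < 0.05.\n", length(hits)))

sel <- select_by_identity(seqs, seqs[hits], threshold = 98.5)
write.table(sel, file.path(OUT_DIR, "selection.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d phylotypes above 98.5%% identity to a periodontitis-associated taxon\n",
            sum(sel$selected)))
cat("Selected:", paste(sel$query_id[sel$selected], collapse = " "), "\n")
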