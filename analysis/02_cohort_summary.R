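# Descriptive statistics: exact recomputation of the published cohort
# breakdown from the printed stratum table, and the same summary for the
# simulated cohort.
source("analysis/00_settings.R")

cat("== Published cohort, recomputed from the printed stratum table ==\n")
printed <- cohort_summary(expand_table2())
print(printed)

cat("\n== Simulated cohort ==\n")
meta <- read_metadata(file.path(DATA_DIR, "metadata.tsv"))
sim <- cohort_summary(meta)
print(sim)

for (nm in c("printed", "sim")) {
  cs <- get(nm)
  jsonlite::write_json(cs[setdiff(names(cs), "strata")],
                       file.path(OUT_DIR, sprintf("cohort_%s.json", nm)),
                       auto_unbox = TRUE, digits = NA)
  write.table(cs$strata, file.path(OUT_DIR, sprintf("cohort_%s_strata.tsv", nm)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
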