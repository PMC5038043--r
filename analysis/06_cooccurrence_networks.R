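# Cooccurrence structure of the selected phylotypes: SparCC correlation
# matrices per disease stratum, a strong-edge network with permutation
# significance for the most severe periodontitis stratum, betweenness
# ranking of its hubs, and Mantel-distance clustering of all strata.
source("analysis/00_settings.R")

counts <- read_count_table(file.path(DATA_DIR, "counts.tsv"))
meta <- read_metadata(file.path(DATA_DIR, "metadata.tsv"))
sel <- read.delim(file.path(OUT_DIR, "selection.tsv"))
nodes <- sel$query_id[sel$selected]
al <- align_samples(counts, meta)
counts <- al$counts; meta <- al$meta

MIN_N <- 25
strata <- unique(meta[, c("bop", "periodontitis")])
strata <- strata[order(strata$bop, strata$periodontitis), ]
strata$n <- mapply(function(b, p) sum(meta$bop == b & meta$periodontitis == p),
                   strata$bop, strata$periodontitis)
strata <- strata[strata$n >= MIN_N, ]
for (k in seq_len(nrow(strata))) {
  idx <- meta$bop == strata$bop[k] & meta$periodontitis == strata$periodontitis[k]
  nodes <- nodes[rowSums(counts[nodes, idx, drop = FALSE]) > 0]
}
cat(sprintf("%d strata with n >= %d; %d shared non-zero nodes.\n",
            nrow(strata), MIN_N, length(nodes)))

mats <- list()
for (k in seq_len(nrow(strata))) {
  key <- sprintf("bop%d_perio%s", strata$bop[k],
                 ifelse(strata$periodontitis[k], "yes", "no"))
  idx <- meta$bop == strata$bop[k] & meta$periodontitis == strata$periodontitis[k]
  mats[[key]] <- sparcc(counts[nodes, idx], seed = SEEDS$networks + k)$corr
  write.table(data.frame(taxon_id = rownames(mats[[key]]), mats[[key]],
                         check.names = FALSE),
              file.path(OUT_DIR, sprintf("corr_%s.tsv", key)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

# focal strong-edge network: most severe periodontitis stratum
pk <- which(strata$periodontitis)
focal <- pk[which.max(strata$bop[pk])]
key <- sprintf("bop%d_perioyes", strata$bop[focal])
idx <- meta$bop == strata$bop[focal] & meta$periodontitis
pv <- permutation_pvalues(counts[nodes, idx], mats[[key]], n_perm = 100,
                          seed = SEEDS$permutations)
thr <- strong_edge_cutoff(mats[[key]])
net <- build_network(mats[[key]], pv, thr)
print(net)
write.table(net$edges, file.path(OUT_DIR, "network_edges.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_network_graphml(net, file.path(OUT_DIR, "network.graphml"))
xy <- layout_fr(net, seed = SEEDS$layout)
write.table(data.frame(node = rownames(xy), xy),
            file.path(OUT_DIR, "network_layout.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
bt <- betweenness_ranking(net)
write.table(bt, file.path(OUT_DIR, "betweenness.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Top hub by betweenness: %s (%.0f shortest paths); the planted bridge taxon is T026.\n",
            bt$node[1], bt$betweenness[1]))

cl <- cluster_strata(mats)
writeLines(cl$newick, file.path(OUT_DIR, "dendrogram.newick"))
write.table(as.matrix(cl$distances), file.path(OUT_DIR, "mantel_distances.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
grp <- stats::cutree(cl$hclust, k = 2)
perio_side <- grepl("perioyes", names(grp))
clean <- length(unique(grp[perio_side])) == 1 &&
  length(unique(grp[!perio_side])) == 1
cat(sprintf("Dendrogram top split separates periodontitis strata cleanly: %s\n",
            ifelse(clean, "yes", "no")))
cat("Newick:", cl$newick, "\n")
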