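#' Strong-edge correlation cutoff
#'
#' The threshold above which a pairwise correlation is considered strong:
#' the upper bound of the 95% interval for the mean correlation between
#' nodes, `mean + 1.96 * SD` of the off-diagonal (upper-triangle)
#' correlations, with the population SD.
#'
#' @param corr symmetric correlation matrix.
#' @return scalar threshold.
#' @export
strong_edge_cutoff <- function(corr) {
  x <- corr[upper.tri(corr)]
  if (length(x) < 2) stop("need at least 2 off-diagonal correlations")
  mean(x) + 1.96 * sqrt(mean((x - mean(x))^2))
}

#' Build a strong-edge cooccurrence network
#'
#' Edges connect pairs with correlation strictly above the threshold and
#' permutation p strictly below the significance level; nodes left without
#' any edge are removed from the network and counted.
#'
#' @param corr correlation matrix.
#' @param pvals p-value matrix conformable with `corr`.
#' @param threshold correlation cutoff (e.g. from [strong_edge_cutoff()]).
#' @param significance edge significance level (default 0.05).
#' @return list of class `cooccurrence_network` with `node_ids`, `corr`,
#'   `pvals` (restricted to kept nodes), `threshold`, `significance`,
#'   `edges` (data.frame `node_a`, `node_b`, `rho`, `p`), and
#'   `dropped_nodes`.
#' @export
build_network <- function(corr, pvals, threshold, significance = 0.05) {
  stopifnot(all(dim(corr) == dim(pvals)))
  ids <- rownames(corr)
  idx <- which(upper.tri(corr) & corr > threshold & pvals < significance,
               arr.ind = TRUE)
  edges <- data.frame(
    node_a = ids[idx[, 1]], node_b = ids[idx[, 2]],
    rho = corr[idx], p = pvals[idx],
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  keep <- ids %in% c(edges$node_a, edges$node_b)
  structure(list(
    node_ids = ids[keep],
    corr = corr[keep, keep, drop = FALSE],
    pvals = pvals[keep, keep, drop = FALSE],
    threshold = threshold,
    significance = significance,
    edges = edges,
    dropped_nodes = ids[!keep]
  ), class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf(
    "Cooccurrence network: %d nodes, %d edges (rho > %.3f, p < %g); %d isolated nodes removed\n",
    length(x$node_ids), nrow(x$edges), x$threshold, x$significance,
    length(x$dropped_nodes)))
  invisible(x)
}

.net_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("node_a", "node_b", "rho")],
                                directed = FALSE,
                                vertices = data.frame(name = net$node_ids))
}

#' Rank network nodes by betweenness centrality
#'
#' Shortest-path betweenness (Brandes' algorithm, unnormalized,
#' undirected). Unweighted by default; the weighted variant uses `1 / rho`
#' as edge length so stronger correlations are shorter paths. Ties are
#' broken by node id; ordering is by descending centrality.
#'
#' @param net `cooccurrence_network`.
#' @param weighted use `1 / rho` edge lengths (default `FALSE`).
#' @return data.frame `node`, `betweenness`, ordered by rank.
#' @export
betweenness_ranking <- function(net, weighted = FALSE) {
  if (length(net$node_ids) < 3) stop("need at least 3 nodes")
  g <- .net_igraph(net)
  w <- if (weighted) 1 / net$edges$rho else NA
  b <- igraph::betweenness(g, directed = FALSE, weights = w)
  out <- data.frame(node = names(b), betweenness = unname(b),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$betweenness, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mantel correlation between two correlation matrices
#'
#' Pearson correlation between the vectorized strict upper triangles of
#' two conformable matrices over the same node set; the associated Mantel
#' distance is `1 - r`. Node sets must match exactly (no implicit
#' intersection).
#'
#' @param corr_a,corr_b square matrices with identical dimnames.
#' @return scalar correlation in [-1, 1].
#' @export
mantel_r <- function(corr_a, corr_b) {
  if (!identical(dim(corr_a), dim(corr_b)) ||
      !identical(rownames(corr_a), rownames(corr_b)))
    stop("matrices must share an identical node set and order")
  if (nrow(corr_a) < 3) stop("need at least 3 nodes")
  cor(corr_a[upper.tri(corr_a)], corr_b[upper.tri(corr_b)])
}

#' Mantel distance (1 - Mantel r)
#' @inheritParams mantel_r
#' @return scalar distance.
#' @export
mantel_distance <- function(corr_a, corr_b) 1 - mantel_r(corr_a, corr_b)

#' Cluster disease strata by the similarity of their correlation matrices
#'
#' Agglomerative clustering (complete linkage by default) on the pairwise
#' Mantel distances between per-stratum correlation matrices. Unadjusted
#' (pre-significance) correlation matrices should be supplied, since the
#' strata differ in sample size and hence permutation power. The
#' dendrogram is also serialized as a Newick string with branch lengths
#' taken from the merge heights.
#'
#' @param mats named list (>= 2) of correlation matrices over a common
#'   node set.
#' @param linkage hclust agglomeration method (default `"complete"`).
#' @return list of class `strata_clustering` with `hclust`, `distances`
#'   (dist object of Mantel distances), `newick`.
#' @export
cluster_strata <- function(mats, linkage = "complete") {
  if (length(mats) < 2) stop("need at least 2 strata")
  if (is.null(names(mats)) || anyDuplicated(names(mats)))
    stop("strata must be uniquely named")
  k <- length(mats)
  D <- matrix(0, k, k, dimnames = list(names(mats), names(mats)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    D[i, j] <- D[j, i] <- mantel_distance(mats[[i]], mats[[j]])
  hc <- hclust(as.dist(D), method = linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, distances = as.dist(D), newick = newick),
            class = "strata_clustering")
}

#' @export
print.strata_clustering <- function(x, ...) {
  cat("Mantel-distance clustering of", length(x$hclust$labels), "strata (",
      x$hclust$method, "linkage )\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Fruchterman-Reingold layout for a cooccurrence network
#'
#' Force-directed 2-D coordinates for export alongside the edge list; the
#' layout plays no analytic role. Deterministic given the seed.
#'
#' @param net `cooccurrence_network`.
#' @param seed integer RNG seed.
#' @param niter iterations of the force simulation (default 500).
#' @return numeric matrix (nodes x 2) with node ids as row names.
#' @export
layout_fr <- function(net, seed = 1, niter = 500) {
  if (length(net$node_ids) == 0) stop("empty network")
  g <- .net_igraph(net)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, niter = niter)
  rownames(xy) <- net$node_ids
  colnames(xy) <- c("x", "y")
  xy
}

#' Write a cooccurrence network to GraphML
#'
#' @param net `cooccurrence_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  g <- .net_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
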