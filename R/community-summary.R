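#' Bray-Curtis dissimilarities between samples
#'
#' `d(u, v) = 1 - 2 sum(min(u_i, v_i)) / (sum(u) + sum(v))`, computed with
#' \pkg{vegan}. All-zero samples are rejected by name, since their
#' dissimilarity is undefined.
#'
#' @param counts count matrix (taxa x samples).
#' @return symmetric dissimilarity matrix (samples x samples) in [0, 1].
#' @export
bray_curtis <- function(counts) {
  validate_count_matrix(counts)
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("all-zero samples: ", paste(colnames(counts)[zero], collapse = ", "))
  as.matrix(vegan::vegdist(t(counts), method = "bray"))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-0.5 * D^2`, eigendecomposes, and scales eigenvectors
#' by the square roots of their eigenvalues. Axes are ordered by
#' decreasing eigenvalue; axes with non-positive eigenvalues carry no
#' coordinates and their count is reported (no Lingoes/Cailliez
#' correction is applied).
#'
#' @param dissim square symmetric dissimilarity matrix with zero diagonal.
#' @return list of class `pcoa_result` with `coordinates` (samples x
#'   positive axes), `eigenvalues` (all), `prop_var` (share of the
#'   positive eigenvalue total per kept axis), `n_negative`.
#' @export
pcoa_ordination <- function(dissim) {
  dissim <- as.matrix(dissim)
  if (nrow(dissim) != ncol(dissim) || any(abs(dissim - t(dissim)) > 1e-8) ||
      any(abs(diag(dissim)) > 1e-12))
    stop("dissimilarity matrix must be square symmetric with zero diagonal")
  n <- nrow(dissim)
  fit <- suppressWarnings(cmdscale(as.dist(dissim), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > 1e-8 * max(abs(eig)))
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    prop_var = eig[pos] / sum(eig[pos]),
    n_negative = sum(eig < -1e-8 * max(abs(eig)))
  ), class = "pcoa_result")
}

#' Summed relative abundance of a taxon set per sample
#'
#' After a single fixed-seed rarefaction draw per sample (classical,
#' without replacement), the percentage of the rarefied reads belonging
#' to the given taxon set, labeled with each sample's disease stratum.
#' Samples below the rarefaction depth are excluded and reported.
#'
#' @param counts count matrix.
#' @param taxon_set character vector of taxon ids (subset of rownames).
#' @param meta metadata with `sample_id`, `bop`, `periodontitis`.
#' @param depth rarefaction depth in reads (default 10000).
#' @param seed integer RNG seed.
#' @return data.frame `sample_id`, `bop`, `periodontitis`, `summed_pct`;
#'   excluded sample ids in `attr(, "excluded")`.
#' @export
group_summed_abundance <- function(counts, taxon_set, meta, depth = 10000,
                                   seed = 1) {
  validate_count_matrix(counts)
  if (length(taxon_set) == 0) stop("taxon_set is empty")
  if (!all(taxon_set %in% rownames(counts)))
    stop("taxon_set contains unknown taxa: ",
         paste(setdiff(taxon_set, rownames(counts)), collapse = ", "))
  al <- align_samples(counts, meta)
  counts <- al$counts; meta <- al$meta
  set.seed(seed)
  keep <- colSums(counts) >= depth
  pct <- vapply(which(keep), function(j) {
    v <- rarefy(counts[, j], depth)
    100 * sum(v[rownames(counts) %in% taxon_set]) / depth
  }, numeric(1))
  out <- data.frame(sample_id = colnames(counts)[keep],
                    bop = meta$bop[keep],
                    periodontitis = meta$periodontitis[keep],
                    summed_pct = pct, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "excluded") <- colnames(counts)[!keep]
  out
}

#' Kruskal-Wallis rank-sum comparison of groups
#'
#' Tie-corrected H statistic with a chi-squared reference on k - 1
#' degrees of freedom. When every value is identical across groups the
#' statistic is 0 with p = 1 (the tie correction would otherwise be
#' degenerate).
#'
#' @param groups list (>= 2) of non-empty numeric vectors.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) == 0)) stop("groups must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1)
    return(list(statistic = 0, df = length(groups) - 1, p_value = 1))
  kt <- kruskal.test(values, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Descriptive cohort statistics
#'
#' Per-stratum counts and the headline cohort fractions: gingivitis
#' (BoP >= 1), periodontitis, disease-free (BoP = 0 and no
#' periodontitis), weighted mean age, and the tie-corrected Spearman
#' correlation between gingivitis severity and the periodontitis
#' indicator (reported as NA when either variable has zero variance).
#'
#' @param meta metadata data.frame.
#' @return list of class `cohort_summary`.
#' @export
cohort_summary <- function(meta) {
  if (nrow(meta) == 0) stop("empty cohort")
  n <- nrow(meta)
  strata <- aggregate(list(n = seq_len(n)),
                      by = list(bop = meta$bop,
                                periodontitis = meta$periodontitis),
                      FUN = length)
  strata <- strata[order(strata$bop, strata$periodontitis), , drop = FALSE]
  rownames(strata) <- NULL
  ging <- sum(meta$bop >= 1)
  perio <- sum(meta$periodontitis)
  free <- sum(meta$bop == 0 & !meta$periodontitis)
  rho <- if (length(unique(meta$bop)) > 1 &&
             length(unique(meta$periodontitis)) > 1)
    cor(meta$bop, as.numeric(meta$periodontitis), method = "spearman")
  else NA_real_
  structure(list(
    n = n,
    strata = strata,
    gingivitis_n = ging, gingivitis_pct = 100 * ging / n,
    periodontitis_n = perio, periodontitis_pct = 100 * perio / n,
    disease_free_n = free, disease_free_pct = 100 * free / n,
    mean_age = mean(meta$age, na.rm = TRUE),
    spearman_bop_periodontitis = rho
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d women\n", x$n))
  cat(sprintf("  gingivitis (BoP >= 1): %d (%.1f%%)\n", x$gingivitis_n,
              x$gingivitis_pct))
  cat(sprintf("  periodontitis:         %d (%.1f%%)\n", x$periodontitis_n,
              x$periodontitis_pct))
  cat(sprintf("  disease-free:          %d (%.1f%%)\n", x$disease_free_n,
              x$disease_free_pct))
  cat(sprintf("  mean age: %.1f years\n", x$mean_age))
  cat(sprintf("  Spearman rho (BoP, periodontitis): %s\n",
              if (is.na(x$spearman_bop_periodontitis)) "not applicable"
              else sprintf("%.2f", x$spearman_bop_periodontitis)))
  invisible(x)
}
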