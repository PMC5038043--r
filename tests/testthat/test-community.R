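test_that("Bray-Curtis matches hand arithmetic and is order-invariant", {
  m <- count_matrix(cbind(u = c(6L, 2L), v = c(2L, 2L)),
                    taxon_ids = c("a", "b"))
  d <- bray_curtis(m)
  expect_equal(d["u", "v"], 1 / 3, tolerance = 1e-12)
  expect_equal(diag(d), c(u = 0, v = 0))

  same <- count_matrix(cbind(x = c(3L, 4L), y = c(3L, 4L)),
                       taxon_ids = c("a", "b"))
  expect_equal(bray_curtis(same)["x", "y"], 0)

  disjoint <- count_matrix(cbind(x = c(5L, 0L), y = c(0L, 7L)),
                           taxon_ids = c("a", "b"))
  expect_equal(bray_curtis(disjoint)["x", "y"], 1)

  big <- small_counts(10, 6, seed = 71)
  expect_equal(bray_curtis(count_matrix(big)),
               bray_curtis(count_matrix(big[sample(10), ])))

  zero <- count_matrix(cbind(x = c(1L, 1L), y = c(0L, 0L)),
                       taxon_ids = c("a", "b"))
  expect_error(bray_curtis(zero), "y")
})

test_that("PCoA recovers planted geometry up to rotation", {
  set.seed(73)
  pts <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(pts))
  ord <- pcoa_ordination(D)
  expect_equal(ncol(ord$coordinates), 2)
  # Procrustes: after centering, the best orthogonal map should be exact
  X <- scale(pts, scale = FALSE)
  Y <- scale(ord$coordinates, scale = FALSE)
  sv <- svd(crossprod(X, Y))
  R <- sv$v %*% t(sv$u)
  expect_lt(max(abs(Y %*% R - X)), 1e-8)
  # axes ordered by decreasing eigenvalue; positive part sums to inertia
  eig <- ord$eigenvalues
  expect_true(all(diff(eig) <= 1e-8))
  # positive eigenvalues sum to the inertia of the doubly centered matrix
  C <- diag(10) - matrix(1 / 10, 10, 10)
  expect_equal(sum(eig[eig > 0]), sum(diag(C %*% (-0.5 * D^2) %*% C)),
               tolerance = 1e-8)

  two <- count_matrix(cbind(x = c(4L, 1L), y = c(4L, 1L), z = c(1L, 9L)),
                      taxon_ids = c("a", "b"))
  ord2 <- pcoa_ordination(bray_curtis(two))
  expect_equal(ord2$coordinates["x", ], ord2$coordinates["y", ],
               tolerance = 1e-10)
})

test_that("summed set abundance is a percentage of the rarefied sample", {
  m <- count_matrix(small_counts(6, 5, seed = 75, lambda = 4000))
  meta <- meta_fixture(5)
  all_set <- group_summed_abundance(m, rownames(m), meta, depth = 5000,
                                    seed = 1)
  expect_true(all(all_set$summed_pct == 100))

  m2 <- m; m2["t01", "s01"] <- 0L
  one <- group_summed_abundance(count_matrix(m2), "t01", meta, depth = 5000,
                                seed = 1)
  expect_equal(one$summed_pct[one$sample_id == "s01"], 0)
  expect_error(group_summed_abundance(m, character(0), meta), "empty")
  expect_error(group_summed_abundance(m, "nope", meta), "unknown")

  shallow <- m; shallow[, 2] <- 1L
  res <- group_summed_abundance(count_matrix(shallow), "t01", meta,
                                depth = 5000, seed = 1)
  expect_equal(attr(res, "excluded"), "s02")
})

test_that("a periodontitis-only module separates stratum medians", {
  cfg <- generator_config(n_samples = 400, n_taxa = 40,
    effect_table = data.frame(taxon_id = sprintf("T%03d", 1:40),
                              beta_bop = 0, beta_perio = log(4)),
    module_spec = list())
  cfg$effect_table$beta_perio[-(11:16)] <- 0
  meta <- sample_cohort_metadata(cfg, seed = 77)
  g <- generate_counts(meta, cfg, seed = 77)
  res <- group_summed_abundance(g$counts, sprintf("T%03d", 11:16), meta,
                                depth = 5000, seed = 2)
  med <- tapply(res$summed_pct, res$periodontitis, median)
  expect_gt(med[["TRUE"]], med[["FALSE"]])
})

test_that("Kruskal-Wallis matches the rank-sum oracle", {
  r <- kruskal_wallis_test(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$statistic, 3.857, tolerance = 1e-3)
  expect_equal(r$df, 1)

  expect_equal(kruskal_wallis_test(list(c(2, 2), c(2, 2)))$statistic, 0)
  expect_equal(kruskal_wallis_test(list(c(2, 2), c(2, 2)))$p_value, 1)

  set.seed(79)
  for (k in 1:30) {
    groups <- lapply(seq_len(sample(2:4, 1)), function(i)
      round(rnorm(sample(3:12, 1)), sample(0:2, 1)))
    if (length(unique(unlist(groups))) == 1) next
    r <- kruskal_wallis_test(groups)
    expect_equal(r$statistic, kw_oracle(groups), tolerance = 1e-8)
  }
  expect_error(kruskal_wallis_test(list(1:3)), ">= 2")
})

test_that("cohort summary reproduces the printed cohort statistics", {
  cs <- cohort_summary(expand_table2())
  expect_equal(cs$n, 962)
  expect_equal(cs$gingivitis_n, 822)
  expect_equal(round(cs$gingivitis_pct, 1), 85.4)
  expect_equal(cs$periodontitis_n, 307)
  expect_equal(round(cs$disease_free_pct, 1), 14.6)
  expect_equal(round(cs$mean_age, 1), 25.4)
  expect_equal(round(cs$spearman_bop_periodontitis, 2), 0.44)

  # Spearman here equals Pearson on midranks (tie-corrected) by identity
  meta <- expand_table2()
  expect_equal(cs$spearman_bop_periodontitis,
               cor(rank(meta$bop), rank(meta$periodontitis)),
               tolerance = 1e-12)

  flat <- meta[meta$bop == 0 & !meta$periodontitis, ]
  expect_true(is.na(cohort_summary(flat)$spearman_bop_periodontitis))
})
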