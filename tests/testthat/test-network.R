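.toy_corr <- function(vals, ids = NULL) {
  n <- (1 + sqrt(1 + 8 * length(vals))) / 2
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- vals
  m <- m + t(m); diag(m) <- 1
  if (is.null(ids)) ids <- LETTERS[seq_len(n)]
  dimnames(m) <- list(ids, ids)
  m
}

test_that("the strong-edge cutoff is mean + 1.96 population SD", {
  expect_equal(strong_edge_cutoff(.toy_corr(rep(0.3, 3))), 0.3)
  # off-diagonal {0, 0.2, 0.4}: mean 0.2, population SD 0.16330
  thr <- strong_edge_cutoff(.toy_corr(c(0, 0.2, 0.4)))
  expect_equal(thr, 0.2 + 1.96 * sqrt(0.08 / 3), tolerance = 1e-12)
  expect_equal(round(thr, 4), 0.5201)
})

test_that("network construction prunes edges and isolated nodes", {
  corr <- .toy_corr(c(0.8, 0.2, 0.1))
  p <- .toy_corr(c(0.001, 0.001, 0.001)); diag(p) <- 0
  net <- build_network(corr, p, threshold = 0.5)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$node_ids, c("A", "B"))
  expect_equal(net$dropped_nodes, "C")

  empty <- build_network(corr, p, threshold = 0.95)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(length(empty$dropped_nodes), 3)

  # a non-significant strong correlation is not an edge
  p2 <- p; p2["A", "B"] <- p2["B", "A"] <- 0.2
  expect_equal(nrow(build_network(corr, p2, threshold = 0.5)$edges), 0)
})

test_that("edge count is monotone non-increasing in the threshold", {
  set.seed(41)
  v <- runif(45, -0.5, 0.9)
  corr <- .toy_corr(v, ids = sprintf("n%02d", 1:10))
  p <- corr * 0 + 0.001
  counts <- vapply(seq(-0.5, 0.9, by = 0.1), function(th)
    nrow(build_network(corr, p, th)$edges), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("betweenness matches closed forms and the exhaustive oracle", {
  path3 <- .toy_corr(c(0.9, 0.1, 0.9))  # A-B, B-C edges only
  p <- path3 * 0 + 0.001
  net <- build_network(path3, p, threshold = 0.5)
  bt <- betweenness_ranking(net)
  expect_equal(bt$betweenness[bt$node == "B"], 1)
  expect_equal(sum(bt$betweenness), 1)

  # star on 5 nodes: center C(4,2) = 6, leaves 0
  star <- diag(5); dimnames(star) <- list(LETTERS[1:5], LETTERS[1:5])
  star["A", 2:5] <- star[2:5, "A"] <- 0.9
  pm <- star * 0 + 0.001
  bts <- betweenness_ranking(build_network(star, pm, 0.5))
  expect_equal(bts$betweenness[bts$node == "A"], 6)
  expect_true(all(bts$betweenness[bts$node != "A"] == 0))

  # random graphs on <= 8 nodes vs exhaustive path enumeration
  for (s in 1:12) {
    set.seed(s)
    n <- sample(4:8, 1)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- ifelse(runif(n * (n - 1) / 2) < 0.45, 0.9, 0)
    m <- m + t(m); diag(m) <- 1
    dimnames(m) <- list(sprintf("v%d", 1:n), sprintf("v%d", 1:n))
    pv <- m * 0 + 0.001
    net <- build_network(m, pv, threshold = 0.5)
    if (length(net$node_ids) < 3) next
    bt <- betweenness_ranking(net)
    edges <- which(upper.tri(m) & m > 0.5, arr.ind = TRUE)
    keep <- sort(match(net$node_ids, rownames(m)))
    remap <- match(seq_len(n), keep)
    oracle <- brute_betweenness(cbind(remap[edges[, 1]], remap[edges[, 2]]),
                                length(keep))
    expect_equal(bt$betweenness[match(rownames(m)[keep], bt$node)], oracle,
                 tolerance = 1e-10)
  }
})

test_that("Mantel correlation matches hand computation and rejects mismatches", {
  a <- .toy_corr(c(0.1, 0.5, -0.2, 0.7, 0.05, 0.3))
  expect_equal(mantel_r(a, a), 1)
  b <- -a; diag(b) <- 1
  expect_equal(mantel_r(a, b), -1)

  vb <- c(0.2, 0.4, -0.1, 0.6, 0, 0.25)
  b2 <- .toy_corr(vb)
  va <- a[upper.tri(a)]
  hand <- sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  expect_equal(mantel_r(a, b2), hand, tolerance = 1e-12)
  expect_equal(mantel_distance(a, b2), 1 - hand, tolerance = 1e-12)

  c_bad <- a; rownames(c_bad)[1] <- colnames(c_bad)[1] <- "Z"
  expect_error(mantel_r(a, c_bad), "identical node set")
})

test_that("stratum clustering follows complete linkage on Mantel distances", {
  set.seed(43)
  base <- .toy_corr(runif(45, -0.5, 0.9), ids = sprintf("n%02d", 1:10))
  other <- .toy_corr(runif(45, -0.5, 0.9), ids = sprintf("n%02d", 1:10))
  cl <- cluster_strata(list(x1 = base, x2 = base, y = other))
  expect_setequal(cl$hclust$labels[-cl$hclust$merge[1, ]], c("x1", "x2"))
  expect_lt(cl$hclust$height[1], 1e-12)
  tree <- ape::read.tree(text = cl$newick)
  expect_setequal(tree$tip.label, c("x1", "x2", "y"))

  # hand-traced complete linkage for distances d(1,2)=.1 d(1,3)=.5 d(2,3)=.6:
  # merge {1,2} at .1 then {12,3} at max(.5,.6)=.6
  mk <- function(target, ref) {
    # build a matrix at controlled Mantel distance from ref by mixing in
    # an orthogonal component
    v <- ref[upper.tri(ref)]
    set.seed(47)
    w <- rnorm(length(v)); w <- resid(lm(w ~ v))
    v2 <- (1 - target) * scale(v) + sqrt(1 - (1 - target)^2) * scale(w)
    .toy_corr(as.vector(v2), ids = rownames(ref))
  }
  m1 <- base
  m2 <- mk(0.1, m1)
  expect_equal(mantel_distance(m1, m2), 0.1, tolerance = 1e-6)
  d12 <- mantel_distance(m1, m2)
  m3 <- .toy_corr(runif(45, -0.5, 0.9), ids = rownames(base))
  cl2 <- cluster_strata(list(a = m1, b = m2, c = m3))
  d13 <- mantel_distance(m1, m3); d23 <- mantel_distance(m2, m3)
  expect_equal(cl2$hclust$height, c(d12, max(d13, d23)), tolerance = 1e-9)
})

test_that("force-directed layout is deterministic and symmetric", {
  star <- diag(5); dimnames(star) <- list(LETTERS[1:5], LETTERS[1:5])
  star["A", 2:5] <- star[2:5, "A"] <- 0.9
  pm <- star * 0 + 0.001
  net <- build_network(star, pm, 0.5)
  xy1 <- layout_fr(net, seed = 3)
  xy2 <- layout_fr(net, seed = 3)
  expect_identical(xy1, xy2)
  d <- sqrt(rowSums((xy1[2:5, ] - rep(xy1["A", ], each = 4))^2))
  expect_lt((max(d) - min(d)) / mean(d), 0.05)

  pair <- build_network(.toy_corr(c(0.9, 0.1, 0.1)), pm[1:3, 1:3], 0.5)
  xyp <- layout_fr(pair, seed = 1)
  expect_equal(nrow(xyp), 2)
})
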