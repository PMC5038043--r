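test_that("rarefaction draws behave at the boundaries", {
  set.seed(1)
  expect_equal(rarefy(c(500L), 100), 100L)
  x <- c(30L, 20L, 10L)
  expect_equal(rarefy(x, 60), x)  # exhaustive draw returns the input
  expect_error(rarefy(x, 61), "fewer reads")
  r <- rarefy(x, 25)
  expect_equal(sum(r), 25)
  expect_true(all(r <= x))
  rw <- rarefy(c(5L, 5L), 1000, mode = "with_replacement")
  expect_equal(sum(rw), 1000)
})

test_that("without-replacement rarefaction is hypergeometric", {
  set.seed(42)
  draws <- replicate(4000, rarefy(c(5000L, 5000L), 5000)[1])
  # hypergeometric: mean 2500, sd = sqrt(d p (1-p) (N-d)/(N-1)) ~ 25
  expect_lt(abs(mean(draws) - 2500), 2)  # ~5 standard errors of the mean
  expect_lt(abs(sd(draws) - sqrt(5000 * 0.25 * 5000 / 9999)), 2)
})

test_that("alpha diversity matches closed-form and hand-computed values", {
  # uniform community: Shannon approaches ln(S)
  cm <- count_matrix(matrix(rep(50000L, 4), ncol = 1,
                            dimnames = list(letters[1:4], "s1")))
  est <- alpha_diversity(cm, depth = 50000, iterations = 5, seed = 1)
  expect_lt(abs(est$shannon - log(4)), 0.01)

  # relative abundances (0.5, 0.25, 0.25): H = -sum p ln p = 1.0397
  cm2 <- count_matrix(matrix(c(200000L, 100000L, 100000L), ncol = 1,
                             dimnames = list(letters[1:3], "s1")))
  est2 <- alpha_diversity(cm2, depth = 100000, iterations = 5, seed = 2)
  expect_lt(abs(est2$shannon - 1.0397), 0.005)

  # mean richness equals the hypergeometric inclusion-probability formula
  set.seed(7)
  x <- as.integer(rmultinom(1, 3000, prob = c(rep(0.003, 40), rep(0.11, 8))))
  N <- sum(x); d <- 600
  closed <- sum(1 - exp(lchoose(N - x, d) - lchoose(N, d)))
  cm3 <- count_matrix(matrix(x, ncol = 1,
                             dimnames = list(sprintf("t%d", 1:48), "s1")))
  est3 <- alpha_diversity(cm3, depth = d, iterations = 100, seed = 3)
  expect_lt(abs(est3$richness / closed - 1), 0.01)
})

test_that("samples below depth are excluded and reported", {
  m <- count_matrix(matrix(c(6000L, 0L, 2000L, 1000L), 2,
                           dimnames = list(c("a", "b"), c("deep", "shallow"))))
  est <- alpha_diversity(m, depth = 5000, iterations = 3, seed = 1)
  expect_equal(attr(est, "excluded"), "shallow")
  expect_true(is.na(est$richness[est$sample_id == "shallow"]))
  expect_false(est$excluded[est$sample_id == "deep"])
})

test_that("Shannon is invariant to taxon order", {
  m <- small_counts(8, 5, seed = 4, lambda = 400)
  e1 <- alpha_diversity(count_matrix(m), depth = 1000, iterations = 20,
                        seed = 9)
  e2 <- alpha_diversity(count_matrix(m[sample(8), ]), depth = 1000,
                        iterations = 20, seed = 9)
  expect_equal(e1$shannon, e2$shannon, tolerance = 0.02)
})

test_that("averaging over more rarefaction iterations stabilizes estimates", {
  m <- count_matrix(small_counts(30, 1, seed = 5, lambda = 300))
  est_at <- function(iters, seed)
    alpha_diversity(m, depth = 2000, iterations = iters, seed = seed)$shannon
  sd10 <- sd(vapply(1:8, function(s) est_at(10, s), numeric(1)))
  sd100 <- sd(vapply(1:8, function(s) est_at(100, s), numeric(1)))
  expect_lt(sd100, sd10)
})

test_that("backward stepwise elimination keeps signal and drops noise", {
  gen <- function(seed) {
    set.seed(seed)
    x <- rnorm(100)
    noise <- rnorm(100)
    data.frame(x = x, noise = noise, y = 5 * x + rnorm(100, 0, 0.1))
  }
  d <- gen(1)
  fit <- backward_stepwise_lm(d$y, d[, c("x", "noise")])
  expect_true("x" %in% fit$retained)

  # AIC retains an irrelevant single-df regressor with probability
  # P(chisq_1 > 2) ~ 0.157, so the long-run drop rate is ~84%
  dropped <- vapply(1:20, function(s) {
    d <- gen(s)
    !("noise" %in% backward_stepwise_lm(d$y, d[, c("x", "noise")])$retained)
  }, logical(1))
  expect_gte(sum(dropped), 14)
})

test_that("stepwise AIC matches its definition and decreases along the trace", {
  set.seed(3)
  d <- data.frame(a = rnorm(60), b = rnorm(60), g = factor(rep(1:3, 20)))
  y <- 2 * d$a + rnorm(60)
  fit <- backward_stepwise_lm(y, d)
  # recompute AIC of the final model from residuals
  res <- fit$model$residuals
  n <- length(res); k <- fit$model$rank
  expect_equal(fit$aic_trace$aic[nrow(fit$aic_trace)],
               n * log(sum(res^2) / n) + 2 * k)
  expect_true(all(diff(fit$aic_trace$aic) < 0))
})

test_that("rank-deficient stepwise designs are rejected with the aliased term", {
  set.seed(4)
  d <- data.frame(a = rnorm(30))
  d$b <- 2 * d$a
  expect_error(backward_stepwise_lm(rnorm(30), d), "aliased.*b")
})
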