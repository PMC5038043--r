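# Independent oracles used across the suite. Each reimplements a quantity
# from first principles by a different route than the package.

# Benjamini-Hochberg step-up by the textbook definition.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Shortest-path betweenness by exhaustive simple-path enumeration
# (feasible for graphs of <= 8 nodes). edges: two-column matrix of node
# indices; n: node count. Returns the unnormalized undirected betweenness.
brute_betweenness <- function(edges, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(v, seen) {
      if (v == t) { paths[[length(paths) + 1]] <<- seen; return(invisible()) }
      for (w in adj[[v]]) if (!(w %in% seen)) walk(w, c(seen, w))
    }
    walk(s, s)
    paths
  }
  bw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t)
    if (length(paths) == 0) next
    len <- min(lengths(paths))
    shortest <- paths[lengths(paths) == len]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      thru <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
      bw[v] <- bw[v] + thru / length(shortest)
    }
  }
  bw
}

# Tie-corrected Kruskal-Wallis H from the rank-sum formula.
kw_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / lengths(groups)) -
    3 * (N + 1)
  t <- table(x)
  H / (1 - sum(t^3 - t) / (N^3 - N))
}

# Global alignment by an independent dynamic program (match +1, mismatch
# -1, linear gap -2; N matches nothing). Returns the optimal score and the
# attainable range of match counts among all co-optimal alignments.
nw_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(-Inf, n + 1, m + 1)
  Mx <- matrix(-Inf, n + 1, m + 1)  # max matches among optimal prefixes
  Mn <- matrix(Inf, n + 1, m + 1)   # min matches among optimal prefixes
  S[1, ] <- -2 * (0:m); S[, 1] <- -2 * (0:n)
  Mx[1, ] <- 0; Mn[1, ] <- 0; Mx[, 1] <- 0; Mn[, 1] <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    hit <- A[i - 1] == B[j - 1] && A[i - 1] != "N"
    cand <- c(S[i - 1, j - 1] + ifelse(hit, 1, -1),
              S[i - 1, j] - 2, S[i, j - 1] - 2)
    S[i, j] <- max(cand)
    mx <- -Inf; mn <- Inf
    if (cand[1] == S[i, j]) {
      mx <- max(mx, Mx[i - 1, j - 1] + hit)
      mn <- min(mn, Mn[i - 1, j - 1] + hit)
    }
    if (cand[2] == S[i, j]) { mx <- max(mx, Mx[i - 1, j]); mn <- min(mn, Mn[i - 1, j]) }
    if (cand[3] == S[i, j]) { mx <- max(mx, Mx[i, j - 1]); mn <- min(mn, Mn[i, j - 1]) }
    Mx[i, j] <- mx; Mn[i, j] <- mn
  }
  list(score = S[n + 1, m + 1], max_matches = Mx[n + 1, m + 1],
       min_matches = Mn[n + 1, m + 1])
}

# Closed-form SparCC basis solution for a 3-taxon log-ratio variance
# matrix with full pair inclusion: (I + J) omega2 = rowSums(T), whose
# inverse is I - J/4.
sparcc3_oracle <- function(Tm) {
  t_i <- rowSums(Tm)
  omega2 <- t_i - sum(t_i) / 4
  om <- sqrt(omega2)
  rho <- (outer(omega2, omega2, "+") - Tm) / (2 * outer(om, om))
  diag(rho) <- 1
  rho
}

# Random DNA sequence helper.
random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small deterministic count matrix fixture.
small_counts <- function(taxa = 6, samples = 8, seed = 1, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(taxa * samples, lambda), taxa, samples,
              dimnames = list(sprintf("t%02d", seq_len(taxa)),
                              sprintf("s%02d", seq_len(samples))))
  storage.mode(m) <- "integer"
  m
}

# Minimal valid metadata fixture.
meta_fixture <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    bop = sample(0:6, n, replace = TRUE),
    periodontitis = sample(c(TRUE, FALSE), n, replace = TRUE),
    site = factor(sample(c("Lungwena", "Malindi", "Namwera", "Mangochi"), n,
                         replace = TRUE)),
    intervention = factor(sample(c("IFA", "MMN", "LNS"), n, replace = TRUE)),
    hiv = sample(c(TRUE, FALSE), n, replace = TRUE),
    seqrun = factor(sample(c("run1", "run2", "run3", "run4"), n,
                           replace = TRUE)),
    age = runif(n, 18, 45), bmi = runif(n, 18, 30),
    education = runif(n, 0, 10), ses = rnorm(n),
    anemia = sample(c(TRUE, FALSE), n, replace = TRUE),
    malaria = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
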