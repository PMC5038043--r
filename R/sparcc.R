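# Log-ratio variance matrix from a matrix of log fractions (taxa x samples):
# t_ij = var(log(x_i / x_j)) = V_ii + V_jj - 2 V_ij.
.logratio_variance <- function(logf) {
  V <- cov(t(logf))
  d <- diag(V)
  Tm <- outer(d, d, "+") - 2 * V
  Tm[Tm < 0] <- 0  # numerical guard; exact zeros on the diagonal
  diag(Tm) <- 0
  Tm
}

# Solve for basis variances omega^2 given the log-ratio variance matrix and
# a logical inclusion matrix over pairs (TRUE = pair participates).
# Each taxon i contributes the equation
#   d_i * omega_i^2 + sum_{j included with i} omega_j^2 = sum_j t_ij,
# the approximation that the correlation cross-terms cancel in aggregate.
.basis_variances <- function(Tm, incl) {
  d <- rowSums(incl)
  M <- diag(d) + incl * 1
  t_i <- rowSums(Tm * incl)
  omega2 <- tryCatch(solve(M, t_i), error = function(e) rep(NA_real_, nrow(Tm)))
  if (any(!is.finite(omega2))) return(NULL)
  pmax(omega2, 1e-12)
}

.basis_correlations <- function(Tm, omega2) {
  om <- sqrt(omega2)
  rho <- (outer(omega2, omega2, "+") - Tm) / (2 * outer(om, om))
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  rho
}

# One SparCC inference iteration on a fixed fraction matrix.
.sparcc_once <- function(logf, exclusion_threshold, max_excluded) {
  D <- nrow(logf)
  Tm <- .logratio_variance(logf)
  incl <- matrix(TRUE, D, D); diag(incl) <- FALSE
  excluded <- matrix(integer(0), ncol = 2)
  repeat {
    omega2 <- .basis_variances(Tm, incl)
    if (is.null(omega2)) break
    rho <- .basis_correlations(Tm, omega2)
    if (nrow(excluded) >= max_excluded) break
    # strongest still-included pair; never orphan a taxon
    cand <- abs(rho)
    cand[!incl] <- -Inf
    cand[lower.tri(cand, diag = TRUE)] <- -Inf
    deg <- rowSums(incl)
    ord <- order(cand, decreasing = TRUE)
    picked <- NULL
    for (k in ord) {
      if (!is.finite(cand[k]) || cand[k] <= exclusion_threshold) break
      ij <- arrayInd(k, dim(cand))
      if (deg[ij[1]] > 1 && deg[ij[2]] > 1) { picked <- ij; break }
    }
    if (is.null(picked)) break
    incl[picked[1], picked[2]] <- incl[picked[2], picked[1]] <- FALSE
    excluded <- rbind(excluded, picked)
  }
  list(rho = rho, Tm = Tm, omega2 = omega2, excluded = excluded, logf = logf)
}

#' SparCC compositional correlation inference
#'
#' Estimates correlations between latent (basis) abundances from
#' compositional count data. Per inference iteration, per-sample relative
#' abundances are drawn from a Dirichlet posterior (counts + 1); the
#' log-ratio variance matrix is formed; the linear system for the basis
#' variances is solved; and the most strongly correlated pair above the
#' exclusion threshold is repeatedly removed from the system and the
#' system re-solved, until no pair exceeds the threshold or half of all
#' pairs have been excluded. The final correlation matrix is the
#' componentwise median over iterations, clamped to [-1, 1].
#'
#' @param counts count matrix (taxa x samples); at least 4 taxa with no
#'   all-zero taxon.
#' @param inference_iters number of Dirichlet resampling iterations
#'   (default 20).
#' @param exclusion_threshold correlation strength above which the
#'   strongest pair is excluded from the basis system (default 0.1).
#' @param seed integer RNG seed.
#' @return list of class `sparcc_fit` with `corr` (median correlation
#'   matrix) and `internals` (from the last iteration: the log-fraction
#'   matrix `logf`, log-ratio variance matrix `T`, basis variances
#'   `omega2`, excluded pair matrix).
#' @export
sparcc <- function(counts, inference_iters = 20, exclusion_threshold = 0.1,
                   seed = 1) {
  validate_count_matrix(counts)
  D <- nrow(counts); n <- ncol(counts)
  if (D < 4) stop("SparCC needs at least 4 taxa")
  if (n < 10) stop("SparCC needs at least 10 samples")
  zero <- rowSums(counts) == 0
  if (any(zero))
    stop("all-zero taxa must be removed before SparCC: ",
         paste(rownames(counts)[zero], collapse = ", "))
  set.seed(seed)
  max_excluded <- floor(choose(D, 2) / 2)
  rhos <- array(NA_real_, c(D, D, inference_iters))
  last <- NULL
  for (it in seq_len(inference_iters)) {
    g <- matrix(rgamma(D * n, shape = as.vector(counts) + 1), D, n)
    logf <- log(sweep(g, 2, colSums(g), "/"))
    last <- .sparcc_once(logf, exclusion_threshold, max_excluded)
    rhos[, , it] <- last$rho
  }
  corr <- apply(rhos, c(1, 2), median)
  corr <- pmin(pmax(corr, -1), 1)
  diag(corr) <- 1
  dimnames(corr) <- list(rownames(counts), rownames(counts))
  structure(list(corr = corr,
                 internals = list(T = last$Tm, omega2 = last$omega2,
                                  excluded = last$excluded,
                                  logf = last$logf)),
            class = "sparcc_fit")
}

#' Permutation pseudo p-values for SparCC correlations
#'
#' Each permutation independently shuffles every taxon's counts across
#' samples (destroying between-taxon dependence while preserving
#' marginals) and reruns SparCC with the same parameters. The two-sided
#' pseudo p-value uses the add-one estimator
#' `(1 + #(|rho_perm| >= |rho_obs|)) / (1 + n_perm)`, so p is never zero.
#'
#' @param counts count matrix.
#' @param observed_corr correlation matrix from [sparcc()] on `counts`.
#' @param n_perm number of permutations (default 100).
#' @param inference_iters,exclusion_threshold passed to [sparcc()].
#' @param seed integer RNG seed.
#' @return symmetric p-value matrix in (0, 1] with zero diagonal.
#' @export
permutation_pvalues <- function(counts, observed_corr, n_perm = 100,
                                inference_iters = 20,
                                exclusion_threshold = 0.1, seed = 1) {
  validate_count_matrix(counts)
  stopifnot(n_perm >= 1)
  set.seed(seed)
  D <- nrow(counts); n <- ncol(counts)
  exceed <- matrix(0L, D, D)
  perm_seeds <- sample.int(.Machine$integer.max, n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(perm_seeds[b])
    shuffled <- counts
    for (i in seq_len(D)) shuffled[i, ] <- counts[i, sample.int(n)]
    fit <- sparcc(shuffled, inference_iters, exclusion_threshold,
                  seed = perm_seeds[b])
    exceed <- exceed + (abs(fit$corr) >= abs(observed_corr))
  }
  p <- (1 + exceed) / (1 + n_perm)
  p <- (p + t(p)) / 2
  diag(p) <- 0
  dimnames(p) <- dimnames(observed_corr)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
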