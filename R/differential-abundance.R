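#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed against a reference of taxa
#' observed in every sample: each sample's factor is the median ratio of
#' its reference counts to the reference taxa's geometric means, rescaled
#' so the factors have geometric mean 1.
#'
#' @param counts count matrix (taxa x samples).
#' @param pseudo_reference if `TRUE`, fall back to a reference over all
#'   taxa with positive geometric-mean counts, taking each sample's median
#'   ratio over its positive counts only (for sparse tables with no
#'   all-positive taxon).
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  validate_count_matrix(counts)
  if (!pseudo_reference) {
    ref <- rowSums(counts == 0) == 0
    if (!any(ref))
      stop("no taxon has positive counts in every sample; rerun with ",
           "pseudo_reference = TRUE")
    logc <- log(counts[ref, , drop = FALSE])
    logratio <- logc - rowMeans(logc)
    f <- exp(apply(logratio, 2, median))
  } else {
    keep <- rowSums(counts > 0) > 0
    logc <- log(counts[keep, , drop = FALSE])
    logc[!is.finite(logc)] <- NA
    geo <- rowMeans(logc, na.rm = TRUE)
    f <- apply(logc - geo, 2, function(v) exp(median(v, na.rm = TRUE)))
    if (any(!is.finite(f)))
      stop("size factors undefined for samples: ",
           paste(names(f)[!is.finite(f)], collapse = ", "))
  }
  f / exp(mean(log(f)))
}

.nb_loglik <- function(y, mu, alpha) {
  sum(dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}

#' Fit a negative-binomial GLM with log link by IRLS
#'
#' Log-link negative binomial regression with known dispersion `alpha`
#' (variance `mu + alpha * mu^2`) and a per-sample offset, fitted by
#' iteratively reweighted least squares to a relative coefficient
#' tolerance, with standard errors from the Fisher information at the
#' optimum.
#'
#' @param y integer response vector (counts for one taxon).
#' @param X model matrix (full rank).
#' @param offset per-sample offset on the log scale (e.g.
#'   `log(size_factors(counts))`).
#' @param alpha NB dispersion (> 0).
#' @param tol relative convergence tolerance (default 1e-8).
#' @param maxit maximum IRLS iterations (default 100).
#' @return list with `coef`, `se`, `vcov`, `mu`, `loglik`, `converged`,
#'   `iterations`.
#' @export
fit_nb_glm <- function(y, X, offset = rep(0, length(y)), alpha,
                       tol = 1e-8, maxit = 100) {
  stopifnot(length(y) == nrow(X), alpha > 0)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design matrix")
  # initialize from a log-linear fit on shifted counts
  beta <- stats::lm.fit(X, log(y + 0.5) - offset)$coefficients
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (any(!is.finite(beta_new)))
      stop("NB-GLM diverged (non-finite coefficients)")
    delta <- max(abs(beta_new - beta) / (abs(beta) + tol))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta) + offset
  mu <- exp(pmin(pmax(eta, -30), 30))
  w <- mu / (1 + alpha * mu)
  info <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(info), error = function(e)
    stop("singular Fisher information (possible separation)"))
  se <- sqrt(diag(vc))
  names(se) <- colnames(X)
  list(coef = beta, se = se, vcov = vc, mu = mu,
       loglik = .nb_loglik(y, mu, alpha), converged = converged,
       iterations = it)
}

#' Profile maximum-likelihood NB dispersion
#'
#' Maximizes the negative-binomial log-likelihood over the dispersion
#' `alpha`, profiling out the GLM coefficients (the GLM is refitted at
#' each candidate `alpha`). The estimate is floored at 1e-8; if the
#' profile optimization fails, a method-of-moments estimate from the
#' Poisson-fit residuals is returned with a warning.
#'
#' @param y integer response vector.
#' @param X model matrix.
#' @param offset per-sample log-scale offset.
#' @param lower,upper search range for `alpha`.
#' @return scalar dispersion estimate (>= 1e-8).
#' @export
estimate_dispersion <- function(y, X, offset = rep(0, length(y)),
                                lower = 1e-8, upper = 50) {
  if (length(y) - ncol(X) < 2)
    stop("need at least 2 residual degrees of freedom")
  prof <- function(log_alpha) {
    a <- exp(log_alpha)
    f <- tryCatch(fit_nb_glm(y, X, offset, a), error = function(e) NULL)
    if (is.null(f)) return(-Inf)
    f$loglik
  }
  opt <- tryCatch(
    optimize(prof, interval = log(c(lower, upper)), maximum = TRUE,
             tol = 1e-4),
    error = function(e) NULL)
  if (!is.null(opt) && is.finite(opt$objective)) {
    a <- exp(opt$maximum)
    # accept the boundary if the likelihood is monotone toward it
    if (prof(log(lower)) >= opt$objective) a <- lower
    return(max(a, 1e-8))
  }
  warning("dispersion profile likelihood failed; using method of moments")
  f0 <- tryCatch(fit_nb_glm(y, X, offset, 1e-6), error = function(e) NULL)
  if (is.null(f0)) return(1e-8)
  mu <- f0$mu
  max(sum((y - mu)^2 - mu) / sum(mu^2), 1e-8)
}

#' Wald tests with Benjamini-Hochberg correction
#'
#' Two-sided p-values from the normal reference for `z = beta / se`,
#' BH-adjusted q-values, and direction labels: positive coefficients
#' (more abundant with more disease) are disease-associated, negative
#' ones health-associated.
#'
#' @param taxon_id character vector.
#' @param beta,se coefficient estimates and standard errors.
#' @param alpha_level significance level on q (default 0.05).
#' @param base_mean optional mean normalized count per taxon.
#' @return data.frame with `taxon_id`, `base_mean`, `beta`, `fold_change`,
#'   `se`, `wald_z`, `p`, `q`, `direction`, `significant`.
#' @export
wald_bh <- function(taxon_id, beta, se, alpha_level = 0.05,
                    base_mean = NA_real_) {
  stopifnot(length(beta) == length(se))
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  q <- p.adjust(p, method = "BH")
  data.frame(
    taxon_id = taxon_id,
    base_mean = base_mean,
    beta = beta,
    fold_change = exp(beta),
    se = se,
    wald_z = z,
    p = p,
    q = q,
    direction = ifelse(beta > 0, "disease", "health"),
    significant = q < alpha_level,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Build the differential-abundance model matrix
#'
#' Gingivitis enters as a continuous BoP term (0-6), periodontitis as a
#' binary indicator, and the adjustment covariates (study site,
#' nutritional intervention, HIV status, sequencing run) with treatment
#' coding, reference level = lexicographically first observed level.
#' Factors observed at a single level are dropped (they carry no
#' information) and reported via the `"dropped_terms"` attribute.
#'
#' @param meta metadata data.frame.
#' @param adjust character vector of adjustment covariates.
#' @return model matrix with an intercept column.
#' @export
design_matrix <- function(meta, adjust = c("site", "intervention", "hiv",
                                           "seqrun")) {
  cols <- list("(Intercept)" = rep(1, nrow(meta)),
               bop = as.numeric(meta$bop),
               periodontitis = as.numeric(meta$periodontitis))
  dropped <- character(0)
  for (a in adjust) {
    v <- meta[[a]]
    if (is.logical(v)) {
      if (length(unique(v)) < 2) { dropped <- c(dropped, a); next }
      cols[[a]] <- as.numeric(v)
    } else {
      v <- factor(as.character(v), levels = sort(unique(as.character(v))))
      if (nlevels(v) < 2) { dropped <- c(dropped, a); next }
      mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
      colnames(mm) <- paste0(a, levels(v)[-1])
      for (cn in colnames(mm)) cols[[cn]] <- mm[, cn]
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- meta$sample_id
  attr(X, "dropped_terms") <- dropped
  X
}

#' Differential abundance of every taxon against gingivitis and periodontitis
#'
#' Fits one joint NB-GLM per taxon containing both focal covariates (BoP
#' as continuous gingivitis severity, periodontitis as a binary factor)
#' and the adjustment terms, on median-of-ratios-normalized counts with
#' per-taxon profile-ML dispersion. Returns separate BH-corrected result
#' tables for the two focal coefficients plus the intersection report
#' (taxa significant for periodontitis but not gingivitis, and vice
#' versa).
#'
#' @param counts count matrix.
#' @param meta metadata aligned to `counts` (see [align_samples()]).
#' @param adjust adjustment covariates (default site, intervention, hiv,
#'   seqrun).
#' @param fdr significance level on q (default 0.05).
#' @param pseudo_reference passed to [size_factors()].
#' @param min_prevalence minimum number of samples in which a taxon must
#'   be observed to be modeled (default 5).
#' @return list of class `diffabund_result` with elements `bop`,
#'   `periodontitis` (per-taxon result data.frames), `intersection`,
#'   `skipped` (taxa not modeled, with reasons), `n_samples_used`,
#'   `size_factors`.
#' @export
run_differential_abundance <- function(counts, meta,
                                       adjust = c("site", "intervention",
                                                  "hiv", "seqrun"),
                                       fdr = 0.05, pseudo_reference = FALSE,
                                       min_prevalence = 5) {
  al <- align_samples(counts, meta)
  counts <- al$counts; meta <- al$meta
  used <- c("bop", "periodontitis", adjust)
  cc <- complete.cases(meta[, used, drop = FALSE])
  counts <- counts[, cc, drop = FALSE]
  meta <- meta[cc, , drop = FALSE]
  X <- design_matrix(meta, adjust)
  sf <- size_factors(counts, pseudo_reference = pseudo_reference)
  offset <- log(sf)
  norm <- sweep(counts, 2, sf, "/")
  res <- list()
  skipped <- data.frame(taxon_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (tx in rownames(counts)) {
    y <- counts[tx, ]
    if (sum(y > 0) < min_prevalence) {
      skipped <- rbind(skipped, data.frame(taxon_id = tx,
                                           reason = "low prevalence"))
      next
    }
    out <- tryCatch({
      a <- suppressWarnings(estimate_dispersion(y, X, offset))
      f <- fit_nb_glm(y, X, offset, a)
      list(fit = f, alpha = a)
    }, error = function(e) e)
    if (inherits(out, "condition")) {
      skipped <- rbind(skipped, data.frame(taxon_id = tx,
                                           reason = conditionMessage(out)))
      next
    }
    res[[tx]] <- c(base_mean = mean(norm[tx, ]),
                   alpha = out$alpha,
                   beta_bop = unname(out$fit$coef["bop"]),
                   se_bop = unname(out$fit$se["bop"]),
                   beta_perio = unname(out$fit$coef["periodontitis"]),
                   se_perio = unname(out$fit$se["periodontitis"]))
  }
  if (length(res) == 0) stop("no taxon could be modeled")
  tab <- as.data.frame(do.call(rbind, res))
  tab$taxon_id <- rownames(tab)
  bop <- wald_bh(tab$taxon_id, tab$beta_bop, tab$se_bop, fdr, tab$base_mean)
  perio <- wald_bh(tab$taxon_id, tab$beta_perio, tab$se_perio, fdr,
                   tab$base_mean)
  inter <- data.frame(
    taxon_id = tab$taxon_id,
    bop_significant = bop$significant,
    periodontitis_significant = perio$significant,
    category = ifelse(bop$significant & perio$significant, "both",
               ifelse(bop$significant, "gingivitis_only",
               ifelse(perio$significant, "periodontitis_only", "neither"))),
    stringsAsFactors = FALSE
  )
  structure(list(bop = bop, periodontitis = perio, intersection = inter,
                 dispersion = setNames(tab$alpha, tab$taxon_id),
                 skipped = skipped, n_samples_used = ncol(counts),
                 size_factors = sf, fdr = fdr),
            class = "diffabund_result")
}

#' @export
print.diffabund_result <- function(x, ...) {
  cat("Negative-binomial differential abundance\n")
  cat(sprintf("  samples used: %d; taxa modeled: %d; skipped: %d\n",
              x$n_samples_used, nrow(x$bop), nrow(x$skipped)))
  cat(sprintf("  gingivitis (BoP) hits at q < %g: %d\n", x$fdr,
              sum(x$bop$significant)))
  cat(sprintf("  periodontitis hits at q < %g: %d\n", x$fdr,
              sum(x$periodontitis$significant)))
  invisible(x)
}
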