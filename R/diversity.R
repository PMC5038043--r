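#' Rarefy one sample to a fixed depth
#'
#' Classical rarefaction (`without_replacement`) draws `depth` reads from
#' the sample's read pool without replacement (multivariate
#' hypergeometric); `with_replacement` draws a multinomial of size `depth`
#' from the observed proportions.
#'
#' @param x integer vector of per-taxon counts for one sample.
#' @param depth number of reads to draw (>= 1).
#' @param mode `"without_replacement"` (default) or `"with_replacement"`.
#' @return integer vector of the same length as `x` summing to `depth`.
#' @export
rarefy <- function(x, depth,
                   mode = c("without_replacement", "with_replacement")) {
  mode <- match.arg(mode)
  if (depth < 1) stop("depth must be >= 1")
  if (any(x < 0 | x != round(x))) stop("counts must be non-negative integers")
  total <- sum(x)
  if (mode == "with_replacement") {
    if (total == 0) stop("cannot rarefy an all-zero sample")
    return(as.vector(rmultinom(1, depth, x)))
  }
  if (total < depth)
    stop("sample has fewer reads (", total, ") than the rarefaction depth (",
         depth, ")")
  if (total == depth) return(as.integer(x))
  # draw read positions without replacement; map to taxa by cumulative count
  pos <- sample.int(total, depth)
  cs <- cumsum(x)
  tabulate(findInterval(pos - 0.5, c(0, cs)), nbins = length(x))
}

.shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Rarefaction-averaged alpha diversity
#'
#' Per-sample observed richness and Shannon index (natural log), each
#' averaged over independent rarefactions to a common depth. In
#' `without_replacement` mode, samples with fewer reads than the depth are
#' excluded and reported rather than estimated.
#'
#' @param counts count matrix (taxa x samples).
#' @param depth rarefaction depth in reads (default 5000).
#' @param iterations number of rarefaction draws to average (default 100).
#' @param mode passed to [rarefy()].
#' @param seed integer RNG seed.
#' @return data.frame with one row per sample: `sample_id`, `richness`,
#'   `shannon`, `depth`, `iterations`, `excluded` (logical; excluded
#'   samples carry NA estimates). The excluded ids are also available as
#'   `attr(, "excluded")`.
#' @export
alpha_diversity <- function(counts, depth = 5000, iterations = 100,
                            mode = c("without_replacement",
                                     "with_replacement"),
                            seed = 1) {
  mode <- match.arg(mode)
  validate_count_matrix(counts)
  if (iterations < 1) stop("iterations must be >= 1")
  set.seed(seed)
  totals <- colSums(counts)
  excluded <- if (mode == "without_replacement") totals < depth
              else totals == 0
  rich <- shan <- rep(NA_real_, ncol(counts))
  for (j in which(!excluded)) {
    r <- s <- 0
    for (it in seq_len(iterations)) {
      v <- rarefy(counts[, j], depth, mode)
      r <- r + sum(v > 0)
      s <- s + .shannon(v / depth)
    }
    rich[j] <- r / iterations
    shan[j] <- s / iterations
  }
  out <- data.frame(sample_id = colnames(counts), richness = rich,
                    shannon = shan, depth = depth, iterations = iterations,
                    excluded = excluded, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "excluded") <- colnames(counts)[excluded]
  out
}

# AIC convention used throughout the stepwise search:
# n * log(RSS / n) + 2k, k = number of estimated coefficients incl intercept.
.aic_lm <- function(fit) {
  rss <- sum(fit$residuals^2)
  n <- length(fit$residuals)
  n * log(rss / n) + 2 * fit$rank
}

#' Backward stepwise linear regression by AIC
#'
#' Fits the full linear model of `response` on every column of
#' `covariates`, then repeatedly removes the single term whose removal
#' most lowers AIC (`n log(RSS/n) + 2k`), stopping when no removal lowers
#' it. Categorical covariates are removed as whole terms. Ties are broken
#' by dropping the term listed last. Incomplete cases are dropped up front
#' and counted.
#'
#' @param response numeric vector.
#' @param covariates data.frame of numeric and/or factor columns.
#' @return list of class `stepwise_lm` with the final `model`, `retained`
#'   term names, `coefficients` table (estimate, se), `aic_trace`
#'   data.frame of accepted steps, and `n_dropped_incomplete`.
#' @export
backward_stepwise_lm <- function(response, covariates) {
  stopifnot(is.data.frame(covariates), length(response) == nrow(covariates))
  cc <- complete.cases(covariates) & !is.na(response)
  n_dropped <- sum(!cc)
  y <- response[cc]
  dat <- covariates[cc, , drop = FALSE]
  terms <- colnames(dat)
  fit_terms <- function(tt) {
    f <- if (length(tt) == 0) y ~ 1
         else stats::as.formula(paste("y ~", paste(tt, collapse = " + ")))
    lm(f, data = cbind(dat, y = y))
  }
  full <- fit_terms(terms)
  if (any(is.na(stats::coef(full))))
    stop("rank-deficient design; aliased terms: ",
         paste(names(stats::coef(full))[is.na(stats::coef(full))],
               collapse = ", "))
  if (length(y) <= full$rank)
    stop("need more observations than parameters")
  current <- terms
  fit <- full
  aic <- .aic_lm(fit)
  trace <- data.frame(dropped = "<full model>", aic = aic,
                      stringsAsFactors = FALSE)
  repeat {
    if (length(current) == 0) break
    cand_aic <- vapply(current,
                       function(tm) .aic_lm(fit_terms(setdiff(current, tm))),
                       numeric(1))
    best <- min(cand_aic)
    if (best >= aic) break
    # tie-break: among minimizers, drop the term listed last in the design
    drop_term <- current[max(which(cand_aic == best))]
    current <- setdiff(current, drop_term)
    fit <- fit_terms(current)
    aic <- best
    trace <- rbind(trace, data.frame(dropped = drop_term, aic = aic,
                                     stringsAsFactors = FALSE))
  }
  sm <- summary(fit)$coefficients
  structure(list(
    model = fit,
    retained = current,
    coefficients = data.frame(term = rownames(sm), estimate = sm[, 1],
                              se = sm[, 2], row.names = NULL,
                              stringsAsFactors = FALSE),
    aic_trace = trace,
    n_dropped_incomplete = n_dropped
  ), class = "stepwise_lm")
}

#' @export
print.stepwise_lm <- function(x, ...) {
  cat("Backward stepwise linear model (AIC = n log(RSS/n) + 2k)\n")
  cat("Retained terms:",
      if (length(x$retained) > 0) paste(x$retained, collapse = ", ")
      else "(intercept only)", "\n")
  cat("Final AIC:", format(x$aic_trace$aic[nrow(x$aic_trace)]), "\n")
  invisible(x)
}
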