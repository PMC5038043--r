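#' Published per-stratum cohort breakdown
#'
#' The printed breakdown of the 962-woman cohort by gingivitis severity
#' (bleeding-on-probing sextant count, 0-6) and periodontitis status:
#' stratum sizes, demographic means/SDs, prevalence counts, and the
#' site / nutritional-intervention / sequencing-run splits. These marginals
#' calibrate the synthetic-cohort generator and drive the deterministic
#' cohort expansion used for descriptive statistics. No women with
#' periodontitis were recorded in the bleeding-free stratum, so that row is
#' absent.
#'
#' @return data.frame with one row per (bop, periodontitis) stratum.
#' @export
table2_strata <- function() {
  df <- data.frame(
    bop           = c(0, 1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6),
    periodontitis = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                      TRUE, FALSE, TRUE, FALSE, TRUE),
    n        = c(140, 72, 11, 95, 23, 111, 27, 72, 51, 63, 50, 102, 145),
    age_mean = c(23.4, 23.9, 31.6, 24.7, 27.5, 24.4, 26.5, 25.0, 26.9, 24.9,
                 26.6, 24.5, 28.3),
    age_sd   = c(5.8, 5.9, 6.1, 6.2, 6.2, 5.4, 5.7, 6.4, 5.4, 5.2, 5.9, 5.5,
                 7.0),
    hiv_n    = c(27, 7, 1, 11, 5, 11, 4, 9, 8, 7, 5, 10, 30),
    malaria_n = c(37, 16, 1, 22, 5, 32, 3, 16, 11, 12, 7, 18, 28),
    bmi_mean = c(22.7, 22.6, 22.7, 22.1, 21.7, 21.7, 22.2, 21.7, 21.8, 21.6,
                 21.8, 21.9, 22.1),
    bmi_sd   = c(3.2, 3.4, 2.4, 2.6, 2.0, 2.3, 2.7, 2.2, 2.7, 2.4, 3.1, 2.3,
                 2.5),
    edu_mean = c(5.6, 5.1, 4.4, 4.4, 2.7, 4.3, 3.6, 3.4, 3.3, 4.0, 2.4, 3.5,
                 2.9),
    edu_sd   = c(3.6, 3.8, 3.3, 3.6, 3.3, 3.3, 3.0, 3.0, 3.1, 3.6, 2.8, 3.0,
                 3.0),
    anemia_n = c(36, 12, 3, 19, 4, 21, 6, 11, 7, 15, 5, 26, 32),
    ses_mean = c(0.38, 0.19, -0.35, 0.10, -0.16, -0.12, -0.20, -0.16, -0.17,
                 -0.16, -0.36, -0.20, -0.27),
    ses_sd   = c(1.22, 1.11, 0.62, 1.10, 0.91, 0.84, 0.91, 0.80, 0.81, 0.81,
                 0.61, 0.81, 0.74)
  )
  df$site_n <- matrix(c(
    36, 37, 18, 49,   25, 9, 17, 21,   6, 2, 1, 2,   39, 19, 13, 24,
    13, 1, 4, 5,      41, 22, 22, 26,  11, 6, 3, 7,  28, 16, 10, 18,
    27, 3, 7, 14,     22, 11, 9, 21,   18, 11, 7, 14, 36, 24, 16, 26,
    66, 28, 17, 34), ncol = 4, byrow = TRUE,
    dimnames = list(NULL, .site_levels))
  df$intervention_n <- matrix(c(
    43, 53, 44,  32, 19, 21,  8, 0, 3,   38, 34, 23,  5, 11, 7,
    40, 34, 37,  11, 4, 12,   16, 26, 30, 14, 19, 18, 22, 23, 18,
    16, 15, 19,  33, 41, 28,  45, 48, 52), ncol = 3, byrow = TRUE,
    dimnames = list(NULL, .intervention_levels))
  df$seqrun_n <- matrix(c(
    47, 49, 41, 3,  34, 26, 12, 0,  3, 5, 3, 0,   31, 41, 23, 0,
    9, 7, 7, 0,     36, 34, 39, 2,  11, 6, 10, 0, 26, 28, 18, 0,
    23, 7, 21, 0,   26, 13, 24, 0,  21, 12, 17, 0, 18, 46, 36, 2,
    59, 43, 41, 2), ncol = 4, byrow = TRUE,
    dimnames = list(NULL, .seqrun_levels))
  df
}

# Deterministic integer split of n across categories with probabilities
# proportional to w (largest-remainder rounding), used by expand_table2.
.apportion <- function(n, w) {
  if (sum(w) == 0) return(rep(0L, length(w)))
  exact <- n * w / sum(w)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Deterministically expand the printed cohort table to per-woman records
#'
#' One metadata record per woman, with continuous fields set to their
#' stratum mean and categorical fields apportioned to match the printed
#' per-stratum counts exactly. This expansion supports exact recomputation
#' of the published cohort statistics (prevalences, weighted mean age,
#' gingivitis-periodontitis rank correlation).
#'
#' @return metadata data.frame with 962 rows.
#' @export
expand_table2 <- function() {
  tab <- table2_strata()
  rows <- vector("list", nrow(tab))
  for (k in seq_len(nrow(tab))) {
    n <- tab$n[k]
    site <- rep(.site_levels, .apportion(n, tab$site_n[k, ]))
    intervention <- rep(.intervention_levels,
                        .apportion(n, tab$intervention_n[k, ]))
    seqrun <- rep(.seqrun_levels, .apportion(n, tab$seqrun_n[k, ]))
    rows[[k]] <- data.frame(
      sample_id = NA_character_,
      bop = as.integer(tab$bop[k]),
      periodontitis = tab$periodontitis[k],
      site = factor(site, levels = .site_levels),
      intervention = factor(intervention, levels = .intervention_levels),
      hiv = seq_len(n) <= tab$hiv_n[k],
      seqrun = factor(seqrun, levels = .seqrun_levels),
      age = tab$age_mean[k],
      bmi = tab$bmi_mean[k],
      education = tab$edu_mean[k],
      ses = tab$ses_mean[k],
      anemia = seq_len(n) <= tab$anemia_n[k],
      malaria = seq_len(n) <= tab$malaria_n[k],
      stringsAsFactors = FALSE
    )
  }
  meta <- do.call(rbind, rows)
  meta$sample_id <- sprintf("W%04d", seq_len(nrow(meta)))
  meta
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study cohort: bleeding-severity weights and
#' periodontitis probabilities from the printed per-stratum counts,
#' lognormal library sizes with arithmetic mean 13565 and SD 6833 reads,
#' lognormally skewed base relative abundances, negative-binomial counts
#' (variance mu + alpha * mu^2), a per-taxon-per-sample lognormal noise
#' term representing biological variability, and two latent cooccurrence
#' modules: one active only in women with periodontitis, one active only
#' in women without, inducing stratum-specific correlation structure.
#' Default taxon effects place a disease-associated periodontitis effect
#' on the periodontitis module and a 1.45-fold-per-sextant gingivitis
#' effect (the strongest published gingivitis association) on a block of
#' gingivitis taxa, with a reciprocal health-associated block.
#'
#' @param n_samples,n_taxa cohort dimensions.
#' @param libsize_mean,libsize_sd target arithmetic mean/SD of library
#'   sizes in reads (lognormal, moment matched).
#' @param bop_weights 7 non-negative sampling weights for BoP 0..6.
#' @param perio_prob_by_bop probability of periodontitis at each BoP level.
#' @param effect_table data.frame with columns `taxon_id`, `beta_bop`,
#'   `beta_perio` (natural-log fold changes) and optional confounder
#'   effect columns `beta_hiv`, `beta_site2`.., defaults to the block
#'   structure described above.
#' @param dispersion per-taxon NB dispersion alpha (recycled).
#' @param base_log_sd log-scale SD of the deterministic base relative
#'   abundances (larger = more skewed community).
#' @param taxon_noise_sd SD of the per-taxon-per-sample lognormal noise on
#'   the log-mean scale.
#' @param module_spec list of modules, each
#'   `list(taxa = <ids or indices>, loading = <log-scale factor loading>,
#'   active_periodontitis = TRUE/FALSE/NA)` (NA = active everywhere).
#' @param seq_identity_targets per-taxon percent identity to the reference
#'   sequence used by [generate_sequences()].
#' @param seq_length length of the synthetic reference 16S fragment
#'   (matching the study's mean amplicon length of 369 nt).
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_samples = 500, n_taxa = 100,
                             libsize_mean = 13565, libsize_sd = 6833,
                             bop_weights = NULL, perio_prob_by_bop = NULL,
                             effect_table = NULL, dispersion = 0.5,
                             base_log_sd = 2, taxon_noise_sd = 0,
                             module_spec = NULL,
                             seq_identity_targets = NULL,
                             seq_length = 369) {
  tab <- table2_strata()
  totals <- tapply(tab$n, tab$bop, sum)
  perio <- sapply(0:6, function(b) {
    yes <- tab$n[tab$bop == b & tab$periodontitis]
    sum(yes) / sum(tab$n[tab$bop == b])
  })
  if (is.null(bop_weights)) bop_weights <- as.numeric(totals)
  if (is.null(perio_prob_by_bop)) perio_prob_by_bop <- as.numeric(perio)
  taxon_ids <- sprintf("T%03d", seq_len(n_taxa))
  # default community layout (taxon index = abundance rank, descending):
  # ranks 1-20 are an unchanged abundant core that anchors median-of-ratios
  # normalization; 21-30 the periodontitis cooccurrence module (also
  # disease-associated); 31-40 the health-stratum module (also mildly
  # health-associated); 41-50 gingivitis-associated with per-sextant fold
  # changes tapering from the strongest published association (1.45) down
  # to 1.1; 51-60 gingivitis-depleted; the rest a rare unchanged tail.
  blk <- function(lo, hi) intersect(lo:hi, seq_len(n_taxa))
  if (is.null(module_spec)) {
    # the periodontitis module is two coaggregation sub-modules sharing a
    # bridging taxon (rank 26), so the strong-edge network has clusters
    # connected through a high-betweenness hub; women without
    # periodontitis share a separate module among the rare relatives of
    # the periodontitis taxa (commensals cooccurring in health)
    module_spec <- list(
      list(taxa = taxon_ids[blk(21, 26)], loading = 1,
           active_periodontitis = TRUE),
      list(taxa = taxon_ids[blk(26, 30)], loading = 1,
           active_periodontitis = TRUE),
      list(taxa = taxon_ids[blk(61, 70)], loading = 1,
           active_periodontitis = FALSE)
    )
    module_spec <- Filter(function(m) length(m$taxa) > 0, module_spec)
  }
  if (is.null(effect_table)) {
    effect_table <- data.frame(taxon_id = taxon_ids,
                               beta_bop = 0, beta_perio = 0,
                               stringsAsFactors = FALSE)
    effect_table$beta_perio[blk(21, 30)] <- log(1.5)
    effect_table$beta_perio[blk(31, 40)] <- -log(1.3)
    effect_table$beta_bop[blk(41, 50)] <-
      log(seq(1.45, 1.1, length.out = length(blk(41, 50))))
    effect_table$beta_bop[blk(51, 60)] <-
      -log(seq(1.3, 1.05, length.out = length(blk(51, 60))))
  }
  if (is.null(seq_identity_targets)) {
    # the periodontitis module plus a block of rare tail phylotypes form
    # one >98.5%-similarity cluster, so similarity-based selection sweeps
    # in rare relatives that end up isolated in the strong-edge network
    seq_identity_targets <- rep(95, n_taxa)
    seq_identity_targets[blk(21, 30)] <- 99.5
    seq_identity_targets[blk(61, 80)] <- 99.2
  }
  dispersion <- rep_len(dispersion, n_taxa)
  # deterministic, skewed base relative abundances (lognormal quantiles),
  # assigned in decreasing order: low taxon indices are the abundant,
  # reliably detectable community members that carry the default effect
  # and module structure
  base_abundance <- qlnorm(ppoints(n_taxa), meanlog = 0, sdlog = base_log_sd)
  base_abundance <- rev(base_abundance) / sum(base_abundance)
  cfg <- list(n_samples = n_samples, n_taxa = n_taxa, taxon_ids = taxon_ids,
              libsize_mean = libsize_mean, libsize_sd = libsize_sd,
              bop_weights = bop_weights,
              perio_prob_by_bop = perio_prob_by_bop,
              effect_table = effect_table, dispersion = dispersion,
              base_abundance = base_abundance,
              taxon_noise_sd = taxon_noise_sd, module_spec = module_spec,
              seq_identity_targets = seq_identity_targets,
              seq_length = seq_length)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#' @param cfg `generator_config` list.
#' @return `cfg`, invisibly.
#' @export
validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 0, cfg$n_taxa >= 1)
  if (length(cfg$bop_weights) != 7 || any(cfg$bop_weights < 0) ||
      sum(cfg$bop_weights) <= 0)
    stop("bop_weights must be 7 non-negative weights with positive sum")
  if (length(cfg$perio_prob_by_bop) != 7 ||
      any(cfg$perio_prob_by_bop < 0 | cfg$perio_prob_by_bop > 1))
    stop("perio_prob_by_bop must be 7 probabilities in [0, 1]")
  if (any(cfg$dispersion <= 0))
    stop("dispersion must be positive for every taxon")
  if (any(cfg$seq_identity_targets < 0 | cfg$seq_identity_targets > 100))
    stop("seq_identity_targets must lie in [0, 100]")
  for (m in cfg$module_spec) {
    if (!all(m$taxa %in% cfg$taxon_ids))
      stop("module_spec references unknown taxa")
    if (m$loading < 0) stop("module loading must be non-negative")
  }
  invisible(cfg)
}

# Draw one categorical value per row of prob matrix `p` (rows sum to 1).
.rcat <- function(p, levels) {
  idx <- apply(p, 1, function(w) sample.int(length(w), 1, prob = w))
  factor(levels[idx], levels = levels)
}

#' Sample synthetic per-woman metadata
#'
#' BoP severity is drawn from `bop_weights`, periodontitis from
#' `perio_prob_by_bop[bop + 1]`, and demographics/technical covariates
#' from the published per-stratum distributions (normal for continuous
#' fields, stratum frequencies for categorical ones). Deterministic given
#' the seed.
#'
#' @param config `generator_config`.
#' @param seed integer RNG seed.
#' @return metadata data.frame with `config$n_samples` rows.
#' @export
sample_cohort_metadata <- function(config, seed = 1) {
  validate_generator_config(config)
  set.seed(seed)
  n <- config$n_samples
  if (n == 0) return(expand_table2()[0, ])
  bop <- sample(0:6, n, replace = TRUE, prob = config$bop_weights)
  perio <- rbinom(n, 1, config$perio_prob_by_bop[bop + 1]) == 1
  tab <- table2_strata()
  # stratum row for demographics; fall back to the periodontitis-free row
  # when a (bop, periodontitis) combination is absent from the table
  row_of <- function(b, p) {
    k <- which(tab$bop == b & tab$periodontitis == p)
    if (length(k) == 0) k <- which(tab$bop == b & !tab$periodontitis)
    k[1]
  }
  k <- mapply(row_of, bop, perio)
  meta <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    bop = as.integer(bop),
    periodontitis = perio,
    site = .rcat(tab$site_n[k, , drop = FALSE], .site_levels),
    intervention = .rcat(tab$intervention_n[k, , drop = FALSE],
                         .intervention_levels),
    hiv = runif(n) < tab$hiv_n[k] / tab$n[k],
    seqrun = .rcat(tab$seqrun_n[k, , drop = FALSE], .seqrun_levels),
    age = pmax(15, rnorm(n, tab$age_mean[k], tab$age_sd[k])),
    bmi = pmax(14, rnorm(n, tab$bmi_mean[k], tab$bmi_sd[k])),
    education = pmax(0, rnorm(n, tab$edu_mean[k], tab$edu_sd[k])),
    ses = rnorm(n, tab$ses_mean[k], tab$ses_sd[k]),
    anemia = runif(n) < tab$anemia_n[k] / tab$n[k],
    malaria = runif(n) < tab$malaria_n[k] / tab$n[k],
    stringsAsFactors = FALSE
  )
  meta
}

#' Generate synthetic taxon counts with ground truth
#'
#' Per sample, a library size `s` is drawn from a lognormal moment-matched
#' to the configured mean/SD. Per taxon and sample the expected count is
#' `mu = s * q * exp(eta)` with `q` the taxon's base relative abundance
#' and `eta` collecting the log-linear covariate effects
#' (`beta_bop * bop + beta_perio * perio`, plus any configured confounder
#' effects), a per-taxon-per-sample normal noise term, and, for taxa in a
#' latent module whose active stratum the sample belongs to,
#' `loading * z` with `z` a standard-normal factor shared by all module
#' taxa in that sample (inducing cooccurrence only in the active
#' stratum). The two random multiplicative terms are centered to mean one
#' on the natural scale, so expected library sizes stay at the configured
#' target. Counts are negative binomial with variance `mu + alpha * mu^2`.
#'
#' @param meta metadata data.frame (from [sample_cohort_metadata()] or real).
#' @param config `generator_config`.
#' @param seed integer RNG seed.
#' @return list with `counts` (count matrix) and `truth`
#'   (effect table, per-stratum latent log-scale correlation matrices,
#'   module memberships, drawn library sizes).
#' @export
generate_counts <- function(meta, config, seed = 1) {
  validate_generator_config(config)
  if (nrow(meta) == 0) stop("metadata is empty")
  set.seed(seed)
  n <- nrow(meta)
  D <- config$n_taxa
  # lognormal moment matching for library sizes
  cv2 <- (config$libsize_sd / config$libsize_mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(config$libsize_mean) - sdlog^2 / 2
  libsize <- stats::rlnorm(n, meanlog, sdlog)

  eff <- config$effect_table
  eta <- matrix(0, D, n, dimnames = list(config$taxon_ids, meta$sample_id))
  eta <- eta + outer(eff$beta_bop, meta$bop) +
    outer(eff$beta_perio, as.numeric(meta$periodontitis))
  if (!is.null(eff$beta_hiv))
    eta <- eta + outer(eff$beta_hiv, as.numeric(meta$hiv))
  # biological taxon-sample noise, mean-one on the natural scale so the
  # expected library size stays at the configured target
  eta <- eta + matrix(rnorm(D * n, 0, config$taxon_noise_sd), D, n) -
    config$taxon_noise_sd^2 / 2
  # the module factor is exp(loading * z) with z standard normal: median
  # one (so median-of-ratios normalization stays anchored on the unchanged
  # taxa) but mean exp(loading^2 / 2); the induced shift in a module
  # taxon's mean between strata is folded into the effective effect sizes
  # recorded in the ground truth
  module_membership <- list()
  eff_perio <- eff$beta_perio
  for (mi in seq_along(config$module_spec)) {
    m <- config$module_spec[[mi]]
    rows <- match(m$taxa, config$taxon_ids)
    active <- if (is.na(m$active_periodontitis)) rep(TRUE, n)
              else meta$periodontitis == m$active_periodontitis
    z <- rnorm(n)
    eta[rows, active] <- eta[rows, active] +
      m$loading * rep(z[active], each = length(rows))
    if (!is.na(m$active_periodontitis))
      eff_perio[rows] <- eff_perio[rows] +
        (if (m$active_periodontitis) 1 else -1) * m$loading^2 / 2
    module_membership[[mi]] <- list(taxa = m$taxa, loading = m$loading,
                                    active_periodontitis =
                                      m$active_periodontitis)
  }
  eff$beta_perio_effective <- eff_perio
  mu <- sweep(config$base_abundance * exp(eta), 2, libsize, "*")
  counts <- matrix(
    rnbinom(D * n, mu = as.vector(mu), size = rep(1 / config$dispersion, n)),
    D, n, dimnames = dimnames(eta))
  storage.mode(counts) <- "integer"

  truth <- list(
    effect_table = eff,
    module_membership = module_membership,
    basis_correlation = .truth_correlations(config),
    libsize = setNames(libsize, meta$sample_id)
  )
  list(counts = count_matrix(counts), truth = truth)
}

# Latent log-scale correlation among taxa within each periodontitis stratum:
# module taxa share variance loading^2 on top of taxon_noise_sd^2 when the
# module is active in the stratum. Taxa with no latent variation at all
# (no noise, no active module) are treated as uncorrelated unit-variance
# so the matrix stays a valid correlation matrix.
.truth_correlations <- function(config) {
  out <- list()
  for (stratum in c(FALSE, TRUE)) {
    v <- rep(config$taxon_noise_sd^2, config$n_taxa)
    C <- diag(v)
    for (m in config$module_spec) {
      if (!is.na(m$active_periodontitis) &&
          m$active_periodontitis != stratum) next
      rows <- match(m$taxa, config$taxon_ids)
      C[rows, rows] <- C[rows, rows] + m$loading^2
    }
    degenerate <- diag(C) == 0
    diag(C)[degenerate] <- 1
    R <- stats::cov2cor(C)
    dimnames(R) <- list(config$taxon_ids, config$taxon_ids)
    out[[if (stratum) "periodontitis" else "no_periodontitis"]] <- R
  }
  out
}

#' Generate representative sequences at controlled identities
#'
#' Each output sequence copies a reference sequence (recycled in order) and
#' substitutes exactly `round((1 - target/100) * L)` positions, each to a
#' different base, so the global identity to its reference is exactly the
#' target (up to the rounding of the substitution count).
#'
#' @param n_taxa number of sequences to produce.
#' @param reference named character vector of reference sequences.
#' @param identity_targets percent identities in [0, 100], recycled.
#' @param seed integer RNG seed.
#' @param taxon_ids optional output names (default `T001`...).
#' @return named character vector of sequences.
#' @export
generate_sequences <- function(n_taxa, reference, identity_targets,
                               seed = 1, taxon_ids = NULL) {
  validate_sequence_set(reference)
  if (any(identity_targets < 0 | identity_targets > 100))
    stop("identity targets must lie in [0, 100]")
  identity_targets <- rep_len(identity_targets, n_taxa)
  if (is.null(taxon_ids)) taxon_ids <- sprintf("T%03d", seq_len(n_taxa))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  out <- character(n_taxa)
  for (i in seq_len(n_taxa)) {
    ref <- reference[[(i - 1) %% length(reference) + 1]]
    s <- strsplit(ref, "")[[1]]
    L <- length(s)
    nsub <- round((1 - identity_targets[i] / 100) * L)
    if (nsub > 0) {
      pos <- sample.int(L, nsub)
      for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
    }
    out[i] <- paste(s, collapse = "")
  }
  names(out) <- taxon_ids
  out
}

#' Generate a random reference 16S fragment
#'
#' @param length sequence length in nt.
#' @param seed integer RNG seed.
#' @param id sequence name.
#' @return named character vector of length 1.
#' @export
random_reference_sequence <- function(length = 369, seed = 1,
                                      id = "reference") {
  set.seed(seed)
  setNames(paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = ""), id)
}

#' Simulate compositional counts from correlated lognormal basis abundances
#'
#' A small generator for validating compositional correlation estimators:
#' basis abundances are lognormal with a specified log-scale correlation
#' matrix, and observed counts are a multinomial draw of fixed depth from
#' the normalized basis composition of each sample.
#'
#' @param n_samples,n_taxa dimensions.
#' @param depth reads per sample.
#' @param log_corr log-scale correlation matrix (default identity).
#' @param meanlog per-taxon lognormal location (default spread over
#'   `[-1, 1]` so abundances vary).
#' @param sdlog common log-scale SD.
#' @param seed integer RNG seed.
#' @return list with `counts` (count matrix) and `basis_log` (latent
#'   log-abundance matrix, taxa x samples).
#' @export
simulate_correlated_composition <- function(n_samples, n_taxa, depth = 5000,
                                            log_corr = NULL, meanlog = NULL,
                                            sdlog = 1, seed = 1) {
  set.seed(seed)
  if (is.null(log_corr)) log_corr <- diag(n_taxa)
  if (is.null(meanlog)) meanlog <- seq(-1, 1, length.out = n_taxa)
  U <- chol(log_corr)
  Z <- matrix(rnorm(n_samples * n_taxa), n_samples, n_taxa) %*% U
  logx <- sweep(Z * sdlog, 2, meanlog, "+")
  counts <- matrix(0L, n_taxa, n_samples,
                   dimnames = list(sprintf("T%03d", seq_len(n_taxa)),
                                   sprintf("S%04d", seq_len(n_samples))))
  for (j in seq_len(n_samples)) {
    p <- exp(logx[j, ])
    counts[, j] <- as.integer(rmultinom(1, depth, p / sum(p)))
  }
  list(counts = count_matrix(counts), basis_log = t(logx))
}
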