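#' Pipeline configuration
#'
#' Collects input locations (or a synthetic-generator block), stage
#' toggles and per-stage parameters, with every threshold defaulting to
#' the study's stated value: 5000-read rarefaction depth averaged over
#' 100 iterations, q < 0.05, 20 SparCC inference iterations, 0.1
#' exclusion threshold, 100 permutations with edge significance 0.05,
#' 98.5% identity, complete linkage.
#'
#' @param output_dir directory for all outputs.
#' @param synthetic `NULL`, or a (possibly empty) list of
#'   [generator_config()] arguments; when given, inputs are generated
#'   rather than read.
#' @param counts_path,metadata_path,fasta_path input files (required when
#'   `synthetic` is `NULL`).
#' @param counts_format `"tsv"` or `"biom"`.
#' @param stages character vector of stages to run, in pipeline order.
#' @param depth,iterations,rarefaction_mode alpha-diversity parameters.
#' @param fdr differential-abundance significance on q.
#' @param sparcc_iters,exclusion SparCC parameters.
#' @param n_perm,significance permutation count and edge significance.
#' @param identity_threshold percent-identity selection cutoff.
#' @param linkage stratum-clustering linkage.
#' @param min_stratum_n smallest stratum modeled as a network.
#' @param seed global seed; per-stage substreams are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            synthetic = list(),
                            counts_path = NULL, metadata_path = NULL,
                            fasta_path = NULL, counts_format = "tsv",
                            stages = c("cohort_summary", "diversity",
                                       "differential_abundance", "selection",
                                       "networks", "clustering"),
                            depth = 5000, iterations = 100,
                            rarefaction_mode = "without_replacement",
                            fdr = 0.05, sparcc_iters = 20, exclusion = 0.1,
                            n_perm = 100, significance = 0.05,
                            identity_threshold = 98.5,
                            linkage = "complete", min_stratum_n = 25,
                            seed = 1) {
  if (is.null(synthetic)) {
    for (p in c(counts_path, metadata_path, fasta_path))
      if (!is.null(p) && !file.exists(p)) stop("no such input file: ", p)
    if (is.null(counts_path) || is.null(metadata_path))
      stop("counts_path and metadata_path are required without a ",
           "synthetic block")
  }
  stopifnot(depth >= 1, iterations >= 1, fdr > 0, fdr < 1,
            sparcc_iters >= 1, exclusion >= 0, n_perm >= 1,
            significance > 0, significance <= 1,
            identity_threshold >= 0, identity_threshold <= 100)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()] arguments; unknown keys are an
#' error.
#'
#' @param path YAML file.
#' @param output_dir optional override of the configured output directory.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path, output_dir = NULL) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), names(formals(pipeline_config)))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(output_dir)) y$output_dir <- output_dir
  do.call(pipeline_config, y)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  .write_tsv(df, path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input loading or synthetic generation, cohort
#' description, rarefaction-averaged diversity with backward stepwise
#' covariate models, joint NB-GLM differential abundance, selection of
#' phylotypes matching periodontitis-associated taxa at the identity
#' threshold, per-stratum SparCC correlation networks (with permutation
#' significance and a strong-edge network for the focal most-severe
#' periodontitis stratum), and Mantel-distance clustering of the
#' per-stratum correlation matrices. All outputs are files under
#' `config$output_dir`; a JSON manifest records files with MD5 hashes,
#' parameters and the derived per-stage seeds.
#'
#' @param config `pipeline_config`.
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # one global seed spawns fixed per-stage substreams, so a stage's
  # randomness does not depend on which other stages are enabled
  set.seed(config$seed)
  ss <- sample.int(.Machine$integer.max - 1, 8)
  stage_seeds <- list(metadata = ss[1], counts = ss[2], sequences = ss[3],
                      diversity = ss[4], networks = ss[5],
                      permutations = ss[6], layout = ss[7], extra = ss[8])
  files <- character(0)
  notes <- list()
  emit <- function(relpath) files <<- c(files, relpath)
  path <- function(relpath) file.path(out_dir, relpath)

  ## ---- inputs ----
  truth <- NULL
  if (!is.null(config$synthetic)) {
    gcfg <- do.call(generator_config, config$synthetic)
    meta <- sample_cohort_metadata(gcfg, seed = stage_seeds$metadata)
    gen <- generate_counts(meta, gcfg, seed = stage_seeds$counts)
    counts <- gen$counts
    truth <- gen$truth
    ref <- random_reference_sequence(gcfg$seq_length,
                                     seed = stage_seeds$sequences)
    seqs <- generate_sequences(gcfg$n_taxa, ref, gcfg$seq_identity_targets,
                               seed = stage_seeds$sequences,
                               taxon_ids = gcfg$taxon_ids)
    write_count_table(counts, path("counts.tsv")); emit("counts.tsv")
    write_metadata(meta, path("metadata.tsv")); emit("metadata.tsv")
    write_fasta(seqs, path("seqs.fasta")); emit("seqs.fasta")
    .write_json(list(
      effect_table = truth$effect_table,
      module_membership = truth$module_membership,
      libsize = unname(truth$libsize)), path("truth.json"))
    emit("truth.json")
  } else {
    counts <- read_count_table(config$counts_path, config$counts_format)
    meta <- read_metadata(config$metadata_path)
    seqs <- if (!is.null(config$fasta_path)) read_fasta(config$fasta_path)
            else NULL
  }
  al <- align_samples(counts, meta)
  counts <- al$counts; meta <- al$meta
  run_stage <- function(name) name %in% config$stages

  ## ---- cohort summary ----
  if (run_stage("cohort_summary")) {
    cs <- cohort_summary(meta)
    .write_json(cs[setdiff(names(cs), "strata")], path("cohort_summary.json"))
    .write_tsv(cs$strata, path("cohort_strata.tsv"))
    emit("cohort_summary.json"); emit("cohort_strata.tsv")
  }

  ## ---- diversity ----
  if (run_stage("diversity")) {
    div <- alpha_diversity(counts, depth = config$depth,
                           iterations = config$iterations,
                           mode = config$rarefaction_mode,
                           seed = stage_seeds$diversity)
    .write_tsv(div, path("diversity.tsv")); emit("diversity.tsv")
    covars <- meta[, c("bop", "periodontitis", "site", "intervention",
                       "hiv", "seqrun", "age", "bmi", "education", "ses",
                       "anemia", "malaria")]
    models <- list()
    for (resp in c("richness", "shannon")) {
      ok <- !div$excluded
      fitted <- tryCatch(
        backward_stepwise_lm(div[[resp]][ok], covars[ok, , drop = FALSE]),
        error = function(e) NULL)
      models[[resp]] <- if (is.null(fitted)) list(error = "model not fit")
        else list(retained = fitted$retained,
                  coefficients = fitted$coefficients,
                  aic_trace = fitted$aic_trace,
                  n_dropped_incomplete = fitted$n_dropped_incomplete)
    }
    .write_json(models, path("diversity_models.json"))
    emit("diversity_models.json")
  }

  ## ---- differential abundance ----
  da <- NULL
  if (run_stage("differential_abundance")) {
    da <- run_differential_abundance(counts, meta, fdr = config$fdr)
    .write_tsv(da$bop, path("diffabund_bop.tsv"))
    .write_tsv(da$periodontitis, path("diffabund_periodontitis.tsv"))
    .write_tsv(da$intersection, path("diffabund_intersection.tsv"))
    emit("diffabund_bop.tsv"); emit("diffabund_periodontitis.tsv")
    emit("diffabund_intersection.tsv")
  }

  ## ---- phylotype selection ----
  selected <- NULL
  if (run_stage("selection")) {
    if (is.null(da))
      stop("stage 'selection' requires stage 'differential_abundance'")
    if (is.null(seqs))
      stop("stage 'selection' requires representative sequences")
    hits <- da$periodontitis$taxon_id[da$periodontitis$significant &
                                        da$periodontitis$beta > 0]
    if (length(hits) == 0) {
      notes$selection <- "no periodontitis-associated taxa at the FDR cutoff"
      selected <- character(0)
    } else {
      sel <- select_by_identity(seqs, seqs[hits],
                                threshold = config$identity_threshold)
      .write_tsv(sel, path("selection.tsv")); emit("selection.tsv")
      selected <- sel$query_id[sel$selected]
      notes$selection <- sprintf(
        "%d periodontitis-associated taxa; %d phylotypes above %g%% identity",
        length(hits), length(selected), config$identity_threshold)
    }
  }

  ## ---- per-stratum networks ----
  corr_mats <- list()
  if (run_stage("networks")) {
    if (is.null(selected))
      stop("stage 'networks' requires stage 'selection'")
    strata <- unique(meta[, c("bop", "periodontitis")])
    strata <- strata[order(strata$bop, strata$periodontitis), , drop = FALSE]
    strata$n <- apply(strata, 1, function(s)
      sum(meta$bop == as.integer(s[["bop"]]) &
            meta$periodontitis == as.logical(s[["periodontitis"]])))
    strata <- strata[strata$n >= config$min_stratum_n, , drop = FALSE]
    nodes <- selected
    for (k in seq_len(nrow(strata))) {
      idx <- meta$bop == strata$bop[k] &
        meta$periodontitis == strata$periodontitis[k]
      nodes <- nodes[rowSums(counts[nodes, idx, drop = FALSE]) > 0]
    }
    if (length(nodes) < 4 || nrow(strata) == 0) {
      notes$networks <- sprintf(
        "skipped: %d shared non-zero nodes across %d strata (need >= 4)",
        length(nodes), nrow(strata))
    } else {
      for (k in seq_len(nrow(strata))) {
        key <- sprintf("bop%d_perio%s", strata$bop[k],
                       ifelse(strata$periodontitis[k], "yes", "no"))
        idx <- meta$bop == strata$bop[k] &
          meta$periodontitis == strata$periodontitis[k]
        fit <- sparcc(counts[nodes, idx, drop = FALSE],
                      inference_iters = config$sparcc_iters,
                      exclusion_threshold = config$exclusion,
                      seed = stage_seeds$networks + k)
        corr_mats[[key]] <- fit$corr
        f <- sprintf("corr_%s.tsv", key)
        .write_matrix_tsv(fit$corr, path(f), "taxon_id"); emit(f)
      }
      # focal network: the most severe periodontitis stratum present
      pk <- which(strata$periodontitis)
      focal <- if (length(pk) > 0) pk[which.max(strata$bop[pk])]
               else which.max(strata$n)
      key <- sprintf("bop%d_perio%s", strata$bop[focal],
                     ifelse(strata$periodontitis[focal], "yes", "no"))
      idx <- meta$bop == strata$bop[focal] &
        meta$periodontitis == strata$periodontitis[focal]
      sub <- counts[nodes, idx, drop = FALSE]
      pv <- permutation_pvalues(sub, corr_mats[[key]],
                                n_perm = config$n_perm,
                                inference_iters = config$sparcc_iters,
                                exclusion_threshold = config$exclusion,
                                seed = stage_seeds$permutations)
      thr <- strong_edge_cutoff(corr_mats[[key]])
      net <- build_network(corr_mats[[key]], pv, thr,
                           significance = config$significance)
      .write_tsv(net$edges, path("network_edges.tsv")); emit("network_edges.tsv")
      notes$focal_network <- sprintf(
        "stratum %s: threshold %.4f, %d nodes, %d edges, %d isolated removed",
        key, thr, length(net$node_ids), nrow(net$edges),
        length(net$dropped_nodes))
      if (nrow(net$edges) > 0) {
        write_network_graphml(net, path("network.graphml"))
        emit("network.graphml")
        if (length(net$node_ids) >= 3) {
          .write_tsv(betweenness_ranking(net), path("betweenness.tsv"))
          emit("betweenness.tsv")
        }
        xy <- layout_fr(net, seed = stage_seeds$layout)
        .write_matrix_tsv(xy, path("layout.tsv"), "node")
        emit("layout.tsv")
      }
    }
  }

  ## ---- stratum clustering ----
  if (run_stage("clustering")) {
    if (length(corr_mats) >= 2) {
      cl <- cluster_strata(corr_mats, linkage = config$linkage)
      writeLines(cl$newick, path("dendrogram.newick"))
      emit("dendrogram.newick")
      .write_matrix_tsv(as.matrix(cl$distances), path("mantel_distances.tsv"),
                        "stratum")
      emit("mantel_distances.tsv")
    } else {
      notes$clustering <- "skipped: fewer than 2 stratum networks"
    }
  }

  params <- config[setdiff(names(config), c("output_dir"))]
  params$stages <- as.list(config$stages)
  manifest <- list(
    package = "plaquenet",
    version = as.character(packageVersion("plaquenet")),
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    stage_seeds = stage_seeds,
    parameters = params[!vapply(params, is.null, logical(1))],
    notes = notes,
    files = lapply(setNames(files, files),
                   function(f) unname(tools::md5sum(path(f))))
  )
  .write_json(manifest, path("manifest.json"))
  invisible(manifest)
}
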