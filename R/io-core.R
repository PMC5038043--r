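#' @importFrom stats median cor var cov sd setNames complete.cases optimize
#'   pnorm p.adjust rbinom rgamma rmultinom rnorm rhyper runif rnbinom lm
#'   lm.wfit hclust as.dist cmdscale kruskal.test quantile dnbinom qlnorm
#'   ppoints aggregate
#' @importFrom utils read.delim write.table head packageVersion
NULL

# Category vocabularies shared by the metadata reader and the cohort generator.
.site_levels <- c("Lungwena", "Malindi", "Namwera", "Mangochi")
.intervention_levels <- c("IFA", "MMN", "LNS")
.seqrun_levels <- c("run1", "run2", "run3", "run4")

#' Construct and validate a taxon-by-sample count matrix
#'
#' The universal input of the pipeline: a non-negative integer matrix with
#' taxa as rows and samples as columns, both uniquely named. Stored as a
#' plain base matrix (storage mode integer) so it composes with standard
#' matrix tooling.
#'
#' @param counts numeric matrix of read counts, taxa x samples.
#' @param taxon_ids,sample_ids optional identifier vectors; default to the
#'   existing dimnames.
#' @return validated integer matrix with dimnames.
#' @export
count_matrix <- function(counts, taxon_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(taxon_ids) || is.null(sample_ids))
    stop("count_matrix requires taxon and sample identifiers")
  rownames(counts) <- as.character(taxon_ids)
  colnames(counts) <- as.character(sample_ids)
  validate_count_matrix(counts)
  storage.mode(counts) <- "integer"
  counts
}

#' Validate the count-matrix invariants
#'
#' Checks non-negativity, integrality and identifier uniqueness; errors
#' name the first offending cell or identifier.
#'
#' @param counts matrix to check.
#' @return the matrix, invisibly.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon (row) and sample (column) identifiers")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "count for taxon '%s', sample '%s' is not a non-negative integer: %s",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, 1], bad[1, 2]])))
  }
  invisible(counts)
}

#' Read a taxon-by-sample count table
#'
#' TSV tables are wide: taxa as rows, first column `taxon_id`, header row of
#' sample ids, tab-separated without quoting. BIOM tables follow the JSON
#' (version 1.0) layout and are read through \pkg{biomformat}.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @return integer count matrix (see [count_matrix()]); row and column
#'   order are preserved from the file.
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(count_matrix(m))
  }
  tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("count table needs a taxon_id column and >=1 sample")
  taxa <- tab[[1]]
  samples <- colnames(tab)[-1]
  m <- matrix(NA_real_, nrow = nrow(tab), ncol = length(samples),
              dimnames = list(taxa, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(tab[[j + 1]]))
    bad <- which(is.na(v))
    if (length(bad) > 0)
      stop(sprintf("non-numeric count for taxon '%s', sample '%s': '%s'",
                   taxa[bad[1]], samples[j], tab[[j + 1]][bad[1]]))
    m[, j] <- v
  }
  count_matrix(m)
}

#' Write a count table
#'
#' @param counts count matrix.
#' @param path output path.
#' @param format `"tsv"` or `"biom"` (JSON v1.0 layout).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  validate_count_matrix(counts)
  if (format == "biom") {
    b <- biomformat::make_biom(counts)
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  df <- data.frame(taxon_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.parse_bool <- function(x, field) {
  x0 <- tolower(trimws(x))
  out <- rep(NA, length(x0))
  out[x0 %in% c("yes", "true", "1")] <- TRUE
  out[x0 %in% c("no", "false", "0")] <- FALSE
  bad <- !is.na(x0) & x0 != "" & is.na(out)
  if (any(bad))
    stop(sprintf("field '%s': cannot interpret '%s' as yes/no", field,
                 x[which(bad)[1]]))
  out[x0 == ""] <- NA
  out
}

.parse_category <- function(x, levels, field) {
  x <- trimws(x)
  x[x == ""] <- NA
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad))
    stop(sprintf("field '%s': unknown label '%s' (expected one of %s)",
                 field, x[which(bad)[1]], paste(levels, collapse = ", ")))
  factor(x, levels = levels)
}

.parse_num <- function(x, field) {
  x <- trimws(x)
  x[x == ""] <- NA
  v <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(v)
  if (any(bad))
    stop(sprintf("field '%s': non-numeric value '%s'", field, x[which(bad)[1]]))
  v
}

#' Read a per-sample metadata table
#'
#' Expects a TSV with required columns `sample_id`, `bop` (number of
#' bleeding sextants, 0-6), `periodontitis`, `site`, `intervention`, `hiv`,
#' `seqrun`, and optional demographics (`age`, `bmi`, `education`, `ses`,
#' `anemia`, `malaria`). Booleans are accepted as yes/no, true/false or
#' 0/1; empty strings are treated as missing and are never imputed.
#'
#' @param path file path.
#' @return data.frame of typed per-sample records.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, colClasses = "character")
  req <- c("sample_id", "bop", "periodontitis", "site", "intervention",
           "hiv", "seqrun")
  miss <- setdiff(req, colnames(tab))
  if (length(miss) > 0)
    stop("metadata is missing required columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample ids in metadata")
  bop <- .parse_num(tab$bop, "bop")
  bad <- !is.na(bop) & (bop < 0 | bop > 6 | bop != round(bop))
  if (any(bad))
    stop(sprintf("bop must be an integer in 0..6; sample '%s' has %s",
                 tab$sample_id[which(bad)[1]], tab$bop[which(bad)[1]]))
  meta <- data.frame(
    sample_id = tab$sample_id,
    bop = as.integer(bop),
    periodontitis = .parse_bool(tab$periodontitis, "periodontitis"),
    site = .parse_category(tab$site, .site_levels, "site"),
    intervention = .parse_category(tab$intervention, .intervention_levels,
                                   "intervention"),
    hiv = .parse_bool(tab$hiv, "hiv"),
    seqrun = .parse_category(tab$seqrun, .seqrun_levels, "seqrun"),
    stringsAsFactors = FALSE
  )
  for (f in c("age", "bmi", "education", "ses"))
    meta[[f]] <- if (f %in% colnames(tab)) .parse_num(tab[[f]], f) else NA_real_
  for (f in c("anemia", "malaria"))
    meta[[f]] <- if (f %in% colnames(tab)) .parse_bool(tab[[f]], f) else NA
  meta
}

#' Write a per-sample metadata table
#'
#' Booleans are serialized as yes/no and missing values as empty strings,
#' round-tripping through [read_metadata()].
#'
#' @param meta metadata data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  out <- meta
  for (f in c("periodontitis", "hiv", "anemia", "malaria")) {
    if (f %in% colnames(out))
      out[[f]] <- ifelse(is.na(out[[f]]), "", ifelse(out[[f]], "yes", "no"))
  }
  for (f in colnames(out)) {
    if (is.factor(out[[f]])) out[[f]] <- as.character(out[[f]])
    out[[f]][is.na(out[[f]])] <- ""
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict counts and metadata to their shared samples
#'
#' Both objects are subset to the intersection of sample ids, in the count
#' matrix's column order; dropped ids on either side are reported in the
#' result.
#'
#' @param counts count matrix.
#' @param meta metadata data.frame.
#' @return list with `counts`, `meta`, `dropped_from_counts`,
#'   `dropped_from_meta`.
#' @export
align_samples <- function(counts, meta) {
  shared <- intersect(colnames(counts), meta$sample_id)
  if (length(shared) == 0)
    stop("counts and metadata share no sample ids")
  keep <- colnames(counts)[colnames(counts) %in% shared]
  list(
    counts = counts[, keep, drop = FALSE],
    meta = meta[match(keep, meta$sample_id), , drop = FALSE],
    dropped_from_counts = setdiff(colnames(counts), shared),
    dropped_from_meta = setdiff(meta$sample_id, shared)
  )
}

#' Read a DNA FASTA file
#'
#' @param path file path.
#' @return named character vector of uppercase sequences over A/C/G/T/N.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  validate_sequence_set(seqs)
  seqs
}

#' Write a DNA FASTA file (wrapped at 80 columns)
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  validate_sequence_set(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 80)
  invisible(path)
}

#' Validate a sequence set
#'
#' @param seqs named character vector.
#' @return `seqs`, invisibly.
#' @export
validate_sequence_set <- function(seqs) {
  if (length(seqs) == 0) stop("empty sequence set")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique ids")
  if (any(nchar(seqs) == 0)) stop("empty sequence present")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence '", names(seqs)[which(bad)[1]],
         "' contains characters outside A/C/G/T/N")
  invisible(seqs)
}
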