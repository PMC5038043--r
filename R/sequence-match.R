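# Scoring scheme for global alignment: match +1, mismatch -1, linear gap -2.
# N is treated as matching nothing (mismatch against every base and itself).
.nw_submat <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m["N", ] <- -1
  m[, "N"] <- -1
  m
}

#' Global percent identity between two DNA sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, linear gap
#' -2, via \pkg{Biostrings}), reporting percent identity as matched
#' columns over alignment columns. The default denominator includes gap
#' columns (alignment-length identity); `denominator = "matched_columns"`
#' restricts it to columns where neither sequence has a gap.
#'
#' @param a,b DNA strings over A/C/G/T/N (N never matches).
#' @param query_id,reference_id identifiers carried into the result.
#' @param denominator `"alignment_length"` (default) or
#'   `"matched_columns"`.
#' @return data.frame (one row) with `query_id`, `reference_id`,
#'   `identity` (percent), `aligned_columns`, `score`.
#' @export
global_identity <- function(a, b, query_id = "query",
                            reference_id = "reference",
                            denominator = c("alignment_length",
                                            "matched_columns")) {
  denominator <- match.arg(denominator)
  for (s in c(a, b)) {
    if (nchar(s) == 0) stop("empty sequence")
    if (grepl("[^ACGTN]", s))
      stop("sequence contains characters outside A/C/G/T/N")
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = .nw_submat(), gapOpening = 0, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  cols <- length(pa)
  matches <- sum(pa == pb & pa != "-" & pa != "N")
  denom <- if (denominator == "alignment_length") cols
           else sum(pa != "-" & pb != "-")
  data.frame(query_id = query_id, reference_id = reference_id,
             identity = 100 * matches / denom, aligned_columns = cols,
             score = Biostrings::score(al), stringsAsFactors = FALSE)
}

#' Select query sequences by best percent identity to a reference set
#'
#' All-vs-all exact global alignment; a query is selected when its best
#' identity over the references is strictly above the threshold
#' (mirroring a strict >98.5% species-level cutoff). The best hit per
#' query is reported, with ties broken by reference id.
#'
#' @param queries,references named character vectors of DNA sequences.
#' @param threshold percent identity cutoff (default 98.5; strict
#'   inequality).
#' @param denominator passed to [global_identity()].
#' @return data.frame with one row per query: `query_id`, `reference_id`
#'   (best hit), `identity`, `aligned_columns`, `selected`.
#' @export
select_by_identity <- function(queries, references, threshold = 98.5,
                               denominator = "alignment_length") {
  validate_sequence_set(queries)
  validate_sequence_set(references)
  rows <- vector("list", length(queries))
  ref_order <- sort(names(references))
  for (qi in seq_along(queries)) {
    best <- NULL
    for (rid in ref_order) {
      hit <- global_identity(queries[[qi]], references[[rid]],
                             query_id = names(queries)[qi],
                             reference_id = rid, denominator = denominator)
      if (is.null(best) || hit$identity > best$identity) best <- hit
    }
    rows[[qi]] <- best
  }
  out <- do.call(rbind, rows)
  out$selected <- out$identity > threshold
  rownames(out) <- NULL
  out
}
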