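# Contamination screening by lineage of the best database hit, best
# bidirectional hit intersection of call sets, introgression-region overlap,
# and one-directional comparison against external pangenome sequence sets.

#' Read a lineage table
#'
#' @param path 2-column TSV (seq_id, semicolon-separated taxonomy path).
#' @return data.frame with db_seq_id, lineage.
#' @export
read_lineage_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("db_seq_id", "lineage"),
                          stringsAsFactors = FALSE, quote = "")
  if (any(!nzchar(df$lineage))) stop("empty lineage path")
  df
}

lineage_is_contaminant <- function(lineage) {
  toks <- strsplit(lineage, ";", fixed = TRUE)[[1L]]
  toks <- trimws(toks)
  if (any(toks %in% c("Archaea", "Bacteria", "Viruses", "Viridiplantae")))
    return(TRUE)
  if ("Metazoa" %in% toks && !("Chordata" %in% toks)) return(TRUE)
  FALSE
}

#' Screen contigs for contamination by database lineage
#'
#' Each contig is aligned against a lineage-labeled database; the best
#' qualifying hit (identity >= `lineage_min_identity`, query coverage >=
#' `lineage_min_coverage`) assigns its lineage. A contig is a contaminant
#' when that lineage contains Archaea, Bacteria, Viruses or Viridiplantae,
#' or is metazoan without Chordata. Contigs with no qualifying hit are novel
#' and clean.
#'
#' @param contigs named character vector.
#' @param db named character vector (the screening database).
#' @param lineages data.frame from [read_lineage_table()].
#' @param params [pipeline_params()].
#' @return data.frame with contig, status (clean/contaminant), call (novel or
#'   the assigned lineage).
#' @export
lineage_screen <- function(contigs, db, lineages,
                           params = pipeline_params()) {
  stopifnot(all(names(db) %in% lineages$db_seq_id))
  lin <- stats::setNames(lineages$lineage, lineages$db_seq_id)
  idx <- build_index(db, k = min(params$index_k,
                                 max(11L, min(nchar(db)) %/% 3)))
  out <- data.frame(contig = names(contigs), status = "clean",
                    call = "novel", stringsAsFactors = FALSE)
  for (i in seq_along(contigs)) {
    h <- local_align(contigs[[i]], idx, min_score = 20)
    h <- h[h$identity >= params$lineage_min_identity &
             h$qcov >= params$lineage_min_coverage, , drop = FALSE]
    if (!nrow(h)) next
    best <- h[1L, ]          # hits are sorted by score
    lg <- lin[[best$tname]]
    out$call[i] <- lg
    out$status[i] <- if (lineage_is_contaminant(lg)) "contaminant" else "clean"
  }
  out
}

# all qualifying hits of each query in `qs` against indexed `ts`; best by
# score, ties by longer alignment then lexicographic target id
best_hit_per_query <- function(qs, ts, identity, coverage) {
  idx <- build_index(ts, k = 15L)
  vapply(seq_along(qs), function(i) {
    h <- local_align(qs[[i]], idx, min_score = 20,
                     seed_step = if (nchar(qs[[i]]) > 2000) 3L else 1L)
    h <- h[h$identity >= identity & h$qcov >= coverage, , drop = FALSE]
    if (!nrow(h)) return(NA_character_)
    alen <- h$tend - h$tstart
    h <- h[order(-h$score, -alen, h$tname), , drop = FALSE]
    h$tname[1L]
  }, character(1))
}

#' Best bidirectional hits between two sequence sets
#'
#' For every `a` in A the best hit `b*(a)` in B with identity and query
#' coverage above the thresholds is found, and vice versa; the pair (a, b)
#' is kept iff `b*(a) = b` and `a*(b) = a`.
#'
#' @param setA,setB named character vectors.
#' @param identity,coverage acceptance thresholds (default 0.95 / 0.95).
#' @return list with `pairs` (data.frame a, b) and `a_paired` (names of A
#'   members with a partner).
#' @export
best_bidirectional_hits <- function(setA, setB, identity = 0.95,
                                    coverage = 0.95) {
  stopifnot(length(setA) > 0, length(setB) > 0)
  bA <- best_hit_per_query(setA, setB, identity, coverage)
  bB <- best_hit_per_query(setB, setA, identity, coverage)
  names(bA) <- names(setA)
  names(bB) <- names(setB)
  a_names <- names(setA)
  keep <- !is.na(bA) & !is.na(bB[bA]) & bB[bA] == a_names
  pairs <- data.frame(a = a_names[keep], b = unname(bA[keep]),
                      stringsAsFactors = FALSE)
  list(pairs = pairs, a_paired = pairs$a)
}

#' Flag calls whose breakpoints fall inside regions
#'
#' A call is flagged when its zero-width breakpoint position `p` satisfies
#' `start <= p < end` for some region (half-open convention; a breakpoint at
#' the region end is outside).
#'
#' @param calls data.frame with chrom, pos.
#' @param regions data.frame with chrom, start, end.
#' @return list with `flagged` (logical per call) and `per_region` counts.
#' @export
region_overlap <- function(calls, regions) {
  flagged <- logical(nrow(calls))
  per_region <- integer(nrow(regions))
  if (nrow(regions)) {
    for (i in seq_len(nrow(regions))) {
      inr <- calls$chrom == regions$chrom[i] &
        calls$pos >= regions$start[i] & calls$pos < regions$end[i]
      per_region[i] <- sum(inr)
      flagged <- flagged | inr
    }
  }
  list(flagged = flagged, per_region = per_region)
}

#' One-directional comparison against an external sequence set
#'
#' A call is shared when any alignment against the external set reaches the
#' identity and query-coverage thresholds.
#'
#' @param calls named character vector of call sequences.
#' @param external named character vector.
#' @param identity,coverage thresholds (default 0.95 / 0.95).
#' @return list with `shared` (logical per call), `shared_ids`, `shared_bp`.
#' @export
compare_external <- function(calls, external, identity = 0.95,
                             coverage = 0.95) {
  idx <- build_index(external, k = 15L)
  shared <- vapply(seq_along(calls), function(i) {
    h <- local_align(calls[[i]], idx, min_score = 20,
                     seed_step = if (nchar(calls[[i]]) > 2000) 3L else 1L)
    any(h$identity >= identity & h$qcov >= coverage)
  }, logical(1))
  list(shared = shared, shared_ids = names(calls)[shared],
       shared_bp = sum(nchar(calls[shared])))
}
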