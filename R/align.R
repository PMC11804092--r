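# The shared alignment engine surface: k-mer indexing, seed-chain-extend
# local alignment, and short-read mapping. Scoring is fixed at +1 match,
# -4 mismatch, -6 gap open, -1 gap extend so scores are reproducible.

#' Build a canonical k-mer index over a set of sequences
#'
#' Every position of every sequence is indexed under the canonical form
#' (lexicographic minimum of the k-mer and its reverse complement); k-mers
#' containing `N` are skipped.
#'
#' @param seqs named character vector of target sequences.
#' @param k k-mer size, 11--31.
#' @return An object of class `kmer_index`.
#' @export
build_index <- function(seqs, k = 15L) {
  stopifnot(is.character(seqs), length(seqs) > 0)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ptr <- cpp_build_index(unname(seqs), names(seqs), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), names = names(seqs),
                 lengths = nchar(unname(seqs))),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("kmer_index: k =", x$k, ",", length(x$names), "sequence(s),",
      sum(x$lengths), "bp\n")
  invisible(x)
}

index_seqs <- function(index) cpp_index_seqs(index$ptr)

#' Local alignment of a query against an indexed target set
#'
#' Seeds are chained by diagonal consistency, chains are stitched with banded
#' affine dynamic programming and extended from both ends with an X-drop
#' band. Chains are split at net indels larger than `max_bridge` bases, so a
#' large insertion in the query yields two flanking hits rather than one
#' gapped alignment. Hits are sorted by score (ties: lower target id, lower
#' target start). An exact substring query returns identity 1 and query
#' coverage 1.
#'
#' @param query a single query sequence.
#' @param index a [build_index()] object over the targets.
#' @param min_score minimum alignment score to report.
#' @param seed_step sample a seed every this many query positions.
#' @param max_occ skip seeds whose k-mer occurs more often than this.
#' @param max_bridge largest net indel bridged within one hit.
#' @param min_chain_bp skip seed chains covering fewer than this many query
#'   bases before extension (0 disables; used when aligning whole contigs to
#'   avoid extending sparse chains between diverged repeat copies).
#' @return data.frame of hits: tname, tstart, tend, qstart, qend (forward
#'   query coordinates, 0-based half-open), strand, score, matches, columns,
#'   identity, qcov.
#' @export
local_align <- function(query, index, min_score = 20, seed_step = 1L,
                        max_occ = 200L, max_bridge = 30L, min_chain_bp = 0) {
  stopifnot(inherits(index, "kmer_index"), is.character(query),
            length(query) == 1)
  if (nchar(query) < index$k) {
    return(empty_hits())
  }
  df <- cpp_align(index$ptr, query, min_score = min_score,
                  seed_step = as.integer(seed_step),
                  max_occ = as.integer(max_occ),
                  max_bridge = as.integer(max_bridge),
                  min_chain_bp = min_chain_bp)
  df
}

empty_hits <- function() {
  data.frame(tid = integer(), tname = character(), tstart = numeric(),
             tend = numeric(), qstart = numeric(), qend = numeric(),
             strand = character(), score = numeric(), matches = numeric(),
             columns = numeric(), identity = numeric(), qcov = numeric(),
             stringsAsFactors = FALSE)
}

#' Map short reads to an indexed genome
#'
#' Ungapped best-diagonal placement by seed voting. A read is mapped when its
#' alignment score reaches `min_frac` of the maximum possible (its length);
#' otherwise it is flagged unmapped. Ties go to the lower target id, then
#' lower position.
#'
#' @param reads character vector of read sequences.
#' @param index a [build_index()] object.
#' @param min_frac mapped-score fraction threshold.
#' @param seed_step seed sampling step along the read.
#' @return data.frame with read, tid, tname, pos (0-based start, may be
#'   negative when the read overhangs the contig start), rev, score, mapped.
#' @export
map_reads <- function(reads, index, min_frac = 0.6, seed_step = 5L) {
  stopifnot(inherits(index, "kmer_index"))
  res <- cpp_map_reads(index$ptr, reads, min_frac = min_frac,
                       seed_step = as.integer(seed_step))
  data.frame(read = seq_along(reads), tid = res$tid,
             tname = ifelse(is.na(res$tid), NA_character_,
                            index$names[res$tid]),
             pos = res$pos, rev = res$rev, score = res$score,
             mapped = res$mapped, stringsAsFactors = FALSE)
}

#' Map a read pair
#'
#' Each mate is placed independently by [map_reads()]; the pair's orientation
#' and insert size are recorded when both mates map to the same target.
#'
#' @param r1,r2 mate sequences (single reads).
#' @param index a [build_index()] object.
#' @param min_frac mapped-score fraction threshold.
#' @return one-row data.frame with per-mate placements plus `proper` and
#'   `insert` fields.
#' @export
map_read_pair <- function(r1, r2, index, min_frac = 0.6) {
  m <- map_reads(c(r1, r2), index, min_frac = min_frac)
  proper <- m$mapped[1] && m$mapped[2] && m$tid[1] == m$tid[2] &&
    !identical(m$rev[1], m$rev[2])
  insert <- if (isTRUE(proper)) {
    abs(max(m$pos + c(nchar(r1), nchar(r2))) - min(m$pos))
  } else NA_integer_
  data.frame(mapped1 = m$mapped[1], tname1 = m$tname[1], pos1 = m$pos[1],
             rev1 = m$rev[1], mapped2 = m$mapped[2], tname2 = m$tname[2],
             pos2 = m$pos[2], rev2 = m$rev[2], proper = proper,
             insert = insert, stringsAsFactors = FALSE)
}

#' Export hits as a PAF-like tab-separated table
#'
#' @param hits data.frame from [local_align()].
#' @param query_name,query_len query identifier and length.
#' @param path output TSV path.
#' @param params optional [pipeline_params()] recorded in `#` header lines.
#' @export
write_hits <- function(hits, query_name, query_len, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    writeLines(sprintf("# %s=%s", names(params),
                       vapply(params, format, character(1))), con)
  }
  df <- data.frame(query = query_name, target = hits$tname,
                   q_start = hits$qstart, q_end = hits$qend,
                   t_start = hits$tstart, t_end = hits$tend,
                   strand = hits$strand, identity = hits$identity,
                   coverage = hits$qcov, score = hits$score)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
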