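# Alignment-branch insertion discovery: unmapped-read clusters on the
# pseudohaplotypes -> 7 kb-extended windows -> breakpoint resolution against
# the reference -> filtered, merged NUI call set.

#' Extract unmapped reads and their mates
#'
#' Given per-mate placements of a paired read set against the reference,
#' returns every read belonging to a pair with at least one unmapped mate
#' (the mapped mate is kept too). Order follows the input.
#'
#' @param m1,m2 placement data.frames from [map_reads()] for mate 1 / mate 2.
#' @param r1,r2 the read sequences.
#' @return character vector of read sequences.
#' @export
unmapped_reads <- function(m1, m2, r1, r2) {
  sel <- which(!m1$mapped | !m2$mapped)
  as.character(rbind(r1[sel], r2[sel]))
}

#' Find read clusters on a depth profile
#'
#' Maximal runs of positions with depth >= `cluster_cov_min` are candidate
#' clusters; runs separated by less than `cluster_merge_gap` bases are merged
#' first, then clusters whose mean depth exceeds `cluster_cov_max` are
#' discarded.
#'
#' @param depth integer vector of per-base depth along one contig.
#' @param params [pipeline_params()].
#' @return data.frame with start, end (0-based half-open), mean_depth.
#' @export
find_clusters <- function(depth, params = pipeline_params()) {
  above <- depth >= params$cluster_cov_min
  if (!any(above)) {
    return(data.frame(start = integer(), end = integer(),
                      mean_depth = numeric()))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by < cluster_merge_gap before the mean test
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] - merged$end[nrow(merged)] < params$cluster_merge_gap) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  merged$mean_depth <- vapply(seq_len(nrow(merged)), function(i)
    mean(depth[(merged$start[i] + 1L):merged$end[i]]), numeric(1))
  merged[merged$mean_depth <= params$cluster_cov_max, , drop = FALSE]
}

#' Extend a cluster along its contig
#'
#' @param cluster one-row data.frame with start, end.
#' @param contig_length length of the contig.
#' @param extension bases added on each side (default 7000), clipped at the
#'   contig ends.
#' @return c(start, end) of the extended window.
#' @export
extend_cluster <- function(cluster, contig_length, extension = 7000L) {
  c(max(0L, cluster$start - extension),
    min(contig_length, cluster$end + extension))
}

# per-contig depth from read placements
depth_from_placements <- function(pl, read_len, contig_len) {
  d <- integer(contig_len)
  ok <- which(pl$mapped)
  if (!length(ok)) return(d)
  s <- pmax(pl$pos[ok], 0L)
  e <- pmin(pl$pos[ok] + read_len, contig_len)
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  if (!length(s)) return(d)
  cumsum(tabulate(s + 1L, contig_len) - tabulate(e + 1L, contig_len))
}

#' Resolve an insertion inside an extended window
#'
#' The window sequence is aligned to the reference; the best co-linear anchor
#' pair (flank hits on the same chromosome and strand with a query gap of at
#' least `min_insertion_len` and a target gap within
#' `merge_breakpoint_slop`) defines the insertion: the unaligned query bases
#' between the anchors become the inserted sequence and the reference
#' coordinate between the anchors the zero-width breakpoint. Anchor overlap
#' on the reference (microhomology) is trimmed and the breakpoint is
#' left-aligned. Returns `NULL` when no anchor pair qualifies.
#'
#' @param extended_seq window sequence from the pseudohaplotype.
#' @param ref_index [build_index()] over the reference.
#' @param params [pipeline_params()].
#' @param genome reference sequences (named character vector); fetched from
#'   the index when omitted.
#' @param focus optional c(start, end) window coordinates of the read
#'   cluster; among qualifying pairs those overlapping the focus win.
#' @param min_anchor_score minimum score of each anchor hit.
#' @return one-row data.frame (chrom, pos, seq, len, left_anchor_len,
#'   right_anchor_len) or `NULL`.
#' @export
resolve_insertion <- function(extended_seq, ref_index,
                              params = pipeline_params(), genome = NULL,
                              focus = NULL, min_anchor_score = 40) {
  qlen <- nchar(extended_seq)
  if (qlen < 100) return(NULL)
  if (is.null(genome)) genome <- index_seqs(ref_index)
  hits <- local_align(extended_seq, ref_index, min_score = min_anchor_score,
                      seed_step = if (qlen > 2000) 3L else 1L,
                      min_chain_bp = if (qlen > 2000) 100 else 0)
  if (nrow(hits) < 2) return(NULL)
  slop <- params$merge_breakpoint_slop
  minlen <- params$min_insertion_len
  best <- NULL
  for (st in c("+", "-")) {
    hs <- hits[hits$strand == st, , drop = FALSE]
    if (nrow(hs) < 2) next
    if (st == "+") {
      hs$oqs <- hs$qstart; hs$oqe <- hs$qend
    } else {
      hs$oqs <- qlen - hs$qend; hs$oqe <- qlen - hs$qstart
    }
    oq <- if (st == "+") extended_seq else unname(revcomp(extended_seq))
    for (a in seq_len(nrow(hs))) {
      for (b in seq_len(nrow(hs))) {
        if (a == b) next
        if (hs$tname[a] != hs$tname[b]) next
        tgap <- hs$tstart[b] - hs$tend[a]
        # negative gaps (anchor overlap on the reference) are trimmed below
        if (tgap > slop || tgap < -50) next
        if (hs$oqs[b] <= hs$oqs[a]) next
        qa_end <- hs$oqe[a]
        qb_start <- hs$oqs[b]
        ts_b <- hs$tstart[b]
        if (tgap < 0) {               # microhomology: trim the right anchor
          qb_start <- qb_start - tgap
          ts_b <- ts_b - tgap
        }
        ins_len <- qb_start - qa_end
        if (ins_len < minlen) next
        if (qa_end < 1 || qb_start > qlen) next
        sc <- hs$score[a] + hs$score[b]
        in_focus <- TRUE
        if (!is.null(focus)) {
          fi <- if (st == "+") c(qa_end, qb_start) else
            c(qlen - qb_start, qlen - qa_end)
          in_focus <- fi[1] < focus[2] + 200 && fi[2] > focus[1] - 200
        }
        cand <- list(chrom = hs$tname[a], pos = hs$tend[a],
                     qa_end = qa_end, qb_start = qb_start, strand = st,
                     score = sc, in_focus = in_focus,
                     left_anchor = hs$oqe[a] - hs$oqs[a],
                     right_anchor = hs$oqe[b] - qb_start)
        better <- is.null(best) ||
          (cand$in_focus > best$in_focus) ||
          (cand$in_focus == best$in_focus && cand$score > best$score) ||
          (cand$in_focus == best$in_focus && cand$score == best$score &&
             cand$pos < best$pos)
        if (better) best <- c(cand, list(oq = oq))
      }
    }
  }
  if (is.null(best)) return(NULL)
  seq <- substr(best$oq, best$qa_end + 1L, best$qb_start)
  la <- left_align_insertion(genome[[best$chrom]], best$pos, seq)
  data.frame(chrom = best$chrom, pos = la$pos, seq = la$seq,
             len = nchar(la$seq), left_anchor_len = best$left_anchor,
             right_anchor_len = best$right_anchor, strand = best$strand,
             stringsAsFactors = FALSE)
}

#' Filter candidate insertion calls
#'
#' Drops calls whose sequence re-aligns to the reference with identity >=
#' `ref_match_identity` at full query coverage, calls whose breakpoint falls
#' in an assembly gap or segmental duplication, and calls with fewer than
#' `min_unique_bases` unique bases after repeat and low-complexity masking.
#'
#' @param calls data.frame with chrom, pos, seq (one row per call).
#' @param ref_index [build_index()] over the reference.
#' @param repeat_library consensus library for masking.
#' @param segdup_bed,gap_bed exclusion intervals (data.frames with chrom,
#'   start, end), possibly empty.
#' @param params [pipeline_params()].
#' @return The retained subset with an added `unique_bases` column.
#' @export
filter_candidates <- function(calls, ref_index, repeat_library,
                              segdup_bed = NULL, gap_bed = NULL,
                              params = pipeline_params()) {
  if (!nrow(calls)) {
    calls$unique_bases <- integer(0)
    return(calls)
  }
  excl <- rbind(
    if (!is.null(segdup_bed) && nrow(segdup_bed))
      segdup_bed[, c("chrom", "start", "end")],
    if (!is.null(gap_bed) && nrow(gap_bed))
      gap_bed[, c("chrom", "start", "end")])
  keep <- logical(nrow(calls))
  ub <- integer(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    # reference-match exclusion: >= 95% identity at 100% query coverage
    h <- local_align(calls$seq[i], ref_index, min_score = 20,
                     seed_step = if (calls$len[i] > 2000) 3L else 1L,
                     min_chain_bp = 60)
    ref_like <- nrow(h) > 0 && any(h$identity >= params$ref_match_identity &
                                     h$qcov >= params$ref_match_coverage - 1e-9)
    if (ref_like) next
    if (!is.null(excl) && nrow(excl)) {
      inside <- any(excl$chrom == calls$chrom[i] &
                      excl$start <= calls$pos[i] & calls$pos[i] < excl$end)
      if (inside) next
    }
    ann <- annotate_repeats(calls$seq[i], repeat_library, params)
    ub[i] <- unique_bases(ann)
    if (!passes_unique_filter(ann, params)) next
    keep[i] <- TRUE
  }
  out <- calls[keep, , drop = FALSE]
  out$unique_bases <- ub[keep]
  rownames(out) <- NULL
  out
}

# do two call sequences merge? shorter aligned to longer at >= identity with
# mutual coverage >= cov
seqs_equivalent <- function(s1, s2, identity = 0.95, cov = 0.95) {
  if (s1 == s2) return(TRUE)
  if (nchar(s1) > nchar(s2)) { tmp <- s1; s1 <- s2; s2 <- tmp }
  if (nchar(s1) / nchar(s2) < cov) return(FALSE)
  k <- min(15L, max(11L, nchar(s1) %/% 4))
  idx <- build_index(c(t = s2), k = k)
  h <- local_align(s1, idx, min_score = 0)
  if (!nrow(h)) return(FALSE)
  tcov <- (h$tend - h$tstart) / nchar(s2)
  any(h$identity >= identity & h$qcov >= cov & tcov >= cov)
}

#' Merge per-sample calls into a non-redundant NUI set
#'
#' Calls whose breakpoints lie within `merge_breakpoint_slop` of each other
#' and whose sequences align at `merge_identity` with mutual coverage
#' >= 0.95 collapse into one NUI; the longest sequence represents the group.
#' The occurrence table records which samples and pseudohaplotypes carry each
#' NUI. The result is independent of input order.
#'
#' @param calls data.frame with chrom, pos, seq, sample, hap.
#' @param params [pipeline_params()].
#' @return list with `nuis` (id, chrom, pos, seq, len, n_samples) and
#'   `occurrence` (nui_id, sample, hap).
#' @export
merge_call_set <- function(calls, params = pipeline_params()) {
  if (!nrow(calls)) {
    return(list(nuis = data.frame(id = character(), chrom = character(),
                                  pos = integer(), seq = character(),
                                  len = integer(), n_samples = integer(),
                                  stringsAsFactors = FALSE),
                occurrence = data.frame(nui_id = character(),
                                        sample = character(), hap = integer(),
                                        stringsAsFactors = FALSE)))
  }
  calls <- calls[order(calls$chrom, calls$pos, calls$seq, calls$sample), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  slop <- params$merge_breakpoint_slop
  group <- integer(nrow(calls))
  g <- 0L
  # breakpoint clusters (single linkage along sorted positions), then
  # sequence-similarity components within each cluster
  i <- 1L
  while (i <= nrow(calls)) {
    j <- i
    while (j < nrow(calls) && calls$chrom[j + 1L] == calls$chrom[i] &&
           calls$pos[j + 1L] - calls$pos[j] <= slop) j <- j + 1L
    members <- i:j
    comp <- seq_along(members)      # union-find over the cluster
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    if (length(members) > 1) {
      for (a in seq_along(members)[-1]) {
        for (b in seq_len(a - 1L)) {
          if (find(a) == find(b)) next
          if (seqs_equivalent(calls$seq[members[a]], calls$seq[members[b]],
                              params$merge_identity, 0.95)) {
            comp[find(a)] <- find(b)
          }
        }
      }
    }
    roots <- vapply(seq_along(members), find, integer(1))
    for (r in unique(roots)) {
      g <- g + 1L
      group[members[roots == r]] <- g
    }
    i <- j + 1L
  }
  nui_rows <- list()
  occ_rows <- list()
  for (gi in seq_len(g)) {
    m <- calls[group == gi, , drop = FALSE]
    rep_i <- which.max(nchar(m$seq))
    nui_rows[[gi]] <- data.frame(
      chrom = m$chrom[rep_i], pos = m$pos[rep_i], seq = m$seq[rep_i],
      len = nchar(m$seq[rep_i]), n_samples = length(unique(m$sample)),
      stringsAsFactors = FALSE)
    occ_rows[[gi]] <- unique(data.frame(group = gi, sample = m$sample,
                                        hap = m$hap, stringsAsFactors = FALSE))
  }
  nuis <- do.call(rbind, nui_rows)
  ord <- order(nuis$chrom, nuis$pos, nuis$seq)
  nuis <- nuis[ord, , drop = FALSE]
  remap <- stats::setNames(seq_len(nrow(nuis)), ord)
  nuis$id <- sprintf("NUI_%04d", seq_len(nrow(nuis)))
  nuis <- nuis[, c("id", "chrom", "pos", "seq", "len", "n_samples")]
  rownames(nuis) <- NULL
  occ <- do.call(rbind, occ_rows)
  occ$nui_id <- nuis$id[remap[as.character(occ$group)]]
  occ <- occ[order(occ$nui_id, occ$sample, occ$hap),
             c("nui_id", "sample", "hap")]
  rownames(occ) <- NULL
  list(nuis = nuis, occurrence = occ)
}

#' Run the full alignment-branch discovery pipeline on one sample
#'
#' Maps the sample's paired reads to the reference, extracts unmapped pairs,
#' remaps them to each pseudohaplotype, finds 8--100X read clusters, extends
#' each by 7 kb, and resolves breakpoints against the reference.
#'
#' @param reads list with `r1`, `r2`.
#' @param haps list with `hap1`, `hap2` named character vectors.
#' @param ref_index [build_index()] over the reference.
#' @param genome reference sequences.
#' @param sample sample name.
#' @param params [pipeline_params()].
#' @param read_len read length used for depth computation.
#' @return data.frame of raw calls (chrom, pos, seq, len, sample, hap, ...).
#' @export
discover_sample <- function(reads, haps, ref_index, genome, sample = "S1",
                            params = pipeline_params(), read_len = 100L) {
  m1 <- map_reads(reads$r1, ref_index, min_frac = params$map_min_frac)
  m2 <- map_reads(reads$r2, ref_index, min_frac = params$map_min_frac)
  um <- unmapped_reads(m1, m2, reads$r1, reads$r2)
  calls <- list()
  if (length(um)) {
    for (h in 1:2) {
      hap <- haps[[paste0("hap", h)]]
      hidx <- build_index(hap, k = params$index_k)
      pl <- map_reads(um, hidx, min_frac = params$map_min_frac)
      for (ci in seq_along(hap)) {
        d <- depth_from_placements(pl[pl$tid == ci, , drop = FALSE],
                                   read_len, nchar(hap[ci]))
        cl <- find_clusters(d, params)
        for (k in seq_len(nrow(cl))) {
          w <- extend_cluster(cl[k, ], nchar(hap[ci]),
                              params$cluster_extension)
          ext <- substr(hap[ci], w[1] + 1L, w[2])
          call <- resolve_insertion(
            ext, ref_index, params, genome,
            focus = c(cl$start[k], cl$end[k]) - w[1])
          if (!is.null(call)) {
            call$sample <- sample
            call$hap <- h
            calls[[length(calls) + 1L]] <- call
          }
        }
      }
    }
  }
  if (!length(calls)) {
    return(data.frame(chrom = character(), pos = integer(), seq = character(),
                      len = integer(), left_anchor_len = integer(),
                      right_anchor_len = integer(), strand = character(),
                      sample = character(), hap = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  # one window can be seen from both ends of a cluster; drop exact duplicates
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Discover NUIs across a set of sequenced samples
#'
#' Runs [discover_sample()] for every sample, applies [filter_candidates()]
#' and merges everything into a non-redundant call set.
#'
#' @param sample_data named list; each element holds `reads` and `haps` for
#'   one sample.
#' @param reference list with `genome` (named character vector).
#' @param repeat_library consensus library.
#' @param segdup_bed,gap_bed optional exclusion intervals.
#' @param params [pipeline_params()].
#' @param verbose print progress.
#' @return list with `nuis`, `occurrence` (see [merge_call_set()]) and
#'   `raw_calls`.
#' @export
discover_nuis <- function(sample_data, reference, repeat_library,
                          segdup_bed = NULL, gap_bed = NULL,
                          params = pipeline_params(), verbose = FALSE) {
  genome <- reference$genome
  ref_index <- build_index(genome, k = params$index_k)
  all_calls <- list()
  for (s in names(sample_data)) {
    if (verbose) message("discovering in ", s)
    sd <- sample_data[[s]]
    all_calls[[s]] <- discover_sample(sd$reads, sd$haps, ref_index, genome,
                                      sample = s, params = params)
  }
  calls <- do.call(rbind, all_calls)
  rownames(calls) <- NULL
  filtered <- filter_candidates(calls, ref_index, repeat_library,
                                segdup_bed, gap_bed, params)
  merged <- merge_call_set(filtered, params)
  merged$raw_calls <- calls
  merged
}
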