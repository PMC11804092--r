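# Graph-branch insertion discovery: Mash-ordered incremental augmentation of
# a reference backbone with assembly-derived insertion bubbles, GFA
# statistics (core/flexible partition, edge classes), and non-reference
# segment extraction. Only insertion bubbles are modeled; the graph exists to
# yield non-reference segments and their summary statistics.

#' Order assemblies by Mash distance to the reference
#'
#' @param reference named character vector (the reference genome).
#' @param assemblies named list of named character vectors (contigs).
#' @param k,s sketch parameters.
#' @return data.frame with assembly, distance, ordered ascending (ties by
#'   name).
#' @export
order_assemblies <- function(reference, assemblies, k = 21L, s = 1000L) {
  cat_genome <- function(seqs) paste(seqs, collapse = strrep("N", k))
  ref_sk <- mash_sketch(cat_genome(reference), k = k, s = s)
  d <- vapply(assemblies, function(a)
    mash_distance(ref_sk, mash_sketch(cat_genome(a), k = k, s = s)),
    numeric(1))
  out <- data.frame(assembly = names(assemblies), distance = unname(d),
                    stringsAsFactors = FALSE)
  out[order(out$distance, out$assembly), , drop = FALSE]
}

#' Start a multi-assembly graph from a reference backbone
#'
#' One segment per chromosome; backbone segments split lazily when
#' augmentation introduces insertion breakpoints.
#'
#' @param reference named character vector.
#' @param reference_label origin label of the backbone genome.
#' @param params [pipeline_params()].
#' @return A mutable `graph_builder` (environment).
#' @export
build_backbone <- function(reference, reference_label = "reference",
                           params = pipeline_params()) {
  b <- new.env(parent = emptyenv())
  b$genome <- reference
  b$ref_label <- reference_label
  b$ref_index <- build_index(reference, k = params$index_k)
  b$params <- params
  b$nonref <- data.frame(chrom = character(), pos = integer(),
                         seq = character(), len = integer(),
                         first_origin = character(), stringsAsFactors = FALSE)
  b$nonref_origins <- list()
  b$coverage <- list()   # assembly -> chrom -> intervals matrix
  b$added <- data.frame(assembly = character(), nodes = integer(),
                        bp = numeric(), stringsAsFactors = FALSE)
  class(b) <- "graph_builder"
  b
}

#' @export
print.graph_builder <- function(x, ...) {
  cat("graph_builder:", length(x$genome), "backbone chromosome(s),",
      nrow(x$nonref), "non-reference segment(s),",
      nrow(x$added), "assembly(ies) integrated\n")
  invisible(x)
}

# co-linear chain of hits for one contig: dominant (tname, + strand) group,
# then a score-weighted longest-colinear-subset DP. A greedy scan is not
# enough: a spurious cross-repeat hit early in query order can hijack the
# chain and shadow the genuine high-score flank anchors.
colinear_chain <- function(hits, max_overlap = 50) {
  hits <- hits[hits$strand == "+", , drop = FALSE]
  if (!nrow(hits)) return(hits)
  by_t <- tapply(hits$score, hits$tname, sum)
  hits <- hits[hits$tname == names(which.max(by_t)), , drop = FALSE]
  hits <- hits[order(hits$qstart, hits$tstart), , drop = FALSE]
  n <- nrow(hits)
  dp <- hits$score
  back <- integer(n)
  for (i in seq_len(n)) {
    if (i == 1) next
    j <- seq_len(i - 1L)
    ok <- hits$qend[j] <= hits$qstart[i] + max_overlap &
      hits$tend[j] <= hits$tstart[i] + max_overlap &
      hits$tstart[j] < hits$tstart[i] & hits$qstart[j] < hits$qstart[i]
    if (any(ok)) {
      jj <- j[ok]
      bestj <- jj[which.max(dp[jj])]
      cand <- dp[bestj] + hits$score[i]
      if (cand > dp[i]) { dp[i] <- cand; back[i] <- bestj }
    }
  }
  sel <- integer(0)
  i <- which.max(dp)
  while (i > 0) { sel <- c(i, sel); i <- back[i] }
  hits[sel, , drop = FALSE]
}

#' Augment the graph with one assembly
#'
#' Each contig is aligned to the backbone; adjacent co-linear anchors whose
#' query gap exceeds the minimum segment length (strict > 50 bp) while the
#' reference gap stays within the breakpoint slop define insertion bubbles.
#' A bubble matching an existing non-reference segment at the same
#' breakpoint (>= 95\% identity, mutual coverage >= 95\%) adds the assembly
#' to that segment's origin set; otherwise a new segment is created.
#' Reference coverage by the assembly's anchors is recorded for the
#' core/flexible partition. Assemblies must be supplied in
#' [order_assemblies()] order for distance-ranked integration.
#'
#' @param builder a [build_backbone()] object.
#' @param assembly_name origin label.
#' @param assembly_seqs named character vector of contigs.
#' @return invisible c(nodes, bp) added by this assembly.
#' @export
augment <- function(builder, assembly_name, assembly_seqs) {
  params <- builder$params
  slop <- params$merge_breakpoint_slop
  minseg <- params$graph_min_segment
  cov <- list()
  added_nodes <- 0L
  added_bp <- 0
  any_anchor <- FALSE
  for (ci in seq_along(assembly_seqs)) {
    contig <- assembly_seqs[[ci]]
    if (nchar(contig) < params$index_k) next
    hits <- local_align(contig, builder$ref_index, min_score = 100,
                        seed_step = if (nchar(contig) > 5000) 5L else 1L,
                        max_occ = if (nchar(contig) > 5000) 50L else 200L,
                        min_chain_bp = if (nchar(contig) > 5000) 500 else 0)
    chain <- colinear_chain(hits)
    if (!nrow(chain)) next
    any_anchor <- TRUE
    chrom <- chain$tname[1]
    iv <- cbind(chain$tstart, chain$tend)
    cov[[chrom]] <- rbind(cov[[chrom]], iv)
    if (nrow(chain) < 2) next
    for (i in seq_len(nrow(chain) - 1L)) {
      tgap <- chain$tstart[i + 1L] - chain$tend[i]
      # negative gaps are anchor overlaps (microhomology / extension
      # overshoot) and are trimmed away below
      if (tgap > slop || tgap < -50) next
      qa_end <- chain$qend[i]
      qb_start <- chain$qstart[i + 1L]
      ts_b <- chain$tstart[i + 1L]
      if (tgap < 0) { qb_start <- qb_start - tgap; ts_b <- ts_b - tgap }
      ins_len <- qb_start - qa_end
      if (ins_len <= minseg) next          # strict: segments must exceed 50 bp
      seq <- substr(contig, qa_end + 1L, qb_start)
      la <- left_align_insertion(builder$genome[[chrom]], chain$tend[i], seq)
      hit <- which(builder$nonref$chrom == chrom &
                     abs(builder$nonref$pos - la$pos) <= slop)
      matched <- FALSE
      for (j in hit) {
        if (seqs_equivalent(la$seq, builder$nonref$seq[j],
                            params$merge_identity, 0.95)) {
          builder$nonref_origins[[j]] <-
            union(builder$nonref_origins[[j]], assembly_name)
          matched <- TRUE
          break
        }
      }
      if (!matched) {
        builder$nonref <- rbind(builder$nonref, data.frame(
          chrom = chrom, pos = la$pos, seq = la$seq, len = nchar(la$seq),
          first_origin = assembly_name, stringsAsFactors = FALSE))
        builder$nonref_origins[[length(builder$nonref_origins) + 1L]] <-
          assembly_name
        added_nodes <- added_nodes + 1L
        added_bp <- added_bp + nchar(la$seq)
      }
    }
  }
  if (!any_anchor) warning("assembly ", assembly_name,
                           " has no anchor to the backbone; nothing added")
  builder$coverage[[assembly_name]] <- cov
  builder$added <- rbind(builder$added, data.frame(
    assembly = assembly_name, nodes = added_nodes, bp = added_bp,
    stringsAsFactors = FALSE))
  invisible(c(nodes = added_nodes, bp = added_bp))
}

# fraction of [start,end) covered by interval set
interval_cover_frac <- function(start, end, iv) {
  if (is.null(iv) || !nrow(iv)) return(0)
  s <- pmax(iv[, 1], start); e <- pmin(iv[, 2], end)
  keep <- e > s
  if (!any(keep)) return(0)
  o <- order(s[keep])
  s <- s[keep][o]; e <- e[keep][o]
  tot <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cur_e) { tot <- tot + cur_e - cur_s; cur_s <- s[i]; cur_e <- e[i] }
    else cur_e <- max(cur_e, e[i])
  }
  (tot + cur_e - cur_s) / (end - start)
}

#' Realize the builder into a pangenome graph
#'
#' Backbone chromosomes are split at every insertion breakpoint; each bubble
#' becomes a non-reference segment linked into the backbone. An assembly is
#' added to a reference segment's origin set when its anchor alignments
#' cover at least half of the segment.
#'
#' @param builder a [build_backbone()] object after augmentation.
#' @return A [pangenome_graph()].
#' @export
realize_graph <- function(builder) {
  ref_label <- builder$ref_label
  assemblies <- names(builder$coverage)
  seg_rows <- list(); link_rows <- list()
  nr <- builder$nonref
  nr_ord <- if (nrow(nr)) order(nr$chrom, nr$pos, nr$seq) else integer(0)
  nr_ids <- character(nrow(nr))
  cnt <- list()
  for (j in nr_ord) {
    fo <- nr$first_origin[j]
    cnt[[fo]] <- (if (is.null(cnt[[fo]])) 0L else cnt[[fo]]) + 1L
    nr_ids[j] <- sprintf("%s_%d", fo, cnt[[fo]])
  }
  for (chrom in names(builder$genome)) {
    cl <- nchar(builder$genome[[chrom]])
    bps <- sort(unique(nr$pos[nr$chrom == chrom]))
    bounds <- unique(c(0L, bps, cl))
    prev_id <- NULL
    for (si in seq_len(length(bounds) - 1L)) {
      s <- bounds[si]; e <- bounds[si + 1L]
      id <- sprintf("ref_%s_%d", chrom, si)
      orig <- ref_label
      for (a in assemblies) {
        if (interval_cover_frac(s, e, builder$coverage[[a]][[chrom]]) >= 0.5)
          orig <- c(orig, a)
      }
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        id = id, seq = substr(builder$genome[[chrom]], s + 1L, e),
        origins = paste(orig, collapse = ","), stringsAsFactors = FALSE)
      if (!is.null(prev_id)) {
        link_rows[[length(link_rows) + 1L]] <- data.frame(
          from = prev_id, from_orient = "+", to = id, to_orient = "+",
          stringsAsFactors = FALSE)
      }
      # bubbles at the junction s (start of this segment)
      at <- which(nr$chrom == chrom & nr$pos == s)
      for (j in at) {
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          id = nr_ids[j], seq = nr$seq[j],
          origins = paste(sort(builder$nonref_origins[[j]]), collapse = ","),
          stringsAsFactors = FALSE)
        if (!is.null(prev_id)) {
          link_rows[[length(link_rows) + 1L]] <- data.frame(
            from = prev_id, from_orient = "+", to = nr_ids[j],
            to_orient = "+", stringsAsFactors = FALSE)
        }
        link_rows[[length(link_rows) + 1L]] <- data.frame(
          from = nr_ids[j], from_orient = "+", to = id, to_orient = "+",
          stringsAsFactors = FALSE)
      }
      prev_id <- id
    }
  }
  pangenome_graph(do.call(rbind, seg_rows),
                  if (length(link_rows)) do.call(rbind, link_rows) else NULL,
                  reference_label = ref_label)
}

#' Node, edge and core/flexible statistics of a pangenome graph
#'
#' Core segments are those whose origin set contains all `n_genomes` genome
#' labels (the reference counts as one); the rest are flexible, split into
#' shared (present in >= 2 genomes) and single-genome segments. Percentages
#' are base-pair shares of the total, rounded to 2 decimals. Edge classes
#' follow the reference labeling of their endpoints.
#'
#' @param graph a [pangenome_graph()].
#' @param n_genomes total number of genomes (reference + assemblies).
#' @return A named list of statistics.
#' @export
graph_stats <- function(graph, n_genomes) {
  s <- graph$segments
  orig <- strsplit(s$origins, ",", fixed = TRUE)
  is_ref <- vapply(orig, function(o) graph$reference_label %in% o, logical(1))
  n_orig <- lengths(orig)
  core <- n_orig >= n_genomes
  single <- n_orig == 1L
  l <- graph$links
  ref_of <- stats::setNames(is_ref, s$id)
  e_rr <- sum(ref_of[l$from] & ref_of[l$to])
  e_nn <- sum(!ref_of[l$from] & !ref_of[l$to])
  e_rn <- nrow(l) - e_rr - e_nn
  bp_total <- sum(s$length)
  per_assembly <- NULL
  all_assemblies <- setdiff(sort(unique(unlist(orig))), graph$reference_label)
  if (length(all_assemblies)) {
    per_assembly <- do.call(rbind, lapply(all_assemblies, function(a) {
      inb <- vapply(orig, function(o) a %in% o, logical(1)) & !is_ref
      data.frame(assembly = a, nodes = sum(inb), bp = sum(s$length[inb]),
                 stringsAsFactors = FALSE)
    }))
  }
  list(
    n_nodes = nrow(s), n_nodes_ref = sum(is_ref), n_nodes_nonref = sum(!is_ref),
    bp_total = bp_total, bp_ref = sum(s$length[is_ref]),
    bp_nonref = sum(s$length[!is_ref]),
    edges_total = nrow(l), edges_ref_ref = e_rr, edges_ref_nonref = e_rn,
    edges_nonref_nonref = e_nn,
    core_nodes = sum(core), core_bp = sum(s$length[core]),
    flexible_nodes = sum(!core), flexible_bp = sum(s$length[!core]),
    flexible_shared_nodes = sum(!core & !single),
    flexible_shared_bp = sum(s$length[!core & !single]),
    flexible_single_nodes = sum(!core & single),
    flexible_single_bp = sum(s$length[!core & single]),
    pct_core = round(100 * sum(s$length[core]) / bp_total, 2),
    pct_flexible = round(100 * sum(s$length[!core]) / bp_total, 2),
    per_assembly_nonref = per_assembly
  )
}

#' Extract non-reference segments exceeding the length floor
#'
#' @param graph a [pangenome_graph()].
#' @param min_len strict lower bound: only segments longer than this are
#'   returned (default 50, matching retention of contigs exceeding 50 bp).
#' @return Named character vector of segment sequences (stable ids).
#' @export
extract_nonref <- function(graph, min_len = 50L) {
  s <- graph$segments
  is_ref <- grepl_origin(s$origins, graph$reference_label)
  keep <- !is_ref & s$length > min_len
  stats::setNames(s$seq[keep], s$id[keep])
}
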