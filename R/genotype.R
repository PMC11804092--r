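# Presence/absence genotyping of the NUI set across a read cohort, MAF
# filtering to the common-insertion (BICI) set, the 0/1/2 occurrence matrix,
# PCA and hierarchical clustering.

#' Build a carrier template for genotyping
#'
#' Splices the NUI set into the reference, producing one target sequence set
#' that carries every NUI at its breakpoint, with the NUI intervals recorded
#' in template coordinates. Cohort reads are genotyped against this
#' template.
#'
#' @param reference list with `genome` (named character vector).
#' @param nuis data.frame with id, chrom, pos, seq.
#' @return list with `template` (named character vector) and `intervals`
#'   (data.frame: nui_id, contig, start, end).
#' @export
build_carrier_template <- function(reference, nuis) {
  genome <- reference$genome
  template <- genome
  names(template) <- paste0("tmpl_", names(genome))
  iv_rows <- list()
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    idx <- which(nuis$chrom == chrom)
    if (!length(idx)) next
    sp <- splice_insertions(genome[[ci]], nuis$pos[idx], nuis$seq[idx])
    template[ci] <- sp$seq
    iv_rows[[length(iv_rows) + 1L]] <- data.frame(
      nui_id = nuis$id[idx][sp$order], contig = names(template)[ci],
      start = sp$intervals[, 1], end = sp$intervals[, 2],
      stringsAsFactors = FALSE)
  }
  intervals <- if (length(iv_rows)) do.call(rbind, iv_rows) else
    data.frame(nui_id = character(), contig = character(), start = integer(),
               end = integer(), stringsAsFactors = FALSE)
  list(template = template, intervals = intervals)
}

#' Genotype NUIs in one sample from mapped reads
#'
#' For every NUI interval the covered fraction (positions with depth >= 1)
#' and the majority-consensus identity against the template (ties resolved
#' to the template base) are computed; the NUI is present iff covered
#' fraction >= `genotype_coverage` and consensus identity >=
#' `genotype_identity` (the 80/90 rule).
#'
#' @param reads character vector of the sample's reads (both mates pooled).
#' @param template_index [build_index()] over the carrier template.
#' @param template named character vector (the template sequences).
#' @param intervals data.frame from [build_carrier_template()].
#' @param sample sample name.
#' @param params [pipeline_params()].
#' @return data.frame: sample, nui_id, covered_fraction, consensus_identity,
#'   mean_depth, present.
#' @export
genotype_sample <- function(reads, template_index, template, intervals,
                            sample = "S1", params = pipeline_params()) {
  if (any(intervals$end <= intervals$start)) stop("zero-length NUI interval")
  pl <- map_reads(reads, template_index, min_frac = params$map_min_frac)
  out <- list()
  for (ci in seq_along(template)) {
    iv <- intervals[intervals$contig == names(template)[ci], , drop = FALSE]
    if (!nrow(iv)) next
    sel <- which(pl$mapped & pl$tid == ci)
    ev <- cpp_interval_evidence(template[[ci]], iv$start, iv$end,
                                reads[sel], pl$pos[sel], pl$rev[sel])
    out[[length(out) + 1L]] <- data.frame(
      sample = sample, nui_id = iv$nui_id,
      covered_fraction = ev[, "covered_fraction"],
      consensus_identity = ev[, "consensus_identity"],
      mean_depth = ev[, "mean_depth"], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$present <- res$covered_fraction >= params$genotype_coverage &
    res$consensus_identity >= params$genotype_identity
  rownames(res) <- NULL
  res
}

#' Consolidate per-sample genotype calls into a matrix
#'
#' @param calls data.frame with sample, nui_id, present (rbind of
#'   [genotype_sample()] outputs).
#' @param breed_of optional named vector mapping sample to breed.
#' @return list with `matrix` (samples x NUIs logical, sorted ids),
#'   `evidence` (the input calls) and `breed` labels.
#' @export
build_matrix <- function(calls, breed_of = NULL) {
  samples <- sort(unique(calls$sample))
  nuis <- sort(unique(calls$nui_id))
  M <- matrix(NA, nrow = length(samples), ncol = length(nuis),
              dimnames = list(samples, nuis))
  M[cbind(match(calls$sample, samples), match(calls$nui_id, nuis))] <-
    calls$present
  if (anyNA(M)) stop("genotype matrix incomplete: ", sum(is.na(M)),
                     " missing cell(s)")
  breed <- if (!is.null(breed_of)) unname(breed_of[samples]) else
    rep(NA_character_, length(samples))
  list(matrix = M, evidence = calls, breed = breed)
}

#' Filter NUIs by minor allele frequency
#'
#' The presence frequency `f` of each NUI across all samples gives
#' `MAF = min(f, 1 - f)`; NUIs with MAF below `maf_min` are excluded.
#' Monomorphic NUIs (present in none or all samples) always drop out.
#'
#' @param genotype_matrix samples x NUIs logical/0-1 matrix.
#' @param maf_min frequency floor (default 0.05).
#' @return Character vector of retained NUI ids (the BICI set).
#' @export
maf_filter <- function(genotype_matrix, maf_min = 0.05) {
  f <- colMeans(genotype_matrix)
  maf <- pmin(f, 1 - f)
  colnames(genotype_matrix)[maf >= maf_min & f > 0 & f < 1]
}

#' Assembly-level 0/1/2 occurrence matrix
#'
#' Codes each insertion per assembly as 0 (absent from both
#' pseudohaplotypes), 1 (present in one) or 2 (present in both).
#'
#' @param occurrence data.frame with nui_id, sample, hap (from
#'   [merge_call_set()]).
#' @param samples assembly/sample names (matrix rows).
#' @param nui_ids insertion ids (matrix columns).
#' @return Integer matrix with values in `{0, 1, 2}`.
#' @export
occurrence_matrix <- function(occurrence, samples, nui_ids) {
  M <- matrix(0L, nrow = length(samples), ncol = length(nui_ids),
              dimnames = list(samples, nui_ids))
  occ <- unique(occurrence[occurrence$sample %in% samples &
                             occurrence$nui_id %in% nui_ids, ])
  for (i in seq_len(nrow(occ))) {
    M[occ$sample[i], occ$nui_id[i]] <- M[occ$sample[i], occ$nui_id[i]] + 1L
  }
  if (any(M > 2L)) stop("more than two pseudohaplotype occurrences recorded")
  M
}

#' Principal component analysis of an occurrence or genotype matrix
#'
#' Columns are centered (constant columns dropped), not scaled; the
#' covariance eigendecomposition gives scores and explained-variance
#' fractions (summing to 1 over retained components).
#'
#' @param M samples x insertions numeric matrix (0/1 or 0/1/2).
#' @return list with `scores`, `explained` and the fitted `prcomp` object.
#' @export
pca_matrix <- function(M) {
  M <- as.matrix(M) * 1
  keep <- apply(M, 2, function(x) stats::var(x) > 0)
  M <- M[, keep, drop = FALSE]
  if (!ncol(M)) stop("no variable columns for PCA")
  p <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, explained = expl, fit = p)
}

#' Hierarchical clustering of presence/absence profiles
#'
#' Pairwise Jaccard distances between sample profiles, average-linkage
#' (UPGMA) clustering, serialized as a Newick string. Sample order is fixed
#' by id so ties resolve deterministically.
#'
#' @param genotype_matrix samples x NUIs logical/0-1 matrix.
#' @return list with `newick`, `hclust` and the `dist` object.
#' @export
hierarchical_cluster <- function(genotype_matrix) {
  M <- (as.matrix(genotype_matrix) * 1)[order(rownames(genotype_matrix)), ,
                                        drop = FALSE]
  d <- vegan::vegdist(M, method = "jaccard", binary = TRUE)
  d[is.na(d)] <- 0      # two all-absent profiles are identical
  hc <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  list(newick = ape::write.tree(phy), hclust = hc, dist = d)
}
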