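#' Pipeline parameter registry
#'
#' Central registry of every numeric threshold used across the workflow.
#' Defaults follow the published pipeline where the number is printed
#' (cluster coverage window 8--100X, 7,000 bp cluster extension, >= 50 bp
#' insertions, >= 50 unique bases, 95\% identity / 100\% coverage reference
#' filter, 95/95 best-bidirectional-hit and cross-species thresholds, 80\%
#' coverage / 90\% identity genotyping rule, MAF >= 5\%, 300 bp repeat flanks,
#' 20 kb nearest-gene window, > 50 bp graph segments); the remaining values
#' are this package's own defaults for steps the original delegated to
#' external tools (Mash sketching, DUST, repeat-hit acceptance, call merging).
#'
#' @param ... name-value overrides of any default listed below.
#'
#' @return A named list of parameters with class `pipeline_params`.
#' @export
#' @examples
#' p <- pipeline_params(maf_min = 0.10)
#' p$maf_min
pipeline_params <- function(...) {
  defaults <- list(
    min_insertion_len   = 50L,     # bp, smallest reported insertion
    cluster_cov_min     = 8,       # X, read-cluster lower depth bound
    cluster_cov_max     = 100,     # X, read-cluster upper mean-depth bound
    cluster_merge_gap   = 100L,    # bp, runs closer than this merge
    cluster_extension   = 7000L,   # bp, extension on each cluster end
    min_unique_bases    = 50L,     # bp, unmasked bases an NUI must keep
    ref_match_identity  = 0.95,    # reference re-alignment exclusion
    ref_match_coverage  = 1.00,    # ... requires full query coverage
    bbh_identity        = 0.95,    # best-bidirectional-hit thresholds
    bbh_coverage        = 0.95,
    genotype_coverage   = 0.80,    # presence rule: covered fraction
    genotype_identity   = 0.90,    # presence rule: consensus identity
    maf_min             = 0.05,    # minor allele frequency floor
    te_flank            = 300L,    # bp, flank taken around each insertion
    nearest_gene_window = 20000L,  # bp
    graph_min_segment   = 50L,     # bp, strict '>' for non-reference nodes
    species_identity    = 0.95,    # cross-species presence thresholds
    species_coverage    = 0.95,
    mash_k              = 21L,
    mash_sketch         = 1000L,
    dust_window         = 64L,
    dust_threshold      = 20,      # score scale T; masking uses T/10
    repeat_hit_identity = 0.80,
    repeat_hit_minlen   = 30L,
    merge_breakpoint_slop = 10L,   # bp, breakpoints this close may merge
    merge_identity      = 0.95,
    lineage_min_identity = 0.80,   # minimum reportable lineage hit
    lineage_min_coverage = 0.50,
    index_k             = 15L,     # k-mer size, genome-scale index
    repeat_k            = 12L,     # k-mer size, repeat-library alignment
    map_min_frac        = 0.6      # read mapped iff score >= frac * max score
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(defaults))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    defaults[names(ov)] <- ov
  }
  fr <- c("ref_match_identity", "ref_match_coverage", "bbh_identity",
          "bbh_coverage", "genotype_coverage", "genotype_identity", "maf_min",
          "species_identity", "species_coverage", "repeat_hit_identity",
          "merge_identity", "lineage_min_identity", "lineage_min_coverage",
          "map_min_frac")
  for (f in fr) {
    v <- defaults[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(f, " must be a fraction in [0,1]")
  }
  ln <- c("min_insertion_len", "cluster_merge_gap", "cluster_extension",
          "min_unique_bases", "te_flank", "nearest_gene_window",
          "graph_min_segment", "mash_k", "mash_sketch", "dust_window",
          "repeat_hit_minlen", "merge_breakpoint_slop", "index_k", "repeat_k")
  for (f in ln) {
    v <- defaults[[f]]
    if (!is.numeric(v) || v <= 0 || v != round(v)) stop(f, " must be a positive integer")
  }
  structure(defaults, class = "pipeline_params")
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("pipeline_params:", length(x), "parameters\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Restore RNG state after seeded generation so generators are pure in (params, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
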