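# Desk-scale study presets and truth-based evaluation. The presets define
# the simulated study conditions used throughout the tests, the analysis
# scripts and the acceptance report: a 2 Mb / 5-sample discovery cohort
# sequenced at 30X with 0.1% substitution error, and a 98-sample genotyping
# cohort over a smaller reference.

# derived seeds stay below 2^31
dseed <- function(seed, i) as.integer((as.numeric(seed) * 1009 + i) %% 2147483647)

#' Simulate the discovery study
#'
#' Two 1 Mb chromosomes at 25\% repeat density, 60 clean-context insertions
#' of 50 bp--5 kb, five sequenced samples (one per breed) with two
#' pseudohaplotypes each, paired 100 bp reads at 30X with 0.1\% substitution
#' error.
#'
#' @param seed study seed; every generated object derives from it.
#' @param n_samples sequenced samples (default 5).
#' @param coverage read depth (default 30).
#' @return list with `reference`, `library`, `insertions`, `cohort`,
#'   `sample_data` (per sample: `haps`, `reads`) and `truth` (insertions
#'   carried by at least one sequenced sample, breakpoints left-aligned).
#' @export
simulate_discovery_study <- function(seed = 1L, n_samples = 5L,
                                     coverage = 30) {
  lib <- make_repeat_library(2L, seed = dseed(seed, 1))
  ref <- make_reference(n_chrom = 2L, chrom_len = 1e6, repeat_library = lib,
                        repeat_density = 0.25, seed = dseed(seed, 2))
  ins <- make_insertions(ref, lib, n = 60L,
                         size_mix = default_size_mix(5000),
                         seed = dseed(seed, 3))
  breeds <- c("Gir", "Kankrej", "Tharparkar", "Sahiwal", "RedSindhi")
  co <- make_cohort(ins, breeds = breeds[seq_len(n_samples)],
                    n_per_breed = 1L, seed = dseed(seed, 4))
  sample_data <- list()
  for (si in seq_len(nrow(co$samples))) {
    nm <- co$samples$sample[si]
    haps <- build_pseudohaplotypes(ref, ins, co$genotypes[si, ],
                                   co$het_hap[si, ], sample = nm)
    reads <- simulate_reads(haps, coverage = coverage, err_rate = 0.001,
                            seed = dseed(seed, 100 + si))
    sample_data[[nm]] <- list(haps = haps, reads = reads)
  }
  carried <- colSums(co$genotypes) > 0
  truth <- ins[carried, , drop = FALSE]
  norm <- lapply(seq_len(nrow(truth)), function(i)
    left_align_insertion(ref$genome[[truth$chrom[i]]], truth$pos[i],
                         truth$seq[i]))
  truth$pos <- vapply(norm, `[[`, numeric(1), "pos")
  truth$seq <- vapply(norm, `[[`, character(1), "seq")
  rownames(truth) <- NULL
  list(reference = ref, library = lib, insertions = ins, cohort = co,
       sample_data = sample_data, truth = truth)
}

#' Compare a call set with ground truth
#'
#' A truth insertion is recovered when a call on the same chromosome has its
#' breakpoint within `tol` bases and an equivalent sequence (>= 95\%
#' identity, mutual coverage >= 95\%); both sides are left-aligned, so exact
#' breakpoints are well defined.
#'
#' @param calls data.frame with chrom, pos, seq.
#' @param truth data.frame with chrom, pos, seq (normalized).
#' @param tol breakpoint tolerance in bp (default 5).
#' @return list with recall, precision, breakpoint_exact (fraction of
#'   recovered truth with an exact-breakpoint call), n_truth, n_calls and
#'   the per-truth match table.
#' @export
evaluate_calls <- function(calls, truth, tol = 5) {
  matched_call <- logical(nrow(calls))
  rec <- logical(nrow(truth))
  exact <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cand <- which(calls$chrom == truth$chrom[i] &
                    abs(calls$pos - truth$pos[i]) <= tol)
    for (j in cand) {
      if (calls$seq[j] == truth$seq[i] ||
          seqs_equivalent(calls$seq[j], truth$seq[i], 0.95, 0.95)) {
        rec[i] <- TRUE
        matched_call[j] <- TRUE
        if (calls$pos[j] == truth$pos[i]) exact[i] <- TRUE
      }
    }
  }
  list(recall = mean(rec), precision = mean(matched_call),
       breakpoint_exact = if (any(rec)) mean(exact[rec]) else 0,
       n_truth = nrow(truth), n_calls = nrow(calls),
       recovered = rec, exact = exact)
}

#' Recovery of truth insertions among graph segments
#'
#' @param segments named character vector from [extract_nonref()].
#' @param truth truth insertions (only those with length >= `min_len` are
#'   scored).
#' @param min_len length floor for scoring (default 100).
#' @return list with recovery fraction and per-truth hits.
#' @export
evaluate_graph_segments <- function(segments, truth, min_len = 100L) {
  t <- truth[truth$len >= min_len, , drop = FALSE]
  hit <- vapply(seq_len(nrow(t)), function(i) {
    any(vapply(segments, function(s)
      s == t$seq[i] || seqs_equivalent(s, t$seq[i], 0.95, 0.95), logical(1)))
  }, logical(1))
  list(recovery = mean(hit), n_truth = nrow(t), hit = hit)
}

#' Simulate the genotyping study
#'
#' One 300 kb chromosome at 25\% repeat density, 40 insertions of 50 bp--2
#' kb, and a 98-sample cohort (Gir 20, Kankrej 19, Tharparkar 20, Sahiwal
#' 20, Red Sindhi 19). Reads are not materialized here; use
#' [cohort_sample_reads()] per sample.
#'
#' @param seed study seed.
#' @param breed_offset breed-structure allele-frequency offset (default 0).
#' @param n_insertions number of insertions (default 40).
#' @return list with `reference`, `library`, `insertions`, `cohort`,
#'   `template` (carrier template + NUI intervals), `seed`.
#' @export
simulate_genotyping_study <- function(seed = 1L, breed_offset = 0,
                                      n_insertions = 40L) {
  lib <- make_repeat_library(2L, seed = dseed(seed, 11))
  ref <- make_reference(n_chrom = 1L, chrom_len = 3e5, repeat_library = lib,
                        repeat_density = 0.25, seed = dseed(seed, 12))
  ins <- make_insertions(ref, lib, n = n_insertions,
                         size_mix = default_size_mix(2000),
                         seed = dseed(seed, 13))
  co <- make_cohort(ins, seed = dseed(seed, 14), breed_offset = breed_offset)
  nuis <- data.frame(id = ins$id, chrom = ins$chrom, pos = ins$pos,
                     seq = ins$seq, stringsAsFactors = FALSE)
  tmpl <- build_carrier_template(ref, nuis)
  list(reference = ref, library = lib, insertions = ins, cohort = co,
       template = tmpl, seed = seed)
}

#' Reads for one cohort sample
#'
#' @param study list from [simulate_genotyping_study()].
#' @param si sample index.
#' @param coverage read depth (default 30).
#' @return character vector of pooled mate sequences.
#' @export
cohort_sample_reads <- function(study, si, coverage = 30) {
  haps <- build_pseudohaplotypes(study$reference, study$insertions,
                                 study$cohort$genotypes[si, ],
                                 study$cohort$het_hap[si, ],
                                 sample = study$cohort$samples$sample[si])
  rd <- simulate_reads(haps, coverage = coverage, err_rate = 0.001,
                       seed = dseed(study$seed, 1000 + si))
  c(rd$r1, rd$r2)
}

#' Genotype the whole cohort against the carrier template
#'
#' @param study list from [simulate_genotyping_study()].
#' @param params [pipeline_params()].
#' @param coverage read depth per sample (default 30).
#' @param verbose print progress.
#' @return list from [build_matrix()] over all samples.
#' @export
genotype_cohort <- function(study, params = pipeline_params(),
                            coverage = 30, verbose = FALSE) {
  tmpl <- study$template
  tidx <- build_index(tmpl$template, k = params$index_k)
  calls <- vector("list", nrow(study$cohort$samples))
  for (si in seq_len(nrow(study$cohort$samples))) {
    nm <- study$cohort$samples$sample[si]
    if (verbose && si %% 10 == 1) message("genotyping ", nm)
    reads <- cohort_sample_reads(study, si, coverage)
    calls[[si]] <- genotype_sample(reads, tidx, tmpl$template,
                                   tmpl$intervals, sample = nm,
                                   params = params)
  }
  build_matrix(do.call(rbind, calls),
               breed_of = stats::setNames(study$cohort$samples$breed,
                                          study$cohort$samples$sample))
}
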