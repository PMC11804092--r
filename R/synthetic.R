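# Truth-annotated synthetic cohort generator: repeat library, reference with
# interspersed repeats, insertion set, diploid cohort genotypes,
# pseudohaplotype assemblies and paired short reads. Every generator is a
# pure function of (parameters, seed); RNG state is restored afterwards.

CLASS_LEN <- list(LINE = c(2000L, 6000L), SINE = c(150L, 350L),
                  LTR = c(300L, 1500L), DNA = c(200L, 1200L))

random_seq <- function(n) {
  if (n <= 0) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

# substitution-only divergence; positions chosen without replacement
mutate_seq <- function(seq, div) {
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, div)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  r <- charToRaw(seq)
  bases <- charToRaw("ACGT")
  for (p in pos) {
    cur <- r[p]
    alt <- bases[bases != cur]
    r[p] <- alt[sample.int(length(alt), 1L)]
  }
  rawToChar(r)
}

#' Generate a synthetic transposable-element consensus library
#'
#' One set of random consensi per TE class (LINE, SINE, LTR, DNA) with class-
#' typical lengths (LINE 2--6 kb, SINE 150--350 bp, LTR 0.3--1.5 kb, DNA
#' 0.2--1.2 kb). Random consensi are pairwise unrelated (identity well below
#' 80\%).
#'
#' @param n_per_class consensi per class (>= 1).
#' @param seed RNG seed.
#' @return data.frame with columns name, te_class, seq.
#' @export
make_repeat_library <- function(n_per_class = 1L, seed = 1L) {
  stopifnot(n_per_class >= 1)
  with_seed(seed, {
    rows <- list()
    for (cls in names(CLASS_LEN)) {
      rng <- CLASS_LEN[[cls]]
      for (i in seq_len(n_per_class)) {
        len <- sample(seq(rng[1], rng[2]), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          name = sprintf("%s_%d", cls, i), te_class = cls,
          seq = random_seq(len), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a multi-chromosome reference with interspersed repeats
#'
#' Repeat copies (diverged 5--15\% from their consensus, random strand) are
#' planted without overlap on a uniform-random background until the requested
#' density of repeat bases is reached.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len length of each chromosome (bp).
#' @param repeat_library data.frame from [make_repeat_library()].
#' @param repeat_density target fraction of repeat bases, in `[0, 0.7]`.
#' @param seed RNG seed.
#' @return list with `genome` (named character vector) and `repeats` (truth
#'   BED data.frame: chrom, start, end, name = TE class, strand).
#' @export
make_reference <- function(n_chrom = 2L, chrom_len = 1e6, repeat_library = NULL,
                           repeat_density = 0.3, seed = 1L) {
  stopifnot(repeat_density >= 0, repeat_density <= 0.7)
  with_seed(seed, {
    genome <- character(n_chrom)
    names(genome) <- paste0("chr", seq_len(n_chrom))
    placed <- list()
    for (ci in seq_len(n_chrom)) {
      s <- random_seq(chrom_len)
      target_bp <- repeat_density * chrom_len
      got <- 0
      iv <- matrix(numeric(0), ncol = 2)
      tries <- 0
      while (got < target_bp) {
        if (tries > 20000) stop("repeat density too high to place non-overlapping copies")
        tries <- tries + 1
        ri <- sample.int(nrow(repeat_library), 1L)
        cons <- repeat_library$seq[ri]
        len <- nchar(cons)
        if (len >= chrom_len) next
        start <- sample.int(chrom_len - len, 1L) - 1L
        if (nrow(iv) && any(start < iv[, 2] & (start + len) > iv[, 1])) next
        copy <- mutate_seq(cons, stats::runif(1, 0.05, 0.15))
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") copy <- unname(revcomp(copy))
        substr(s, start + 1L, start + len) <- copy
        iv <- rbind(iv, c(start, start + len))
        placed[[length(placed) + 1L]] <- data.frame(
          chrom = names(genome)[ci], start = start, end = start + len,
          name = repeat_library$te_class[ri], strand = strand,
          stringsAsFactors = FALSE)
        got <- got + len
      }
      genome[ci] <- s
    }
    repeats <- if (length(placed)) do.call(rbind, placed) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 name = character(), strand = character(),
                 stringsAsFactors = FALSE)
    repeats <- repeats[order(repeats$chrom, repeats$start), , drop = FALSE]
    rownames(repeats) <- NULL
    list(genome = genome, repeats = repeats)
  })
}

#' Default insertion size mixture
#'
#' Log-size bins over `[50, max_len]` skewed toward small insertions, echoing
#' the observed size landscape where half of all common insertions are under
#' ~300 bp.
#'
#' @param max_len largest insertion length.
#' @return list with `breaks` and `weights` (renormalized after truncation).
#' @export
default_size_mix <- function(max_len = 50000) {
  breaks <- c(50, 100, 200, 500, 1000, 2000, 5000, 20000, 50000)
  weights <- c(0.18, 0.20, 0.22, 0.15, 0.10, 0.08, 0.05, 0.02)
  keep <- breaks[-length(breaks)] < max_len
  breaks <- c(breaks[c(keep, FALSE)], min(max_len, 50000))
  weights <- weights[keep] / sum(weights[keep])
  list(breaks = breaks, weights = weights)
}

# closed-form median of the (uniform-within-bin) size mixture
size_mix_median <- function(mix) {
  cw <- cumsum(mix$weights)
  b <- which(cw >= 0.5)[1L]
  lo <- mix$breaks[b]; hi <- mix$breaks[b + 1L]
  prev <- if (b > 1) cw[b - 1L] else 0
  lo + (0.5 - prev) / mix$weights[b] * (hi - lo)
}

#' Generate ground-truth insertions
#'
#' Insertion sequences are concatenations of unique random segments and
#' mutated repeat-consensus slices (LINE-weighted), giving a call set whose
#' bases are roughly 60\% interspersed repeat. Each insertion keeps at least
#' `min_unique` unique bases -- an insertion without 50 unique bases would
#' not qualify as an NUI by definition. Breakpoints are >= 1 kb apart and, for
#' the clean subset, >= `clean_margin` bp away from planted reference repeats.
#' Population allele frequencies are drawn from Beta(0.3, 0.3) truncated to
#' `[0.01, 0.99]`.
#'
#' @param reference list from [make_reference()].
#' @param repeat_library data.frame from [make_repeat_library()].
#' @param n number of insertions.
#' @param size_mix list from [default_size_mix()].
#' @param seed RNG seed.
#' @param repeat_target range of the per-insertion target repeat base
#'   fraction (drawn uniformly; the default centers the call set near the
#'   observed ~60\% interspersed-repeat content).
#' @param min_unique minimum unique bases per insertion.
#' @param clean_margin distance kept from planted reference repeats.
#' @return data.frame: id, chrom, pos (0-based zero-width breakpoint), seq,
#'   len, allele_freq, plus truth composition columns comp_LINE, comp_SINE,
#'   comp_LTR, comp_DNA, comp_unique (base fractions).
#' @export
make_insertions <- function(reference, repeat_library, n,
                            size_mix = default_size_mix(), seed = 1L,
                            repeat_target = c(0.45, 0.85), min_unique = 60L,
                            clean_margin = 100L) {
  if (n == 0) {
    return(data.frame(id = character(), chrom = character(), pos = integer(),
                      seq = character(), len = integer(),
                      allele_freq = numeric(), stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    genome <- reference$genome
    reps <- reference$repeats
    # breakpoint placement with 1 kb spacing, away from planted repeats
    placed <- data.frame(chrom = character(), pos = numeric())
    tries <- 0
    while (nrow(placed) < n) {
      if (tries > 50000) stop("cannot place ", n, " breakpoints 1 kb apart")
      tries <- tries + 1
      ci <- sample.int(length(genome), 1L)
      chrom <- names(genome)[ci]
      pos <- sample(seq(1000L, nchar(genome[ci]) - 1000L), 1L)
      same <- placed$pos[placed$chrom == chrom]
      if (length(same) && min(abs(same - pos)) < 1000) next
      r <- reps[reps$chrom == chrom, , drop = FALSE]
      if (nrow(r) && any(pos > r$start - clean_margin &
                         pos < r$end + clean_margin)) next
      placed <- rbind(placed, data.frame(chrom = chrom, pos = pos))
    }
    placed <- placed[order(placed$chrom, placed$pos), , drop = FALSE]
    # sizes from the mixture
    bins <- sample.int(length(size_mix$weights), n, replace = TRUE,
                       prob = size_mix$weights)
    lens <- vapply(bins, function(b) {
      lo <- size_mix$breaks[b]; hi <- size_mix$breaks[b + 1L]
      sample(seq(lo, hi - 1L), 1L)
    }, integer(1))
    cls_w <- c(LINE = 0.55, SINE = 0.20, LTR = 0.15, DNA = 0.10)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      len <- lens[i]
      segs <- character(0)
      comp <- c(LINE = 0, SINE = 0, LTR = 0, DNA = 0, unique = 0)
      u0 <- min(len, max(min_unique, 0L))
      segs <- random_seq(u0)
      comp["unique"] <- u0
      left <- len - u0
      # fill toward a per-insertion target repeat fraction
      tr <- stats::runif(1, repeat_target[1], repeat_target[2])
      while (left > 0) {
        rep_bp <- sum(comp[c("LINE", "SINE", "LTR", "DNA")])
        want_repeat <- rep_bp < tr * len && left >= 30L
        if (want_repeat) {
          cls <- sample(names(cls_w), 1L, prob = cls_w)
          cand <- repeat_library[repeat_library$te_class == cls, , drop = FALSE]
          cons <- cand$seq[sample.int(nrow(cand), 1L)]
          take <- min(left, nchar(cons), sample(seq(80L, 1200L), 1L),
                      max(30L, ceiling(tr * len - rep_bp)))
          if (take < 30L) {
            segs <- c(segs, random_seq(take))
            comp["unique"] <- comp["unique"] + take
          } else {
            start <- sample.int(nchar(cons) - take + 1L, 1L)
            piece <- mutate_seq(substr(cons, start, start + take - 1L),
                                stats::runif(1, 0.02, 0.10))
            if (stats::runif(1) < 0.5) piece <- unname(revcomp(piece))
            segs <- c(segs, piece)
            comp[cls] <- comp[cls] + take
          }
        } else {
          take <- min(left, sample(seq(60L, 300L), 1L))
          segs <- c(segs, random_seq(take))
          comp["unique"] <- comp["unique"] + take
        }
        left <- len - sum(comp)
      }
      seq <- paste(segs, collapse = "")
      rows[[i]] <- data.frame(
        id = sprintf("INS_%03d", i), chrom = placed$chrom[i],
        pos = as.integer(placed$pos[i]), seq = seq, len = nchar(seq),
        allele_freq = NA_real_, comp_LINE = comp[["LINE"]] / len,
        comp_SINE = comp[["SINE"]] / len, comp_LTR = comp[["LTR"]] / len,
        comp_DNA = comp[["DNA"]] / len, comp_unique = comp[["unique"]] / len,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    f <- stats::rbeta(n, 0.3, 0.3)
    out$allele_freq <- pmin(pmax(f, 0.01), 0.99)
    rownames(out) <- NULL
    out
  })
}

#' Draw a diploid cohort with breed structure
#'
#' Per-sample diploid genotypes (0/1/2 insertion copies) are drawn binomially
#' from each insertion's allele frequency. With `breed_offset > 0` each
#' insertion's frequency is raised by `offset/2` in a random half of the
#' breeds and lowered in the rest, creating breed structure. For heterozygous
#' genotypes the carrying haplotype (1 or 2) is drawn and recorded.
#'
#' @param insertions data.frame from [make_insertions()].
#' @param breeds breed labels.
#' @param n_per_breed samples per breed (recycled across breeds).
#' @param seed RNG seed.
#' @param breed_offset allele-frequency offset creating breed structure.
#' @return list with `samples` (sample, breed), `genotypes`
#'   (samples x insertions integer matrix), `het_hap` (same shape; 1/2 for
#'   heterozygotes, NA otherwise), and `freqs` (breeds x insertions).
#' @export
make_cohort <- function(insertions, breeds = c("Gir", "Kankrej", "Tharparkar",
                                               "Sahiwal", "RedSindhi"),
                        n_per_breed = c(20L, 19L, 20L, 20L, 19L), seed = 1L,
                        breed_offset = 0) {
  n_per_breed <- rep_len(n_per_breed, length(breeds))
  with_seed(seed, {
    samples <- data.frame(
      sample = unlist(lapply(seq_along(breeds), function(b)
        sprintf("%s_%02d", breeds[b], seq_len(n_per_breed[b])))),
      breed = rep(breeds, n_per_breed), stringsAsFactors = FALSE)
    ni <- nrow(insertions)
    freqs <- matrix(rep(insertions$allele_freq, each = length(breeds)),
                    nrow = length(breeds),
                    dimnames = list(breeds, insertions$id))
    if (breed_offset > 0) {
      up <- matrix(stats::runif(length(breeds) * ni) < 0.5, nrow = length(breeds))
      freqs <- freqs + ifelse(up, breed_offset / 2, -breed_offset / 2)
      freqs <- pmin(pmax(freqs, 0.02), 0.98)
    }
    G <- matrix(0L, nrow = nrow(samples), ncol = ni,
                dimnames = list(samples$sample, insertions$id))
    H <- matrix(NA_integer_, nrow = nrow(samples), ncol = ni,
                dimnames = dimnames(G))
    for (si in seq_len(nrow(samples))) {
      f <- freqs[samples$breed[si], ]
      G[si, ] <- stats::rbinom(ni, 2L, f)
      het <- which(G[si, ] == 1L)
      if (length(het)) H[si, het] <- sample(c(1L, 2L), length(het), replace = TRUE)
    }
    list(samples = samples, genotypes = G, het_hap = H, freqs = freqs)
  })
}

# splice insertions into one chromosome; returns new sequence plus the
# half-open interval of every spliced insertion in new coordinates
splice_insertions <- function(chrom_seq, pos, seqs) {
  o <- order(pos)
  pos <- pos[o]; seqs <- seqs[o]
  pieces <- character(0)
  iv <- matrix(0L, nrow = length(pos), ncol = 2)
  prev <- 0L
  off <- 0L
  for (i in seq_along(pos)) {
    pieces <- c(pieces, substr(chrom_seq, prev + 1L, pos[i]))
    iv[i, 1] <- pos[i] + off
    iv[i, 2] <- pos[i] + off + nchar(seqs[i])
    pieces <- c(pieces, seqs[i])
    off <- off + nchar(seqs[i])
    prev <- pos[i]
  }
  pieces <- c(pieces, substr(chrom_seq, prev + 1L, nchar(chrom_seq)))
  list(seq = paste(pieces, collapse = ""), intervals = iv, order = o)
}

#' Build the two pseudohaplotypes of one sample
#'
#' Each haplotype equals the reference with the sample's allele-bearing
#' insertions spliced at their breakpoints (heterozygous insertions go to the
#' recorded haplotype only). Optionally fragments the haplotypes into contigs
#' with a target N50.
#'
#' @param reference list from [make_reference()].
#' @param insertions data.frame from [make_insertions()].
#' @param genotype integer vector (one per insertion) of 0/1/2 copies.
#' @param het_hap integer vector; haplotype (1/2) carrying each heterozygous
#'   insertion.
#' @param sample sample name used in contig ids.
#' @param n50 optional contig N50 target; `NULL` keeps chromosome-length
#'   haplotypes.
#' @param seed RNG seed (used only when fragmenting).
#' @return list with `hap1`, `hap2` (named character vectors) and `truth`
#'   (data.frame: ins_id, hap, contig, start, end -- insertion intervals in
#'   haplotype coordinates).
#' @export
build_pseudohaplotypes <- function(reference, insertions, genotype, het_hap,
                                   sample = "S1", n50 = NULL, seed = 1L) {
  genome <- reference$genome
  haps <- list()
  truth <- list()
  for (h in 1:2) {
    carried <- which(genotype == 2L | (genotype == 1L & het_hap == h))
    hap <- character(length(genome))
    names(hap) <- sprintf("%s_h%d_%s", sample, h, names(genome))
    for (ci in seq_along(genome)) {
      chrom <- names(genome)[ci]
      idx <- carried[insertions$chrom[carried] == chrom]
      if (!length(idx)) {
        hap[ci] <- genome[ci]
        next
      }
      sp <- splice_insertions(genome[ci], insertions$pos[idx],
                              insertions$seq[idx])
      hap[ci] <- sp$seq
      truth[[length(truth) + 1L]] <- data.frame(
        ins_id = insertions$id[idx][sp$order], hap = h,
        contig = names(hap)[ci], start = sp$intervals[, 1],
        end = sp$intervals[, 2], stringsAsFactors = FALSE)
    }
    haps[[h]] <- hap
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(ins_id = character(), hap = integer(), contig = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  res <- list(hap1 = haps[[1]], hap2 = haps[[2]], truth = truth)
  if (!is.null(n50)) {
    res$hap1 <- fragment_contigs(res$hap1, n50, seed = seed)
    res$hap2 <- fragment_contigs(res$hap2, n50, seed = seed + 1L)
    res$truth <- NULL  # interval bookkeeping not maintained across fragments
  }
  res
}

#' Fragment contigs to emulate assembly contiguity
#'
#' Cuts each sequence into pieces with exponentially distributed lengths whose
#' base-weighted median approximates the requested N50.
#'
#' @param seqs named character vector.
#' @param n50 target N50 (bp).
#' @param seed RNG seed.
#' @return Named character vector of fragments.
#' @export
fragment_contigs <- function(seqs, n50, seed = 1L) {
  with_seed(seed, {
    mean_len <- n50 / 1.6783            # bp-weighted median of Exp is ~1.678 mean
    out <- character(0)
    for (i in seq_along(seqs)) {
      L <- nchar(seqs[i])
      cuts <- 0
      while (sum(cuts) < L) {
        cuts <- c(cuts, max(1000, round(stats::rexp(1, 1 / mean_len))))
      }
      ends <- pmin(cumsum(cuts[-1]), L)
      starts <- c(0, ends[-length(ends)]) + 1L
      keep <- starts <= L
      frags <- substring(seqs[i], starts[keep], ends[keep])
      names(frags) <- sprintf("%s_f%d", names(seqs)[i], seq_along(frags))
      out <- c(out, frags)
    }
    out
  })
}

#' Contig N50
#'
#' @param lengths contig lengths (or a named character vector of sequences).
#' @return The N50 value.
#' @export
compute_n50 <- function(lengths) {
  if (is.character(lengths)) lengths <- nchar(lengths)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Simulate paired-end reads from a diploid sample
#'
#' Fragments are placed uniformly over both haplotypes (half the requested
#' depth each, so mapped depth on shared sequence is `coverage`); per-base
#' substitution errors are injected at `err_rate`. Deterministic given the
#' seed.
#'
#' @param haps list with `hap1` and `hap2` named character vectors.
#' @param coverage requested mean depth over the haploid genome.
#' @param read_len read length.
#' @param frag_mean,frag_sd fragment-size distribution (must exceed two read
#'   lengths).
#' @param err_rate per-base substitution error rate.
#' @param seed RNG seed.
#' @return list with `r1`, `r2` (character vectors) and `n_pairs`.
#' @export
simulate_reads <- function(haps, coverage, read_len = 100L, frag_mean = 350,
                           frag_sd = 35, err_rate = 0.001, seed = 1L) {
  if (coverage <= 0) stop("coverage must be positive")
  if (frag_mean <= 2 * read_len) stop("frag_mean must exceed 2 * read_len")
  with_seed(seed, {
    contigs <- c(haps$hap1, haps$hap2)
    clen <- nchar(contigs)
    haploid <- sum(clen) / 2
    n_pairs <- max(1L, round(coverage * haploid / (2 * read_len)))
    ci <- sample.int(length(contigs), n_pairs, replace = TRUE,
                     prob = clen / sum(clen))
    fl <- pmax(2L * read_len, round(stats::rnorm(n_pairs, frag_mean, frag_sd)))
    fl <- pmin(fl, clen[ci])
    start <- floor(stats::runif(n_pairs) * (clen[ci] - fl + 1)) + 1L
    r1 <- substring(contigs[ci], start, start + read_len - 1L)
    r2 <- unname(revcomp(substring(contigs[ci], start + fl - read_len,
                                   start + fl - 1L)))
    flip <- stats::runif(n_pairs) < 0.5
    tmp <- r1[flip]; r1[flip] <- r2[flip]; r2[flip] <- tmp
    if (err_rate > 0) {
      for (nm in c("r1", "r2")) {
        v <- get(nm)
        B <- n_pairs * read_len
        n_err <- stats::rbinom(1L, B, err_rate)
        if (n_err > 0) {
          slot <- sample.int(B, n_err)
          ri <- (slot - 1L) %/% read_len + 1L
          pp <- (slot - 1L) %% read_len + 1L
          bases <- c("A", "C", "G", "T")
          for (e in seq_len(n_err)) {
            if (pp[e] > nchar(v[ri[e]])) next
            cur <- substr(v[ri[e]], pp[e], pp[e])
            alt <- bases[bases != cur]
            substr(v[ri[e]], pp[e], pp[e]) <- alt[sample.int(length(alt), 1L)]
          }
        }
        assign(nm, v)
      }
    }
    list(r1 = r1, r2 = r2, n_pairs = n_pairs)
  })
}

#' Write paired reads as FASTQ
#'
#' @param reads list from [simulate_reads()].
#' @param prefix output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @export
write_fastq <- function(reads, prefix) {
  for (m in 1:2) {
    v <- reads[[paste0("r", m)]]
    con <- file(sprintf("%s_%d.fastq", prefix, m), "w")
    writeLines(paste0("@read", seq_along(v), "/", m, "\n", v, "\n+\n",
                      strrep("I", nchar(v))), con)
    close(con)
  }
  invisible(prefix)
}

#' Left-align an insertion breakpoint (VCF convention)
#'
#' While the inserted sequence's last base equals the reference base just
#' before the breakpoint, the representation is rotated one base left. Used
#' to normalize both truth and called insertions in tandem contexts.
#'
#' @param chrom_seq reference chromosome sequence.
#' @param pos 0-based zero-width breakpoint.
#' @param seq inserted sequence.
#' @return list with normalized `pos` and `seq`.
#' @export
left_align_insertion <- function(chrom_seq, pos, seq) {
  while (pos > 0 &&
         substr(seq, nchar(seq), nchar(seq)) == substr(chrom_seq, pos, pos)) {
    seq <- paste0(substr(chrom_seq, pos, pos), substr(seq, 1L, nchar(seq) - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, seq = seq)
}
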