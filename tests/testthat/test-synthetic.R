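# The synthetic cohort generator: repeat library, reference, insertions,
# genotypes, pseudohaplotypes, reads.

test_that("repeat library respects class counts, length ranges, determinism", {
  lib <- make_repeat_library(1L, seed = 7)
  expect_equal(nrow(lib), 4L)
  expect_setequal(lib$te_class, c("LINE", "SINE", "LTR", "DNA"))
  rng <- list(LINE = c(2000, 6000), SINE = c(150, 350),
              LTR = c(300, 1500), DNA = c(200, 1200))
  for (i in seq_len(nrow(lib))) {
    r <- rng[[lib$te_class[i]]]
    expect_gte(nchar(lib$seq[i]), r[1])
    expect_lte(nchar(lib$seq[i]), r[2])
  }
  expect_identical(lib, make_repeat_library(1L, seed = 7))
  expect_false(identical(lib$seq, make_repeat_library(1L, seed = 8)$seq))
})

test_that("library consensi are pairwise unrelated below 80% identity", {
  lib <- make_repeat_library(1L, seed = 7)
  for (i in 1:(nrow(lib) - 1)) {
    for (j in (i + 1):nrow(lib)) {
      a <- Biostrings::pairwiseAlignment(lib$seq[i], lib$seq[j],
                                         type = "local",
                                         substitutionMatrix = nw_submat,
                                         gapOpening = 5, gapExtension = 1)
      # any local alignment of unrelated sequence is short and weak: the
      # longer consensus could never be 80% covered at 80% identity
      expect_lt(Biostrings::nchar(a) / max(nchar(lib$seq[i]), nchar(lib$seq[j])),
                0.5)
    }
  }
})

test_that("reference hits the requested repeat density and is deterministic", {
  lib <- make_repeat_library(1L, seed = 7)
  ref0 <- make_reference(1L, 5e4, lib, repeat_density = 0, seed = 9)
  expect_equal(nrow(ref0$repeats), 0L)
  ref <- make_reference(2L, 2e5, lib, repeat_density = 0.3, seed = 9)
  planted <- sum(ref$repeats$end - ref$repeats$start)
  expect_lt(abs(planted / (2 * 2e5) - 0.3), 0.05)
  expect_identical(ref$genome,
                   make_reference(2L, 2e5, lib, 0.3, seed = 9)$genome)
  expect_true(all(nchar(ref$genome) == 2e5))
})

test_that("insertions respect the size mixture, floor and clean margins", {
  lib <- make_repeat_library(1L, seed = 7)
  ref <- make_reference(1L, 5e5, lib, 0.2, seed = 9)
  expect_equal(nrow(make_insertions(ref, lib, 0)), 0L)
  ins <- make_insertions(ref, lib, 200L, seed = 10)
  expect_true(all(ins$len >= 50))
  mix <- default_size_mix()
  expect_lt(abs(stats::median(ins$len) - size_mix_median(mix)), 300)
  # breakpoints >= 1 kb apart, >= 100 bp from planted repeats
  for (ch in unique(ins$chrom)) {
    p <- sort(ins$pos[ins$chrom == ch])
    if (length(p) > 1) expect_true(all(diff(p) >= 1000))
    r <- ref$repeats[ref$repeats$chrom == ch, ]
    for (pos in p)
      expect_false(any(pos > r$start - 100 & pos < r$end + 100))
  }
  # composition truth sums to 1 and keeps >= 50 unique bases
  comp <- ins$comp_LINE + ins$comp_SINE + ins$comp_LTR + ins$comp_DNA +
    ins$comp_unique
  expect_equal(comp, rep(1, nrow(ins)), tolerance = 1e-9)
  expect_true(all(round(ins$comp_unique * ins$len) >= 50))
})

test_that("cohort genotypes follow their target frequencies", {
  lib <- make_repeat_library(1L, seed = 7)
  ref <- make_reference(1L, 2e5, lib, 0.1, seed = 9)
  ins <- make_insertions(ref, lib, 30L, default_size_mix(500), seed = 10)
  # degenerate frequency 1 -> genotype 2 everywhere
  ins$allele_freq <- 1.0
  co <- make_cohort(ins, seed = 11)
  expect_true(all(co$genotypes == 2L))
  # binomial property: realized allele frequency within 3 SE of target
  ins$allele_freq <- runif(nrow(ins), 0.1, 0.9)
  co <- make_cohort(ins, seed = 12)
  n2 <- 2 * nrow(co$samples)
  f_hat <- colSums(co$genotypes) / n2
  se <- sqrt(ins$allele_freq * (1 - ins$allele_freq) / n2)
  expect_gte(mean(abs(f_hat - ins$allele_freq) <= 3 * se), 0.95)
  expect_identical(co$genotypes, make_cohort(ins, seed = 12)$genotypes)
  # heterozygotes carry exactly one recorded haplotype
  het <- co$genotypes == 1L
  expect_true(all(co$het_hap[het] %in% 1:2))
  expect_true(all(is.na(co$het_hap[!het])))
})

test_that("pseudohaplotypes splice the right alleles with exact bookkeeping", {
  lib <- make_repeat_library(1L, seed = 7)
  ref <- make_reference(1L, 1e5, lib, 0.1, seed = 9)
  ins <- make_insertions(ref, lib, 5L, default_size_mix(1000), seed = 10)
  # genotype 0 everywhere: haplotypes equal the reference
  h0 <- build_pseudohaplotypes(ref, ins, rep(0L, 5), rep(NA_integer_, 5))
  expect_equal(unname(h0$hap1), unname(ref$genome))
  expect_equal(unname(h0$hap2), unname(ref$genome))
  # single homozygous insertion: both haplotypes longer by exactly its length
  g <- c(2L, 0L, 0L, 0L, 0L)
  h2 <- build_pseudohaplotypes(ref, ins, g, rep(NA_integer_, 5))
  expect_equal(nchar(h2$hap1[[1]]), nchar(ref$genome[[1]]) + ins$len[1])
  expect_equal(nchar(h2$hap2[[1]]), nchar(ref$genome[[1]]) + ins$len[1])
  # the recorded interval extracts the inserted sequence verbatim
  tr <- h2$truth[h2$truth$hap == 1, ]
  expect_equal(substr(h2$hap1[[1]], tr$start + 1, tr$end), ins$seq[1])
  # heterozygous insertion lands on the recorded haplotype only
  g1 <- c(1L, 0L, 0L, 0L, 0L)
  h1 <- build_pseudohaplotypes(ref, ins, g1, c(2L, NA, NA, NA, NA))
  expect_equal(nchar(h1$hap1[[1]]), nchar(ref$genome[[1]]))
  expect_equal(nchar(h1$hap2[[1]]), nchar(ref$genome[[1]]) + ins$len[1])
})

test_that("contig fragmentation approximates the requested N50", {
  set.seed(61)
  seqs <- c(c1 = rand_seq(3e5), c2 = rand_seq(3e5))
  frags <- fragment_contigs(seqs, n50 = 30000, seed = 13)
  expect_equal(sum(nchar(frags)), sum(nchar(seqs)))
  expect_lt(abs(compute_n50(frags) - 30000) / 30000, 0.2)
})

test_that("read simulation hits depth, is deterministic, and errors are real", {
  lib <- make_repeat_library(1L, seed = 7)
  ref <- make_reference(2L, 1e5, lib, 0.1, seed = 9)
  haps <- list(hap1 = ref$genome, hap2 = ref$genome)
  rd <- simulate_reads(haps, coverage = 30, seed = 14)
  emitted <- sum(nchar(rd$r1)) + sum(nchar(rd$r2))
  expect_gte(emitted, 0.9 * 30 * 2e5)
  expect_lte(emitted, 1.1 * 30 * 2e5)
  rd2 <- simulate_reads(haps, coverage = 30, seed = 14)
  expect_identical(rd, rd2)
  expect_error(simulate_reads(haps, coverage = 0), "positive")
  expect_error(simulate_reads(haps, coverage = 10, read_len = 100,
                              frag_mean = 150), "exceed")
  # error-free reads map back at full identity
  rd0 <- simulate_reads(haps, coverage = 2, err_rate = 0, seed = 15)
  idx <- build_index(ref$genome, k = 15)
  m <- map_reads(rd0$r1[1:200], idx)
  expect_true(all(m$mapped))
  expect_true(all(m$score == 100))
})

test_that("FASTQ output is byte-identical across runs of the same seed", {
  lib <- make_repeat_library(1L, seed = 7)
  ref <- make_reference(1L, 2e4, lib, 0, seed = 9)
  haps <- list(hap1 = ref$genome, hap2 = ref$genome)
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  write_fastq(simulate_reads(haps, 5, seed = 16), p1)
  write_fastq(simulate_reads(haps, 5, seed = 16), p2)
  expect_identical(readLines(paste0(p1, "_1.fastq")),
                   readLines(paste0(p2, "_1.fastq")))
  expect_identical(readLines(paste0(p1, "_2.fastq")),
                   readLines(paste0(p2, "_2.fastq")))
})
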