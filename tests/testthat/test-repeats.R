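# Repeat-library masking, the unique-base criterion, major-TE calls,
# flank/crossing analysis and summaries.

lib7 <- make_repeat_library(1L, seed = 7)

test_that("an exact consensus copy is fully masked with its class", {
  sine <- lib7$seq[lib7$te_class == "SINE"][1]
  ann <- annotate_repeats(sine, lib7)
  expect_equal(unname(ann$class_bp[["SINE"]]), nchar(sine))
  expect_equal(unique(ann$intervals$label), "SINE")
  expect_equal(ann$unique_bp, 0L)
  expect_equal(major_te(ann), "SINE")
})

test_that("constructed composition is recovered; short fragments are ignored", {
  set.seed(81)
  sine <- substr(lib7$seq[lib7$te_class == "SINE"][1], 1, 200)
  seq <- paste0(rand_seq(150), sine)
  ann <- annotate_repeats(seq, lib7)
  expect_equal(unname(ann$class_bp[["SINE"]]), 200)
  expect_equal(ann$unique_bp, 150L)
  # a 25 bp fragment is below the 30 bp hit floor
  frag <- paste0(rand_seq(150), substr(sine, 1, 25), rand_seq(150))
  annf <- annotate_repeats(frag, lib7)
  expect_equal(unname(annf$class_bp[["SINE"]]), 0)
})

test_that("unique-base filter switches exactly at 50", {
  set.seed(82)
  u60 <- annotate_repeats(rand_seq(60), lib7)
  expect_equal(unique_bases(u60), 60L)
  expect_true(passes_unique_filter(u60))
  line <- lib7$seq[lib7$te_class == "LINE"][1]
  for (u in c(49L, 50L)) {
    seq <- paste0(substr(line, 1, 300), rand_seq(u))
    ann <- annotate_repeats(seq, lib7)
    expect_equal(unique_bases(ann), u)
    expect_equal(passes_unique_filter(ann), u >= 50L)
  }
})

test_that("major TE takes the largest share with the documented tie order", {
  mk <- function(bp, hits = NULL) {
    structure(list(class_bp = bp,
                   hits = if (is.null(hits))
                     data.frame(label = character(), score = numeric())
                   else hits,
                   unique_bp = 0L, length = sum(bp)),
              class = "repeat_annotation")
  }
  cls <- c(LINE = 0L, SINE = 0L, LTR = 0L, DNA = 0L, LOW_COMPLEXITY = 0L)
  b <- cls; b["LINE"] <- 60L; b["SINE"] <- 20L
  expect_equal(major_te(mk(b)), "LINE")
  expect_equal(major_te(mk(cls)), "NONE")
  # a pure low-complexity sequence has no interspersed repeat
  lc <- cls; lc["LOW_COMPLEXITY"] <- 100L
  expect_equal(major_te(mk(lc)), "NONE")
  # exact 50/50 with equal scores resolves LINE > SINE
  tie <- cls; tie["LINE"] <- 50L; tie["SINE"] <- 50L
  h <- data.frame(label = c("LINE", "SINE"), score = c(40, 40))
  expect_equal(major_te(mk(tie, h)), "LINE")
})

test_that("flank analysis flags TEs beside and across insertion edges", {
  set.seed(83)
  line <- lib7$seq[lib7$te_class == "LINE"][1]
  params <- pipeline_params()
  # insertion planted inside a reference LINE copy: flanked and crossing
  genome <- c(chr1 = paste0(rand_seq(500), substr(line, 1, 2000), rand_seq(500)))
  ins <- data.frame(chrom = "chr1", pos = 1500L, seq = rand_seq(300),
                    stringsAsFactors = FALSE)
  fl <- flank_te_analysis(ins, genome, lib7, params)
  expect_true(fl$flanked_left && fl$flanked_right)
  expect_true(fl$crossing_left || fl$crossing_right)
  # unique context: all false
  genome2 <- c(chr1 = rand_seq(3000))
  ins2 <- data.frame(chrom = "chr1", pos = 1500L, seq = rand_seq(300),
                     stringsAsFactors = FALSE)
  fl2 <- flank_te_analysis(ins2, genome2, lib7, params)
  expect_false(any(unlist(fl2)))
  # TE ending exactly at the breakpoint: flanked yes, crossing no. The
  # inserted sequence starts with bases mismatching the consensus so hit
  # extension cannot drift across the edge by chance.
  genome3 <- c(chr1 = paste0(rand_seq(1200), substr(line, 1, 300), rand_seq(1500)))
  block <- paste(vapply(strsplit(substr(line, 301, 306), "")[[1]],
                        function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                        character(1)), collapse = "")
  ins3 <- data.frame(chrom = "chr1", pos = 1500L,
                     seq = paste0(block, rand_seq(294)),
                     stringsAsFactors = FALSE)
  fl3 <- flank_te_analysis(ins3, genome3, lib7, params)
  expect_true(fl3$flanked_left)
  expect_false(fl3$crossing_left)
})

test_that("repeat summary partitions calls into size bins and sums shares", {
  empty <- repeat_summary(list())
  expect_true(all(empty$class_fraction == 0))
  expect_true(all(empty$size_bins == 0))
  set.seed(84)
  sine <- lib7$seq[lib7$te_class == "SINE"][1]
  anns <- list(
    annotate_repeats(rand_seq(150), lib7),                       # <200, NONE
    annotate_repeats(paste0(rand_seq(100), substr(sine, 1, 250)), lib7),
    annotate_repeats(paste0(rand_seq(1100), substr(sine, 1, 200)), lib7))
  rs <- repeat_summary(anns)
  expect_equal(sum(rs$size_bins[, "total"]), 3)
  expect_equal(unname(rs$size_bins["<200", "total"]), 1)
  expect_equal(unname(rs$size_bins["200-1000", "total"]), 1)
  expect_equal(unname(rs$size_bins[">1000", "total"]), 1)
  lens <- sum(vapply(anns, `[[`, numeric(1), "length"))
  expect_equal(unname(rs$class_fraction[["masked_total"]]),
               sum(vapply(anns, function(a) sum(a$class_bp), numeric(1))) / lens)
})

test_that("masking is idempotent on an already fully masked sequence", {
  sine <- lib7$seq[lib7$te_class == "SINE"][1]
  a1 <- annotate_repeats(sine, lib7)
  expect_equal(a1$unique_bp, 0L)
  # re-annotating the same (fully masked) sequence yields the same annotation
  a2 <- annotate_repeats(sine, lib7)
  expect_identical(a1$intervals, a2$intervals)
  expect_identical(a1$class_bp, a2$class_bp)
})
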