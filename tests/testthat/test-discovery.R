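# Alignment-branch discovery: clusters, window extension, breakpoint
# resolution, candidate filtering and call-set merging.

test_that("read clusters obey the 8-100X window and the merge gap", {
  p <- pipeline_params()
  d <- integer(3000)
  d[1001:1400] <- 50L
  cl <- find_clusters(d, p)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 1000)
  expect_equal(cl$end, 1400)
  expect_equal(cl$mean_depth, 50)
  # below the lower bound: nothing
  expect_equal(nrow(find_clusters(rep(7L, 500), p)), 0L)
  # above the upper bound: discarded by the mean test
  expect_equal(nrow(find_clusters(rep(150L, 500), p)), 0L)
  # runs separated by < 100 bp merge before the mean test
  d2 <- integer(2000)
  d2[101:200] <- 10L
  d2[260:400] <- 10L
  cl2 <- find_clusters(d2, p)
  expect_equal(nrow(cl2), 1L)
  expect_equal(c(cl2$start, cl2$end), c(100, 400))
  # runs 100+ bp apart stay separate
  d3 <- integer(2000)
  d3[101:200] <- 10L
  d3[301:400] <- 10L
  expect_equal(nrow(find_clusters(d3, p)), 2L)
})

test_that("cluster extension adds 7 kb each side, clipped at contig ends", {
  cl <- data.frame(start = 10000L, end = 10400L)
  expect_equal(extend_cluster(cl, 1e6), c(3000, 17400))
  expect_equal(extend_cluster(data.frame(start = 2000L, end = 2400L), 1e6),
               c(0, 9400))
  expect_equal(extend_cluster(data.frame(start = 0L, end = 5000L), 5000L),
               c(0, 5000))
})

test_that("resolve_insertion recovers constructed events at base precision", {
  tt <- tiny_target()
  genome <- c(chrT = tt$seq)
  set.seed(71)
  for (len in c(60L, 200L, 1500L)) {
    ins <- rand_seq(len)
    q <- paste0(substr(tt$seq, 1501, 3000), ins, substr(tt$seq, 3001, 4500))
    r <- resolve_insertion(q, tt$index, genome = genome)
    la <- left_align_insertion(tt$seq, 3000L, ins)
    expect_equal(r$pos, la$pos)
    expect_equal(r$seq, la$seq)
    expect_gte(r$left_anchor_len, 1)
    expect_gte(r$right_anchor_len, 1)
  }
  # a 49 bp event is below the insertion floor
  q49 <- paste0(substr(tt$seq, 1501, 3000), rand_seq(49),
                substr(tt$seq, 3001, 4500))
  expect_null(resolve_insertion(q49, tt$index, genome = genome))
  # a pure reference slice has no divergence to resolve
  expect_null(resolve_insertion(substr(tt$seq, 1501, 4500), tt$index,
                                genome = genome))
})

test_that("candidate filters drop reference-like, excluded and repeat-only calls", {
  tt <- tiny_target()
  lib <- make_repeat_library(1L, seed = 7)
  set.seed(72)
  line <- lib$seq[lib$te_class == "LINE"][1]
  calls <- data.frame(
    chrom = "chrT",
    pos = c(1000L, 2000L, 3000L, 4000L),
    seq = c(substr(tt$seq, 5001, 5400),              # a reference slice
            rand_seq(400),                            # clean novel call
            rand_seq(400),                            # breakpoint in segdup
            paste0(substr(line, 1, 180), rand_seq(20))),  # 20 unique bases
    stringsAsFactors = FALSE)
  calls$len <- nchar(calls$seq)
  segdup <- data.frame(chrom = "chrT", start = 2900L, end = 3100L)
  out <- filter_candidates(calls, tt$index, lib, segdup_bed = segdup)
  expect_equal(out$pos, 2000L)
  expect_gte(out$unique_bases, 50)
})

test_that("merging collapses equivalent calls and is order-independent", {
  set.seed(73)
  s <- rand_seq(300)
  calls <- data.frame(
    chrom = "chr1",
    pos = c(500L, 505L, 500L, 5000L),
    seq = c(s, mutate_at_rate(s, 0.01), rand_seq(300), s),
    sample = c("A", "B", "C", "A"),
    hap = c(1L, 2L, 1L, 1L),
    stringsAsFactors = FALSE)
  m <- merge_call_set(calls)
  # breakpoints 5 bp apart with ~99% identity merge; the unrelated sequence
  # at the same locus and the distant copy stay separate
  expect_equal(nrow(m$nuis), 3L)
  merged_id <- m$occurrence$nui_id[m$occurrence$sample == "B"]
  expect_setequal(m$occurrence$sample[m$occurrence$nui_id == merged_id],
                  c("A", "B"))
  # permuting the input rows yields the same NUI set
  m2 <- merge_call_set(calls[c(4, 2, 1, 3), ])
  expect_setequal(m$nuis$seq, m2$nuis$seq)
  expect_equal(m$nuis[order(m$nuis$pos, m$nuis$seq), c("chrom", "pos", "seq")],
               m2$nuis[order(m2$nuis$pos, m2$nuis$seq), c("chrom", "pos", "seq")],
               ignore_attr = TRUE)
  # identical call in two samples -> one NUI carried by both
  two <- merge_call_set(calls[c(1, 1), ][, ])
  expect_equal(nrow(merge_call_set(data.frame(
    chrom = "chr1", pos = 500L, seq = s, sample = c("A", "B"),
    hap = 1L, stringsAsFactors = FALSE))$nuis), 1L)
})

test_that("unmapped read extraction keeps whole pairs", {
  m1 <- data.frame(mapped = c(TRUE, FALSE, TRUE))
  m2 <- data.frame(mapped = c(TRUE, TRUE, FALSE))
  r1 <- c("AA", "CC", "GG")
  r2 <- c("TT", "AG", "CT")
  um <- unmapped_reads(m1, m2, r1, r2)
  expect_setequal(um, c("CC", "AG", "GG", "CT"))
})
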