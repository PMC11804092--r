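# Genic classification, nearest genes, cross-species sharing, reporting.

toy_models <- list(
  genes = data.frame(
    gene_id = c("g1", "g2", "g3"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 5000L, 2000L), end = c(3000L, 8000L, 4000L),
    strand = "+", biotype = c("protein_coding", "lncRNA", "protein_coding"),
    stringsAsFactors = FALSE),
  exons = data.frame(
    gene_id = c("g1", "g1", "g2", "g3"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1000L, 2500L, 5000L, 2000L),
    end = c(1500L, 3000L, 5600L, 2400L),
    stringsAsFactors = FALSE))

test_that("breakpoints classify as exonic, intronic or intergenic", {
  bicis <- data.frame(
    id = paste0("b", 1:5), chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(1200L, 2000L, 4000L, 2100L, 9000L), stringsAsFactors = FALSE)
  cl <- classify_breakpoints(bicis, toy_models)
  expect_equal(cl$per_bici$category,
               c("exonic", "intronic", "intergenic", "exonic", "intergenic"))
  # partition: exonic + intronic + intergenic == total
  cc <- cl$category_counts
  expect_equal(unname(cc["exonic"] + cc["intronic"] + cc["intergenic"]),
               nrow(bicis))
  expect_equal(unname(cc["genic"]), unname(cc["exonic"] + cc["intronic"]))
  expect_equal(cl$biotype_tally[["protein_coding"]], 2L)
  # b1 and b2 both fall in g1, so g1 is already on the multi-hit list
  expect_equal(cl$genes_multi, "g1")
  expect_equal(cl$gene_hits$n_bicis[cl$gene_hits$gene_id == "g1"], 2L)
  # two further breakpoints inside g2 promote it as well
  bic2 <- rbind(bicis,
                data.frame(id = c("b6", "b7"), chrom = "chr1",
                           pos = c(5200L, 6000L)))
  cl2 <- classify_breakpoints(bic2, toy_models)
  expect_setequal(cl2$genes_multi, c("g1", "g2"))
})

test_that("nearest gene search honors the 20 kb window and reports ties", {
  # 1 kb downstream of g1 (ends 3000), g2 starts at 5000
  ng <- nearest_gene("chr1", 3999L, toy_models)
  expect_equal(ng$gene_id, "g1")
  expect_equal(ng$distance, 999L)
  # exact tie between both neighbors
  tie <- nearest_gene("chr1", 4000L, toy_models)
  expect_setequal(tie$gene_id, c("g1", "g2"))
  expect_equal(unique(tie$distance), 1000L)
  # beyond the window: nothing
  expect_equal(nrow(nearest_gene("chr1", 28001L, toy_models)), 0L)
  expect_equal(nrow(nearest_gene("chr1", 28000L, toy_models)), 1L)
  # inside a gene: distance zero
  expect_equal(nearest_gene("chr1", 1500L, toy_models)$distance, 0L)
})

test_that("species presence needs 95/95 and sharing counts follow the matrix", {
  set.seed(111)
  bicis <- stats::setNames(vapply(1:5, function(i) rand_seq(300),
                                  character(1)), paste0("b", 1:5))
  mk_genome <- function(carry) {
    seq <- rand_seq(2000)
    for (s in carry) seq <- paste0(seq, s, rand_seq(500))
    c(chr = seq)
  }
  genomes <- list(sp1 = mk_genome(bicis[c(1, 2, 3)]),
                  sp2 = mk_genome(bicis[c(1, 4)]),
                  sp3 = mk_genome(character(0)))
  M <- species_presence(bicis, genomes)
  expect_equal(unname(colSums(M)), c(3L, 2L, 0L))
  expect_true(M["b1", "sp1"] && M["b1", "sp2"])
  expect_false(any(M["b5", ]))
  sm <- sharing_summary(M)
  expect_equal(sm$any_species, 4L)
  expect_equal(sm$all_species, 0L)
  expect_equal(unname(sm$unique_per_species), c(2L, 1L, 0L))
  # oracle identity: direct row-sum recomputation
  rs <- rowSums(M)
  expect_equal(sm$any_species, sum(rs >= 1))
  expect_equal(sm$all_species, sum(rs == ncol(M)))
  expect_equal(unname(sm$unique_per_species),
               unname(colSums(M[rs == 1, , drop = FALSE])))
})

test_that("percentages round half-up at the displayed precision", {
  expect_equal(percentage(467, 2312), 20.20)
  expect_equal(percentage(467, 2312, 1), 20.2)
  expect_equal(percentage(1, 8), 12.5)
  expect_equal(percentage(1, 3), 33.33)
  expect_equal(percentage(5, 1000), 0.5)
  expect_equal(percentage(25, 1000, 0), 3)   # 2.5 rounds half-up to 3
  expect_equal(percentage(0, 0), 0)
})

test_that("reports serialize deterministically with parameter headers", {
  secs <- list(counts = c(n_nuis = 5, n_bicis = 2),
               table = data.frame(id = c("a", "b"), n = c(1L, 2L)))
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".tsv")
  report(secs, json_path = jf, tsv_path = tf)
  j <- jsonlite::read_json(jf)
  expect_equal(j$sections$counts$n_nuis, 5)
  expect_equal(j$parameters$maf_min, 0.05)
  lines <- readLines(tf)
  expect_true(any(grepl("^# maf_min=0.05", lines)))
  expect_true(any(lines == "## counts"))
  # regeneration is byte-identical
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  report(secs, tsv_path = tf2)
  expect_identical(readLines(tf2), lines)
  # empty input gives an empty-sectioned report
  empty <- report(list())
  expect_equal(length(empty$sections), 0L)
})
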