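# Pangenome graph: ordering, backbone, augmentation, statistics, extraction.

test_that("assembly ordering follows constructed divergence", {
  set.seed(91)
  ref <- c(chr1 = rand_seq(60000))
  asm <- list(closest = c(c1 = mutate_at_rate(ref[[1]], 0.005)),
              middle = c(c1 = mutate_at_rate(ref[[1]], 0.02)),
              farthest = c(c1 = mutate_at_rate(ref[[1]], 0.05)),
              identical = c(c1 = ref[[1]]))
  ord <- order_assemblies(ref, asm)
  expect_equal(ord$assembly, c("identical", "closest", "middle", "farthest"))
  expect_equal(ord$distance[1], 0)
  expect_equal(order_assemblies(ref, asm["middle"])$assembly, "middle")
})

test_that("backbone has one segment per chromosome and round-trips as GFA", {
  set.seed(92)
  ref <- c(chr1 = rand_seq(5000), chr2 = rand_seq(4000))
  b <- build_backbone(ref)
  g <- realize_graph(b)
  expect_equal(nrow(g$segments), 2L)
  expect_equal(nrow(g$links), 0L)   # no inter-chromosome link
  st <- graph_stats(g, n_genomes = 1)
  expect_equal(st$bp_ref, 9000)
  expect_equal(st$bp_nonref, 0)
  expect_equal(st$pct_core, 100.00)
  f <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(g, f)
  g2 <- read_gfa(f)
  expect_identical(g2$segments$seq, g$segments$seq)
})

test_that("augmentation adds bubbles, reuses shared segments, idempotent", {
  set.seed(93)
  ref <- c(chr1 = rand_seq(40000))
  ins <- rand_seq(200)
  asm1 <- c(c1 = paste0(substr(ref[[1]], 1, 20000), ins,
                        substr(ref[[1]], 20001, 40000)))
  b <- build_backbone(ref)
  # assembly identical to the reference adds nothing
  a0 <- augment(b, "same", c(c1 = ref[[1]]))
  expect_equal(unname(a0), c(0, 0))
  # one 200 bp novel insertion: 1 node, 200 bp, two ref-nonref edges
  a1 <- augment(b, "asmA", asm1)
  expect_equal(unname(a1), c(1, 200))
  g <- realize_graph(b)
  st <- graph_stats(g, n_genomes = 3)
  expect_equal(st$n_nodes_nonref, 1L)
  expect_equal(st$bp_nonref, 200)
  expect_equal(st$edges_ref_nonref, 2L)
  # a second assembly carrying the same insertion adds nothing new but
  # joins the segment's origin set
  a2 <- augment(b, "asmB", asm1)
  expect_equal(unname(a2), c(0, 0))
  expect_setequal(b$nonref_origins[[1]], c("asmA", "asmB"))
  # augmenting the same assembly twice is idempotent
  a3 <- augment(b, "asmA", asm1)
  expect_equal(unname(a3), c(0, 0))
  expect_equal(nrow(b$nonref), 1L)
})

test_that("graph statistics satisfy the conservation identities", {
  gr <- graph_result()
  st <- gr$stats
  expect_equal(st$n_nodes, st$n_nodes_ref + st$n_nodes_nonref)
  expect_equal(st$bp_total, st$bp_ref + st$bp_nonref)
  expect_equal(st$edges_total,
               st$edges_ref_ref + st$edges_ref_nonref + st$edges_nonref_nonref)
  expect_equal(st$n_nodes, st$core_nodes + st$flexible_nodes)
  expect_equal(st$bp_total, st$core_bp + st$flexible_bp)
  expect_equal(st$flexible_nodes,
               st$flexible_shared_nodes + st$flexible_single_nodes)
  expect_equal(st$flexible_bp,
               st$flexible_shared_bp + st$flexible_single_bp)
  expect_equal(st$pct_core + st$pct_flexible, 100, tolerance = 0.011)
  # per-assembly incremental additions sum to the non-reference totals
  expect_equal(sum(gr$builder$added$nodes), st$n_nodes_nonref)
  expect_equal(sum(gr$builder$added$bp), st$bp_nonref)
})

test_that("edge classes count mixed graphs correctly", {
  g <- pangenome_graph(
    data.frame(id = c("r1", "r2", "n1", "n2"),
               seq = c(strrep("A", 60), strrep("C", 60),
                       strrep("G", 60), strrep("T", 60)),
               origins = c("reference", "reference", "X", "X,Y"),
               stringsAsFactors = FALSE),
    data.frame(from = c("r1", "r1", "n1", "n1"), from_orient = "+",
               to = c("r2", "n1", "n2", "r2"), to_orient = "+",
               stringsAsFactors = FALSE))
  st <- graph_stats(g, n_genomes = 3)
  expect_equal(st$edges_ref_ref, 1L)
  expect_equal(st$edges_ref_nonref, 2L)
  expect_equal(st$edges_nonref_nonref, 1L)
  expect_equal(st$core_nodes, 0L)             # no segment carries all 3 labels
  expect_equal(st$flexible_single_nodes, 3L)  # r1, r2, n1 have one origin each
  expect_equal(st$flexible_shared_nodes, 1L)  # n2 is in two genomes
})

test_that("non-reference extraction is strict about the 50 bp floor", {
  g <- pangenome_graph(
    data.frame(id = c("r1", "n50", "n51"),
               seq = c(strrep("A", 100), strrep("C", 50), strrep("G", 51)),
               origins = c("reference", "X", "X"), stringsAsFactors = FALSE))
  segs <- extract_nonref(g)
  expect_equal(names(segs), "n51")
  # backbone-only graph yields nothing
  gb <- pangenome_graph(data.frame(id = "r1", seq = strrep("A", 100),
                                   origins = "reference",
                                   stringsAsFactors = FALSE))
  expect_equal(length(extract_nonref(gb)), 0L)
})
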