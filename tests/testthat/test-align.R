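# The k-mer alignment engine: indexing, local alignment, read mapping.

test_that("index counts positions, canonicalizes, and skips N k-mers", {
  idx <- build_index(c(s = "ACGTACGT"), k = 11)
  # too short for k=11: no positions
  expect_equal(cpp_index_info(idx$ptr)$n_positions, 0)
  idx <- build_index(c(s = "ACGTACGTACGTACG"), k = 12)
  expect_equal(cpp_index_info(idx$ptr)$n_positions, 15 - 12 + 1)
  # a k-mer and its reverse complement share one canonical key
  s <- rand_seq(40)
  i1 <- build_index(c(a = s), k = 15)
  i2 <- build_index(c(a = unname(revcomp(s))), k = 15)
  expect_equal(cpp_index_info(i1$ptr)$n_keys, cpp_index_info(i2$ptr)$n_keys)
  # N wipes out every k-mer window it touches: only the N-free window at
  # position 0 survives here
  iN <- build_index(c(a = "ACGTACGTACGTNCA"), k = 12)
  expect_equal(cpp_index_info(iN$ptr)$n_positions, 1)
  # with an N inside every window nothing is indexed
  iN2 <- build_index(c(a = "ACGTANGTACGTACG"), k = 12)
  expect_equal(cpp_index_info(iN2$ptr)$n_positions, 0)
})

test_that("exact substring and reverse-complement queries hit their contract", {
  tt <- tiny_target()
  q <- substr(tt$seq, 3001, 3500)
  h <- local_align(q, tt$index)
  expect_equal(h$identity[1], 1.0)
  expect_equal(h$qcov[1], 1.0)
  expect_equal(h$tstart[1], 3000)
  expect_equal(h$tend[1], 3500)
  expect_equal(h$strand[1], "+")
  hr <- local_align(unname(revcomp(q)), tt$index)
  expect_equal(hr$tstart[1], 3000)
  expect_equal(hr$tend[1], 3500)
  expect_equal(hr$strand[1], "-")
  expect_equal(hr$identity[1], 1.0)
  expect_equal(hr$qcov[1], 1.0)
})

test_that("a single interior substitution in 100 bp gives identity 0.99", {
  tt <- tiny_target()
  q <- substr(tt$seq, 1001, 1100)
  old <- substr(q, 50, 50)
  substr(q, 50, 50) <- setdiff(c("A", "C", "G", "T"), old)[1]
  h <- local_align(q, tt$index)
  expect_equal(h$identity[1], 0.99)
  o <- oracle_global_identity(q, substr(tt$seq, 1001, 1100))
  expect_equal(unname(o["identity"]), 0.99)
  expect_equal(h$matches[1], unname(o["matches"]))
})

test_that("reported identity matches the full local-DP oracle within 1 column", {
  set.seed(31)
  oracle_local_identity <- function(q, t) {
    a <- Biostrings::pairwiseAlignment(q, t, type = "local",
                                       substitutionMatrix = nw_submat,
                                       gapOpening = 5, gapExtension = 1)
    c(identity = Biostrings::nmatch(a) / Biostrings::nchar(a),
      columns = Biostrings::nchar(a))
  }
  mut_interior <- function(seq, k, margin = 20) {
    ch <- strsplit(seq, "")[[1]]; n <- length(ch)
    for (p in sample((margin + 1):(n - margin), k))
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    paste(ch, collapse = "")
  }
  for (t in 1:30) {
    n <- sample(100:300, 1)
    tg <- rand_seq(n)
    q <- mut_interior(tg, rbinom(1, n - 40, 0.05))
    if (runif(1) < 0.5) {
      p <- sample(30:(n - 30), 1)
      q <- paste0(substr(q, 1, p), rand_seq(sample(1:5, 1)),
                  substr(q, p + 1, nchar(q)))
    }
    idx <- build_index(c(t = tg), k = 11)
    h <- local_align(q, idx, min_score = 10)
    o <- oracle_local_identity(q, tg)
    expect_gt(nrow(h), 0)
    col_diff <- abs(h$identity[1] - o["identity"]) *
      max(h$columns[1], o["columns"])
    expect_lte(col_diff, 1)
  }
})

test_that("adding interior substitutions never increases best-hit identity", {
  set.seed(32)
  for (t in 1:8) {
    tg <- rand_seq(400)
    idx <- build_index(c(t = tg), k = 13)
    q <- substr(tg, 51, 350)
    prev <- 1 + 1e-9
    for (step in 1:6) {
      ch <- strsplit(q, "")[[1]]
      for (p in sample(21:(nchar(q) - 20), 3))
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      q <- paste(ch, collapse = "")
      h <- local_align(q, idx, min_score = 10)
      id <- if (nrow(h)) h$identity[1] else 0
      expect_lte(id, prev)
      prev <- id + 1e-9
    }
  }
})

test_that("large insertions split hits; resolve recovers the exact event", {
  tt <- tiny_target()
  set.seed(33)
  ins <- rand_seq(200)
  q <- paste0(substr(tt$seq, 2001, 3000), ins, substr(tt$seq, 3001, 4000))
  h <- local_align(q, tt$index, min_score = 50)
  expect_gte(nrow(h), 2)
  r <- resolve_insertion(q, tt$index, genome = c(chrT = tt$seq))
  la <- left_align_insertion(tt$seq, 3000L, ins)
  expect_equal(r$pos, la$pos)
  expect_equal(r$seq, la$seq)
})

test_that("read mapping places clean reads and rejects novel sequence", {
  tt <- tiny_target()
  set.seed(34)
  starts <- sample(1:(8000 - 100), 50)
  reads <- substring(tt$seq, starts, starts + 99)
  m <- map_reads(reads, tt$index)
  expect_true(all(m$mapped))
  expect_equal(m$pos, starts - 1L)
  # reverse-strand reads map to the same loci
  mr <- map_reads(unname(revcomp(reads[1:10])), tt$index)
  expect_true(all(mr$mapped))
  expect_equal(mr$pos, starts[1:10] - 1L)
  expect_true(all(mr$rev))
  # reads drawn from novel sequence stay unmapped
  novel <- vapply(1:20, function(i) rand_seq(100), character(1))
  mn <- map_reads(novel, tt$index)
  expect_false(any(mn$mapped))
})

test_that("map_read_pair records pairing of both mates", {
  tt <- tiny_target()
  r1 <- substr(tt$seq, 501, 600)
  r2 <- unname(revcomp(substr(tt$seq, 751, 850)))
  p <- map_read_pair(r1, r2, tt$index)
  expect_true(p$mapped1 && p$mapped2)
  expect_true(p$proper)
  expect_equal(p$insert, 350L)
  pu <- map_read_pair(r1, rand_seq(100), tt$index)
  expect_true(pu$mapped1)
  expect_false(pu$mapped2)
  expect_false(pu$proper)
})
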