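# Presence/absence genotyping, MAF filtering, occurrence coding, PCA and
# hierarchical clustering.

test_that("the 80/90 presence rule separates carriers from non-carriers", {
  set.seed(105)
  ref <- list(genome = c(chr1 = rand_seq(20000)))
  ins <- rand_seq(800)
  nuis <- data.frame(id = "NUI_1", chrom = "chr1", pos = 10000L, seq = ins,
                     stringsAsFactors = FALSE)
  tmpl <- build_carrier_template(ref, nuis)
  tidx <- build_index(tmpl$template, k = 15)
  carrier <- list(hap1 = tmpl$template, hap2 = tmpl$template)
  noncar <- list(hap1 = ref$genome, hap2 = ref$genome)
  rc <- simulate_reads(carrier, 30, err_rate = 0, seed = 1)
  gn <- genotype_sample(c(rc$r1, rc$r2), tidx, tmpl$template, tmpl$intervals)
  expect_true(gn$present)
  expect_equal(gn$covered_fraction, 1.0)
  expect_equal(gn$consensus_identity, 1.0)
  rn <- simulate_reads(noncar, 30, err_rate = 0, seed = 2)
  ga <- genotype_sample(c(rn$r1, rn$r2), tidx, tmpl$template, tmpl$intervals)
  expect_false(ga$present)
  expect_lt(ga$covered_fraction, 0.8)
  # a carrier whose insertion copy diverged 15% fails the identity rule
  div <- list(hap1 = ref$genome, hap2 = ref$genome)
  divseq <- mutate_at_rate(ins, 0.15)
  sp <- splice_insertions(ref$genome[[1]], 10000L, divseq)
  div$hap1 <- div$hap2 <- c(chr1 = sp$seq)
  rd <- simulate_reads(div, 30, err_rate = 0, seed = 3)
  gd <- genotype_sample(c(rd$r1, rd$r2), tidx, tmpl$template, tmpl$intervals)
  expect_lt(gd$consensus_identity, 0.90)
  expect_false(gd$present)
  # zero-length interval is rejected
  bad <- tmpl$intervals
  bad$end <- bad$start
  expect_error(genotype_sample("ACGT", tidx, tmpl$template, bad),
               "zero-length")
})

test_that("matrix building is complete, sorted and breed-labeled", {
  calls <- data.frame(sample = c("s1", "s1", "s2", "s2"),
                      nui_id = c("n1", "n2", "n1", "n2"),
                      present = c(TRUE, FALSE, FALSE, TRUE),
                      stringsAsFactors = FALSE)
  m <- build_matrix(calls, breed_of = c(s1 = "Gir", s2 = "Sahiwal"))
  expect_equal(dim(m$matrix), c(2L, 2L))
  expect_equal(m$breed, c("Gir", "Sahiwal"))
  expect_true(m$matrix["s1", "n1"])
  expect_error(build_matrix(calls[-1, ]), "incomplete")
  one <- build_matrix(calls[1, , drop = FALSE])
  expect_equal(dim(one$matrix), c(1L, 1L))
})

test_that("MAF filter drops rare and monomorphic insertions", {
  n <- 98
  M <- matrix(FALSE, nrow = n, ncol = 4,
              dimnames = list(paste0("s", 1:n), paste0("n", 1:4)))
  M[, 1] <- TRUE                 # present in all -> excluded
  M[1:10, 3] <- TRUE             # 10/98 ~ 0.102 -> kept
  M[1:2, 4] <- TRUE              # 2/98 ~ 0.020 -> excluded
  expect_equal(maf_filter(M), "n3")
  # oracle identity: brute-force per-column frequency count on random matrices
  set.seed(106)
  for (t in 1:20) {
    R <- matrix(runif(50 * 30) < runif(30)[col(matrix(0, 50, 30))],
                nrow = 50, dimnames = list(NULL, paste0("c", 1:30)))
    mine <- maf_filter(R)
    f <- apply(R, 2, function(x) sum(x) / length(x))
    oracle <- colnames(R)[pmin(f, 1 - f) >= 0.05 & f > 0 & f < 1]
    expect_identical(mine, oracle)
  }
})

test_that("occurrence matrix codes pseudohaplotype occupancy as 0/1/2", {
  occ <- data.frame(nui_id = c("n1", "n1", "n1", "n2"),
                    sample = c("A", "A", "B", "A"),
                    hap = c(1L, 2L, 1L, 2L), stringsAsFactors = FALSE)
  M <- occurrence_matrix(occ, samples = c("A", "B"), nui_ids = c("n1", "n2"))
  expect_equal(M["A", "n1"], 2L)
  expect_equal(M["B", "n1"], 1L)
  expect_equal(M["B", "n2"], 0L)
  expect_true(all(M %in% 0:2))
})

test_that("PCA centers without scaling and matches the closed-form eigenproblem", {
  M <- rbind(a = c(0, 0), b = c(1, 0), c = c(1, 1))
  p <- pca_matrix(M)
  expect_equal(sum(p$explained), 1)
  ev <- eigen(stats::cov(M))
  expect_equal(p$explained, ev$values / sum(ev$values), tolerance = 1e-12)
  # scores match the eigenvector projection up to sign
  ctr <- scale(M, center = TRUE, scale = FALSE)
  proj <- ctr %*% ev$vectors
  for (j in 1:2) {
    expect_true(isTRUE(all.equal(p$scores[, j], proj[, j],
                                 check.attributes = FALSE)) ||
                isTRUE(all.equal(p$scores[, j], -proj[, j],
                                 check.attributes = FALSE)))
  }
  # identical rows get identical scores; constant columns are dropped
  M2 <- rbind(a = c(1, 0, 5), b = c(1, 0, 5), c = c(0, 1, 5))
  p2 <- pca_matrix(M2)
  expect_equal(p2$scores["a", ], p2$scores["b", ], ignore_attr = TRUE)
})

test_that("UPGMA over Jaccard distances matches the hand-computed merge", {
  # d(s1,s2) = 1 - 1/2 = 0.5 ; d(s1,s3) = d(s2,s3) = 1
  M <- rbind(s1 = c(1, 1, 0, 0), s2 = c(1, 0, 0, 0), s3 = c(0, 0, 1, 1))
  hc <- hierarchical_cluster(M)
  expect_equal(as.vector(hc$dist), c(0.5, 1, 1))
  # s1+s2 join first at height 0.5 (plotted half-heights 0.25), then s3 at 1
  expect_equal(hc$newick, "(s3:0.5,(s1:0.25,s2:0.25):0.25);")
  expect_equal(hc$hclust$height, c(0.5, 1.0))
  # duplicate samples join first at height 0
  Md <- rbind(a = c(1, 0, 1), b = c(1, 0, 1), c = c(0, 1, 0))
  hd <- hierarchical_cluster(Md)
  expect_equal(hd$hclust$height[1], 0)
  tree <- ape::read.tree(text = hd$newick)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
})
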