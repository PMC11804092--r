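#!/usr/bin/env Rscript
# Genotype the insertion panel across the 98-sample cohort: map each
# sample's 30X reads to the carrier template, apply the 80% coverage / 90%
# consensus-identity presence rule, build the genotype matrix, and filter at
# MAF >= 5% to obtain the common-insertion (BICI) set. Then the population
# structure: PCA of the matrix and a UPGMA cladogram over Jaccard distances.

library(panins)

study <- readRDS("scratch/genotyping_study.rds")
message("Genotyping ", nrow(study$cohort$samples), " samples against ",
        nrow(study$template$intervals), " insertion loci...")
gm <- genotype_cohort(study, verbose = TRUE)

truth <- study$cohort$genotypes[rownames(gm$matrix), colnames(gm$matrix)] > 0
message(sprintf("  genotype accuracy vs truth: %.4f",
                mean(gm$matrix == truth)))

bici <- maf_filter(gm$matrix)
message(length(bici), " of ", ncol(gm$matrix),
        " insertions pass MAF >= 5% -> BICI set")

utils::write.table(
  data.frame(sample = rownames(gm$matrix), breed = gm$breed,
             gm$matrix * 1L, check.names = FALSE),
  "results/genotype_matrix.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(gm$evidence, "results/genotype_evidence.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
writeLines(bici, "results/bici_ids.txt")

# population structure on the BICI columns
M <- gm$matrix[, bici, drop = FALSE] * 1
p <- pca_matrix(M)
message(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance",
                100 * p$explained[1], 100 * p$explained[2]))
utils::write.table(
  data.frame(sample = rownames(p$scores), breed = gm$breed,
             round(p$scores[, 1:min(4, ncol(p$scores))], 4)),
  "results/pca_scores.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
hc <- hierarchical_cluster(M)
writeLines(hc$newick, "results/cladogram.nwk")
saveRDS(list(gm = gm, bici = bici), "scratch/genotype_result.rds")
message("Done; matrix, PCA scores and cladogram under results/.")
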