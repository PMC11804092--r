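#!/usr/bin/env Rscript
# Characterize the final insertion set: repeat/TE composition with major-TE
# assignment and 300 bp flank analysis, genic context of breakpoints against
# a synthetic gene annotation, cross-species sharing against mutated
# "sister species" genomes, and the consolidated report.

library(panins)

st <- readRDS("scratch/discovery_study.rds")
final <- readRDS("scratch/final_nuis.rds")
params <- pipeline_params()

message("Repeat composition of ", nrow(final), " insertions...")
anns <- lapply(final$seq, annotate_repeats, repeat_library = st$library,
               params = params)
major <- vapply(anns, major_te, character(1))
rs <- repeat_summary(anns, major)
message(sprintf("  interspersed repeat fraction: %.2f%%",
                100 * sum(rs$class_fraction[c("LINE", "SINE", "LTR", "DNA")])))
flanks <- t(vapply(seq_len(nrow(final)), function(i)
  unlist(flank_te_analysis(final[i, ], st$reference$genome, st$library,
                           params)), logical(4)))
ann_tab <- data.frame(id = final$id, len = final$len, major_te = major,
                      unique_bp = vapply(anns, unique_bases, numeric(1)),
                      flanks)
utils::write.table(ann_tab, "results/insertion_repeats.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# synthetic gene annotation over the reference: non-overlapping genes with
# 1-3 exons, mixed biotypes
set.seed(4)
genes <- list()
exons <- list()
gid <- 0
for (chrom in names(st$reference$genome)) {
  pos <- 0
  L <- nchar(st$reference$genome[[chrom]])
  while (pos < L - 40000) {
    pos <- pos + sample(10000:30000, 1)
    glen <- sample(3000:15000, 1)
    if (pos + glen >= L) break
    gid <- gid + 1
    id <- sprintf("gene%03d", gid)
    genes[[gid]] <- data.frame(
      gene_id = id, chrom = chrom, start = pos, end = pos + glen,
      strand = sample(c("+", "-"), 1),
      biotype = sample(c("protein_coding", "protein_coding", "protein_coding",
                         "lncRNA", "pseudogene"), 1))
    ne <- sample(1:3, 1)
    bounds <- sort(sample(seq(pos, pos + glen), 2 * ne))
    exons[[gid]] <- data.frame(gene_id = id, chrom = chrom,
                               start = bounds[seq(1, 2 * ne, 2)],
                               end = bounds[seq(2, 2 * ne, 2)])
    pos <- pos + glen
  }
}
models <- list(genes = do.call(rbind, genes), exons = do.call(rbind, exons))
models$exons <- models$exons[models$exons$end > models$exons$start, ]
write_gff3(models, "results/synthetic_annotation.gff3")

cl <- classify_breakpoints(final, models)
message(sprintf("  genic %d (exonic %d, intronic %d), intergenic %d",
                cl$category_counts["genic"], cl$category_counts["exonic"],
                cl$category_counts["intronic"],
                cl$category_counts["intergenic"]))
ng <- do.call(rbind, lapply(which(cl$per_bici$category == "intergenic"),
  function(i) {
    g <- nearest_gene(final$chrom[i], final$pos[i], models,
                      params$nearest_gene_window)
    if (nrow(g)) cbind(id = final$id[i], g[1, ]) else NULL
  }))
utils::write.table(cl$per_bici, "results/breakpoint_annotation.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# cross-species sharing: sister species = mutated reference copies, each
# carrying a subset of the insertions
message("Cross-species sharing against 5 synthetic sister genomes...")
set.seed(5)
species <- list()
carried <- list()
for (sp in c("taurus", "gaurus", "frontalis", "grunniens", "mutus")) {
  keep <- runif(nrow(final)) < 0.6
  g <- st$reference$genome
  ins <- final[keep, ]
  for (chrom in names(g)) {
    idx <- which(ins$chrom == chrom)
    if (length(idx))
      g[[chrom]] <- panins:::splice_insertions(g[[chrom]], ins$pos[idx],
                                               ins$seq[idx])$seq
    g[[chrom]] <- panins:::mutate_seq(g[[chrom]], 0.01)
  }
  species[[sp]] <- g
  carried[[sp]] <- keep
}
M <- species_presence(stats::setNames(final$seq, final$id), species, params)
sm <- sharing_summary(M)
message(sprintf("  shared with any sister species: %d (%.2f%%); all five: %d (%.2f%%)",
                sm$any_species, sm$pct_any, sm$all_species, sm$pct_all))
utils::write.table(data.frame(id = rownames(M), M * 1L),
                   "results/sharing_matrix.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

gres <- readRDS("scratch/genotype_result.rds")
graph <- readRDS("scratch/graph_result.rds")
report(
  list(
    discovery = c(raw_nuis = nrow(readRDS("scratch/discovery_result.rds")$nuis),
                  final_nuis = nrow(final), final_bp = sum(final$len)),
    graph = c(nonref_nodes = graph$stats$n_nodes_nonref,
              nonref_bp = graph$stats$bp_nonref,
              pct_core = graph$stats$pct_core),
    genotyping = c(n_samples = nrow(gres$gm$matrix),
                   n_bicis = length(gres$bici)),
    repeat_fractions = as.list(rs$class_fraction),
    size_bins = as.data.frame(rs$size_bins),
    genic = as.list(cl$category_counts),
    sharing = list(any_species = sm$any_species, pct_any = sm$pct_any,
                   all_species = sm$all_species, pct_all = sm$pct_all)),
  json_path = "results/report.json", tsv_path = "results/report.tsv",
  params = params)
message("Done; consolidated report under results/report.{json,tsv}.")
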