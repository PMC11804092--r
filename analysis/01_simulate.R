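#!/usr/bin/env Rscript
# Simulate the study cohorts: a 2 Mb, 5-sample discovery cohort (two
# pseudohaplotypes per sample, 30X paired reads, 0.1% substitution error)
# and a 98-sample genotyping cohort over a 300 kb reference. Truth tables
# and small artifacts go to results/; the heavyweight objects are cached
# under scratch/ for the later steps.

library(panins)

seed <- 1L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

message("Simulating discovery study (2 Mb reference, 5 samples, 30X)...")
st <- simulate_discovery_study(seed = seed)
message("  ", nrow(st$insertions), " insertions drawn; ",
        nrow(st$truth), " carried by at least one sequenced sample")
message("  insertion sizes: median ", stats::median(st$truth$len),
        " bp, range ", min(st$truth$len), "-", max(st$truth$len), " bp")

write_fasta(st$reference$genome, "scratch/reference.fa")
write_fasta(stats::setNames(st$library$seq, st$library$name),
            "results/repeat_library.fa")
write_bed(st$reference$repeats, "results/reference_repeats.bed")
utils::write.table(st$truth[, c("id", "chrom", "pos", "len", "allele_freq")],
                   "results/truth_insertions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(sample = rownames(st$cohort$genotypes),
                              st$cohort$genotypes, check.names = FALSE),
                   "results/truth_genotypes_discovery.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
saveRDS(st, "scratch/discovery_study.rds")

message("Simulating 98-sample genotyping cohort (300 kb reference)...")
gs <- simulate_genotyping_study(seed = seed)
utils::write.table(gs$cohort$samples, "results/cohort_samples.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(gs, "scratch/genotyping_study.rds")
message("Done; truth tables under results/, cached objects under scratch/.")
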