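# Lazy shared fixtures for the heavy study-scale tests. Each study is
# simulated and processed once per test run and reused by every block that
# needs it.

.preset_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .preset_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .preset_cache)
  }
  get(key, envir = .preset_cache, inherits = FALSE)
}

discovery_study <- function() cached("disc_study", simulate_discovery_study(seed = 101L))

discovery_result <- function() cached("disc_result", {
  st <- discovery_study()
  discover_nuis(st$sample_data, st$reference, st$library)
})

graph_result <- function() cached("graph_result", {
  st <- discovery_study()
  assemblies <- lapply(st$sample_data, function(sd) c(sd$haps$hap1, sd$haps$hap2))
  ord <- order_assemblies(st$reference$genome, assemblies)
  b <- build_backbone(st$reference$genome)
  for (a in ord$assembly) augment(b, a, assemblies[[a]])
  g <- realize_graph(b)
  list(builder = b, graph = g, order = ord, assemblies = assemblies,
       stats = graph_stats(g, n_genomes = 1 + length(assemblies)))
})

genotyping_study <- function() cached("geno_study", simulate_genotyping_study(seed = 101L))

genotyping_result <- function() cached("geno_result", genotype_cohort(genotyping_study()))

# small reusable alignment fixture
tiny_target <- function() cached("tiny_target", {
  set.seed(77)
  t <- rand_seq(8000)
  list(seq = t, index = build_index(c(chrT = t), k = 15))
})
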