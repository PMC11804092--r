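# Genic classification of insertion breakpoints, nearest-gene search,
# cross-species presence, and the summary reporter.

#' Round-half-up percentage
#'
#' @param n numerator, @param d denominator, @param digits displayed
#'   precision (default 2).
#' @return `100 * n / d` rounded half-up at `digits`.
#' @export
percentage <- function(n, d, digits = 2) {
  if (d == 0) return(0)
  x <- 100 * n / d
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Classify insertion breakpoints against gene models
#'
#' A zero-width breakpoint is exonic when it falls inside any exon, else
#' intronic when inside a gene span, else intergenic. A breakpoint inside
#' two overlapping genes credits both genes but is counted once (exonic
#' dominates intronic).
#'
#' @param bicis data.frame with id, chrom, pos.
#' @param models gene models from [read_gff3()] (list with `genes`, `exons`).
#' @return list with `per_bici` (id, category, genes), `category_counts`,
#'   `gene_hits` (gene_id, n_bicis, biotype), `biotype_tally`,
#'   `genes_multi` (genes with >= 2 breakpoints).
#' @export
classify_breakpoints <- function(bicis, models) {
  genes <- models$genes
  exons <- models$exons
  cat <- character(nrow(bicis))
  gene_list <- vector("list", nrow(bicis))
  for (i in seq_len(nrow(bicis))) {
    p <- bicis$pos[i]; ch <- bicis$chrom[i]
    g_in <- genes$gene_id[genes$chrom == ch & genes$start <= p & p < genes$end]
    if (!length(g_in)) { cat[i] <- "intergenic"; next }
    e_in <- exons$gene_id[exons$chrom == ch & exons$start <= p & p < exons$end]
    cat[i] <- if (length(intersect(e_in, g_in))) "exonic" else "intronic"
    gene_list[[i]] <- sort(unique(g_in))
  }
  per_bici <- data.frame(
    id = bicis$id, category = cat,
    genes = vapply(gene_list, function(g)
      if (is.null(g)) "" else paste(g, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  category_counts <- c(exonic = sum(cat == "exonic"),
                       intronic = sum(cat == "intronic"),
                       genic = sum(cat != "intergenic"),
                       intergenic = sum(cat == "intergenic"))
  hit_genes <- unlist(gene_list)
  gene_hits <- if (length(hit_genes)) {
    tab <- table(hit_genes)
    data.frame(gene_id = names(tab), n_bicis = as.integer(tab),
               biotype = genes$biotype[match(names(tab), genes$gene_id)],
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), n_bicis = integer(),
               biotype = character(), stringsAsFactors = FALSE)
  }
  biotype_tally <- table(factor(gene_hits$biotype,
                                levels = c("protein_coding", "lncRNA",
                                           "pseudogene", "other")))
  list(per_bici = per_bici, category_counts = category_counts,
       gene_hits = gene_hits, biotype_tally = biotype_tally,
       genes_multi = gene_hits$gene_id[gene_hits$n_bicis >= 2L])
}

#' Nearest gene within a window
#'
#' Distance is measured from the breakpoint to the nearer gene-span
#' boundary; 0 inside a gene. Returns no gene when the minimum distance
#' exceeds the window; exact ties report every tied gene.
#'
#' @param chrom,pos breakpoint location (0-based).
#' @param models gene models from [read_gff3()].
#' @param window maximum distance (default 20000).
#' @return data.frame with gene_id, distance (0 rows when none qualify).
#' @export
nearest_gene <- function(chrom, pos, models, window = 20000L) {
  g <- models$genes[models$genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(data.frame(gene_id = character(), distance = integer()))
  d <- ifelse(pos < g$start, g$start - pos,
              ifelse(pos >= g$end, pos - g$end, 0L))
  dmin <- min(d)
  if (dmin > window) return(data.frame(gene_id = character(),
                                       distance = integer()))
  data.frame(gene_id = g$gene_id[d == dmin], distance = d[d == dmin],
             stringsAsFactors = FALSE)
}

#' Cross-species presence of insertion sequences
#'
#' An insertion is present in a species when any alignment against that
#' species' genome reaches `species_identity` and `species_coverage`.
#'
#' @param bici_seqs named character vector.
#' @param species_genomes named list of named character vectors.
#' @param params [pipeline_params()].
#' @return Logical matrix (insertions x species).
#' @export
species_presence <- function(bici_seqs, species_genomes,
                             params = pipeline_params()) {
  M <- matrix(FALSE, nrow = length(bici_seqs),
              ncol = length(species_genomes),
              dimnames = list(names(bici_seqs), names(species_genomes)))
  for (sp in names(species_genomes)) {
    idx <- build_index(species_genomes[[sp]], k = params$index_k)
    M[, sp] <- vapply(seq_along(bici_seqs), function(i) {
      h <- local_align(bici_seqs[[i]], idx, min_score = 20,
                       seed_step = if (nchar(bici_seqs[[i]]) > 2000) 3L else 1L)
      any(h$identity >= params$species_identity &
            h$qcov >= params$species_coverage)
    }, logical(1))
  }
  M
}

#' Summarize a sharing matrix
#'
#' @param M logical matrix (insertions x species).
#' @return list of counts (per species, shared in any, shared in all, unique
#'   per species) with raw fractions and rounded percentages.
#' @export
sharing_summary <- function(M) {
  n <- nrow(M)
  rs <- rowSums(M)
  per_species <- colSums(M)
  uniq <- colSums(M[rs == 1L, , drop = FALSE])
  list(
    n_insertions = n,
    per_species = per_species,
    any_species = sum(rs >= 1L),
    all_species = sum(rs == ncol(M)),
    unique_per_species = uniq,
    pct_any = percentage(sum(rs >= 1L), n),
    pct_all = percentage(sum(rs == ncol(M)), n),
    pct_per_species = vapply(per_species, percentage, numeric(1), d = n)
  )
}

#' Assemble the master analysis report
#'
#' Gathers every upstream table into one structure and optionally writes it
#' as JSON plus a `#`-annotated TSV. Regeneration from the same inputs is
#' deterministic.
#'
#' @param sections named list of report sections (data.frames, vectors,
#'   lists of numbers).
#' @param json_path,tsv_path optional output paths.
#' @param params [pipeline_params()] recorded alongside the numbers.
#' @return The report list, invisibly when written.
#' @export
report <- function(sections, json_path = NULL, tsv_path = NULL,
                   params = pipeline_params()) {
  # named atomic vectors keep their names as JSON keys
  sections_json <- lapply(sections, function(x)
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x)
  rep <- list(parameters = unclass(params), sections = sections_json)
  if (!is.null(json_path)) {
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, "w")
    on.exit(close(con))
    writeLines(sprintf("# %s=%s", names(params),
                       vapply(params, format, character(1))), con)
    for (nm in names(sections)) {
      writeLines(paste0("## ", nm), con)
      x <- sections[[nm]]
      if (is.data.frame(x)) {
        utils::write.table(x, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      } else if (is.matrix(x)) {
        utils::write.table(x, con, sep = "\t", quote = FALSE,
                           row.names = TRUE, col.names = NA)
      } else {
        x <- unlist(x)
        writeLines(paste(names(x), x, sep = "\t"), con)
      }
    }
  }
  if (is.null(json_path) && is.null(tsv_path)) rep else invisible(rep)
}
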