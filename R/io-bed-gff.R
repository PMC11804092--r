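# Interval IO. All internal coordinates are 0-based half-open; GFF3 (1-based
# inclusive) is converted at the boundary and converted back on write.

#' Read a BED3/BED6 file
#'
#' @param path BED file (0-based half-open, as the format defines).
#' @return data.frame with columns chrom, start, end and, when present,
#'   name, score, strand.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t| +")
  ncol <- min(vapply(parts, length, integer(1)))
  if (ncol < 3) stop("BED line with fewer than 3 fields")
  df <- data.frame(
    chrom = vapply(parts, `[[`, character(1), 1L),
    start = as.integer(vapply(parts, `[[`, character(1), 2L)),
    end   = as.integer(vapply(parts, `[[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
  if (ncol >= 4) df$name <- vapply(parts, `[[`, character(1), 4L)
  if (ncol >= 5) df$score <- vapply(parts, `[[`, character(1), 5L)
  if (ncol >= 6) df$strand <- vapply(parts, `[[`, character(1), 6L)
  bad <- which(df$end <= df$start)
  if (length(bad)) stop("BED line ", bad[[1L]], ": end <= start")
  df
}

#' Write intervals as BED
#'
#' @param df data.frame with chrom, start, end and optional name/score/strand.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Genes and their exons are extracted; coordinates are converted to the
#' internal 0-based half-open convention (`start-1`, `end`). The gene biotype
#' is taken from the `biotype`/`gene_biotype` attribute and collapsed to
#' `protein_coding`, `lncRNA`, `pseudogene` or `other`.
#'
#' @param path GFF3 file.
#' @return list with `genes` (gene_id, chrom, start, end, strand, biotype)
#'   and `exons` (gene_id, chrom, start, end) data.frames.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  to_df <- function(x) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
               start = GenomicRanges::start(x) - 1L,   # 1-based -> 0-based
               end = GenomicRanges::end(x),
               strand = as.character(GenomicRanges::strand(x)),
               stringsAsFactors = FALSE)
  }
  is_gene <- type %in% c("gene", "pseudogene", "ncRNA_gene")
  g <- gr[is_gene]
  gmd <- S4Vectors::mcols(g)
  gid <- as.character(gmd$ID)
  if (all(is.na(gid)) && !is.null(gmd$gene_id)) gid <- as.character(gmd$gene_id)
  bt <- rep(NA_character_, length(g))
  for (cand in c("biotype", "gene_biotype", "gene_type")) {
    if (!is.null(gmd[[cand]])) {
      v <- as.character(gmd[[cand]])
      bt[is.na(bt) & !is.na(v)] <- v[is.na(bt) & !is.na(v)]
    }
  }
  bt[as.character(gmd$type) == "pseudogene" & is.na(bt)] <- "pseudogene"
  bt <- ifelse(is.na(bt), "other",
        ifelse(bt %in% c("protein_coding"), "protein_coding",
        ifelse(bt %in% c("lncRNA", "lincRNA"), "lncRNA",
        ifelse(grepl("pseudogene", bt), "pseudogene", "other"))))
  genes <- cbind(data.frame(gene_id = gid, stringsAsFactors = FALSE), to_df(g))
  genes$biotype <- bt
  ex <- gr[type == "exon"]
  parent <- S4Vectors::mcols(ex)$Parent
  pid <- if (is.null(parent)) rep(NA_character_, length(ex)) else
    vapply(as.list(parent), function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1))
  # exons usually point at transcripts; walk one level up to the gene
  tx <- gr[type %in% c("mRNA", "transcript", "lnc_RNA", "ncRNA",
                       "pseudogenic_transcript")]
  txmd <- S4Vectors::mcols(tx)
  tx_id <- as.character(txmd$ID)
  tx_parent <- vapply(as.list(txmd$Parent), function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))
  map <- stats::setNames(tx_parent, tx_id)
  gene_of <- ifelse(pid %in% gid, pid, unname(map[pid]))
  exons <- cbind(data.frame(gene_id = gene_of, stringsAsFactors = FALSE), to_df(ex))
  exons <- exons[!is.na(exons$gene_id), c("gene_id", "chrom", "start", "end")]
  if (any(genes$end <= genes$start)) {
    stop("GFF3 record with end <= start after conversion (gene ",
         genes$gene_id[which(genes$end <= genes$start)[1L]], ")")
  }
  list(genes = genes, exons = exons)
}

#' Write gene models back to GFF3
#'
#' Inverse of [read_gff3()]; internal 0-based half-open coordinates are
#' converted back to 1-based inclusive.
#'
#' @param models list with `genes` and `exons` as returned by [read_gff3()].
#' @param path output file.
#' @export
write_gff3 <- function(models, path) {
  g <- models$genes
  e <- models$exons
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(g))) {
    writeLines(sprintf("%s\tpanins\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                       g$chrom[i], g$start[i] + 1L, g$end[i], g$strand[i],
                       g$gene_id[i], g$biotype[i]), con)
    ge <- e[e$gene_id == g$gene_id[i], , drop = FALSE]
    if (nrow(ge)) {
      for (j in seq_len(nrow(ge))) {
        writeLines(sprintf("%s\tpanins\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                           ge$chrom[j], ge$start[j] + 1L, ge$end[j],
                           g$strand[i], g$gene_id[i]), con)
      }
    }
  }
  invisible(path)
}
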