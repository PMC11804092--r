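# GFA1 IO for pangenome graphs. Segment origin (which genomes contain the
# segment) is carried in an optional SR:Z: tag holding a comma-separated
# genome list; segments without the tag are classed as reference-only.

#' Construct a pangenome graph object
#'
#' @param segments data.frame with columns `id`, `seq`, `origins`
#'   (comma-separated genome labels; the reference carries the label
#'   `reference`).
#' @param links data.frame with columns `from`, `from_orient`, `to`,
#'   `to_orient`.
#' @param reference_label label identifying the reference genome among
#'   origins.
#' @return An object of class `pangenome_graph`.
#' @export
pangenome_graph <- function(segments, links = NULL,
                            reference_label = "reference") {
  if (is.null(links)) {
    links <- data.frame(from = character(), from_orient = character(),
                        to = character(), to_orient = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "seq", "origins") %in% names(segments)))
  if (anyDuplicated(segments$id)) stop("duplicate segment id")
  unknown <- setdiff(c(links$from, links$to), segments$id)
  if (length(unknown)) stop("link references unknown segment: ", unknown[[1L]])
  segments$length <- nchar(segments$seq)
  structure(list(segments = segments, links = links,
                 reference_label = reference_label),
            class = "pangenome_graph")
}

#' @export
print.pangenome_graph <- function(x, ...) {
  ref <- grepl_origin(x$segments$origins, x$reference_label)
  cat("pangenome_graph:", nrow(x$segments), "segments (",
      sum(ref), "reference /", sum(!ref), "non-reference ),",
      nrow(x$links), "links\n")
  invisible(x)
}

# does the comma-separated origin string contain this label?
grepl_origin <- function(origins, label) {
  vapply(strsplit(origins, ",", fixed = TRUE),
         function(o) label %in% o, logical(1))
}

#' Read a GFA1 graph
#'
#' Parses H/S/L lines. Sequence length is validated against any `LN:i:` tag;
#' origins come from the `SR:Z:` tag (absent tag means reference-only).
#'
#' @param path GFA file.
#' @param reference_label origin label used for untagged segments.
#' @return A [pangenome_graph()] object.
#' @export
read_gfa <- function(path, reference_label = "reference") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  srec <- list(); lrec <- list()
  for (ln in lines) {
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (f[[1L]] == "S") {
      if (length(f) < 3) stop("malformed S line: ", ln)
      origins <- reference_label
      for (tag in f[-(1:3)]) {
        if (startsWith(tag, "SR:Z:")) origins <- substring(tag, 6L)
        if (startsWith(tag, "LN:i:")) {
          if (as.integer(substring(tag, 6L)) != nchar(f[[3L]]))
            stop("LN tag disagrees with sequence length for segment ", f[[2L]])
        }
      }
      srec[[length(srec) + 1L]] <- data.frame(
        id = f[[2L]], seq = f[[3L]], origins = origins, stringsAsFactors = FALSE)
    } else if (f[[1L]] == "L") {
      if (length(f) < 5) stop("malformed L line: ", ln)
      lrec[[length(lrec) + 1L]] <- data.frame(
        from = f[[2L]], from_orient = f[[3L]], to = f[[4L]],
        to_orient = f[[5L]], stringsAsFactors = FALSE)
    }
  }
  if (!length(srec)) stop("no records: GFA has no S lines")
  segments <- do.call(rbind, srec)
  links <- if (length(lrec)) do.call(rbind, lrec) else NULL
  pangenome_graph(segments, links, reference_label)
}

#' Write a pangenome graph as GFA1
#'
#' @param graph a [pangenome_graph()].
#' @param path output file.
#' @export
write_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "pangenome_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  s <- graph$segments
  writeLines(sprintf("S\t%s\t%s\tLN:i:%d\tSR:Z:%s",
                     s$id, s$seq, nchar(s$seq), s$origins), con)
  l <- graph$links
  if (nrow(l)) {
    writeLines(sprintf("L\t%s\t%s\t%s\t%s\t0M",
                       l$from, l$from_orient, l$to, l$to_orient), con)
  }
  invisible(path)
}
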