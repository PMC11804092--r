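# Repeat and low-complexity masking: symmetric DUST, repeat-library masking
# with TE classification, the >= 50-unique-base criterion, major-TE
# assignment, and flank/breakpoint-crossing analysis.

#' Symmetric DUST low-complexity intervals
#'
#' Scores every interval of up to `W` bases as
#' `S = sum c_t (c_t - 1) / 2 / (w - 2)` over its triplet counts `c_t` and
#' reports maximal perfect intervals (score above `T/10` and at least the
#' score of every subinterval), merged when overlapping.
#'
#' @param seq a single sequence.
#' @param W window size (default 64).
#' @param T score threshold on the 10x scale (default 20, i.e. score > 2).
#' @return data.frame with 0-based half-open `start`, `end` columns.
#' @export
sdust <- function(seq, W = 64L, T = 20) {
  stopifnot(is.character(seq), length(seq) == 1)
  m <- cpp_sdust(seq, as.integer(W), T / 10)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Annotate a sequence against a repeat consensus library
#'
#' Each consensus is aligned locally to the sequence (both strands); hits
#' with identity >= `repeat_hit_identity` and length >=
#' `repeat_hit_minlen` become intervals labeled with the consensus TE class.
#' Overlaps are resolved best-score-first; DUST intervals are appended as
#' `LOW_COMPLEXITY`. Unique bases are those left unmasked by the union.
#'
#' @param seq a single sequence.
#' @param repeat_library data.frame with name, te_class, seq.
#' @param params [pipeline_params()].
#' @return list of class `repeat_annotation`: `intervals` (start, end, label),
#'   `hits` (qualified raw hits with label), `class_bp` (named vector over
#'   LINE/SINE/LTR/DNA/LOW_COMPLEXITY), `unique_bp`, `length`.
#' @export
annotate_repeats <- function(seq, repeat_library, params = pipeline_params()) {
  stopifnot(nrow(repeat_library) > 0)
  n <- nchar(seq)
  classes <- c("LINE", "SINE", "LTR", "DNA", "LOW_COMPLEXITY")
  empty <- function() {
    structure(list(
      intervals = data.frame(start = integer(), end = integer(),
                             label = character(), stringsAsFactors = FALSE),
      hits = data.frame(start = integer(), end = integer(), label = character(),
                        score = numeric(), identity = numeric(),
                        stringsAsFactors = FALSE),
      class_bp = stats::setNames(rep(0L, length(classes)), classes),
      unique_bp = n, length = n), class = "repeat_annotation")
  }
  if (n < params$repeat_k) return(empty())
  idx <- build_index(c(target = seq), k = params$repeat_k)
  hits <- list()
  for (i in seq_len(nrow(repeat_library))) {
    h <- local_align(repeat_library$seq[i], idx, min_score = 0,
                     max_occ = 5000L)
    if (!nrow(h)) next
    len <- h$tend - h$tstart
    keep <- h$identity >= params$repeat_hit_identity &
      len >= params$repeat_hit_minlen
    h <- h[keep, , drop = FALSE]
    if (!nrow(h)) next
    hits[[length(hits) + 1L]] <- data.frame(
      start = h$tstart, end = h$tend,
      label = repeat_library$te_class[i], score = h$score,
      identity = h$identity, stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else empty()$hits
  # best-score-first painting
  lab <- integer(n)  # 0 = unmasked, otherwise index into classes
  if (nrow(hits)) {
    hits <- hits[order(-hits$score, hits$start), , drop = FALSE]
    for (i in seq_len(nrow(hits))) {
      span <- seq.int(hits$start[i] + 1L, hits$end[i])
      free <- span[lab[span] == 0L]
      lab[free] <- match(hits$label[i], classes)
    }
  }
  d <- sdust(seq, params$dust_window, params$dust_threshold)
  if (nrow(d)) {
    for (i in seq_len(nrow(d))) {
      span <- seq.int(d$start[i] + 1L, d$end[i])
      free <- span[lab[span] == 0L]
      lab[free] <- match("LOW_COMPLEXITY", classes)
    }
  }
  # painted runs -> intervals
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0L
  intervals <- data.frame(start = starts[keep], end = ends[keep],
                          label = classes[r$values[keep]],
                          stringsAsFactors = FALSE)
  class_bp <- vapply(classes, function(cl) sum(lab == match(cl, classes)),
                     integer(1))
  structure(list(intervals = intervals, hits = hits, class_bp = class_bp,
                 unique_bp = sum(lab == 0L), length = n),
            class = "repeat_annotation")
}

#' @export
print.repeat_annotation <- function(x, ...) {
  cat("repeat_annotation:", x$length, "bp,", x$unique_bp, "unique;",
      paste(sprintf("%s=%d", names(x$class_bp), x$class_bp), collapse = " "),
      "\n")
  invisible(x)
}

#' Unique (unmasked) bases and the NUI uniqueness filter
#'
#' @param annotation a [annotate_repeats()] result.
#' @param params [pipeline_params()].
#' @return `unique_bases()` the count; `passes_unique_filter()` whether it
#'   reaches `min_unique_bases` (>= 50 by default).
#' @export
unique_bases <- function(annotation) annotation$unique_bp

#' @rdname unique_bases
#' @export
passes_unique_filter <- function(annotation, params = pipeline_params()) {
  unique_bases(annotation) >= params$min_unique_bases
}

#' Major TE class of an annotated sequence
#'
#' The interspersed class with the largest base share wins; no interspersed
#' repeat at all gives `NONE`. Ties break by larger summed hit score, then by
#' the fixed order LINE > SINE > LTR > DNA.
#'
#' @param annotation a [annotate_repeats()] result.
#' @return One of `"LINE"`, `"SINE"`, `"LTR"`, `"DNA"`, `"NONE"`.
#' @export
major_te <- function(annotation) {
  order_cls <- c("LINE", "SINE", "LTR", "DNA")
  bp <- annotation$class_bp[order_cls]
  if (all(bp == 0)) return("NONE")
  top <- order_cls[bp == max(bp)]
  if (length(top) == 1L) return(top)
  sc <- vapply(top, function(cl)
    sum(annotation$hits$score[annotation$hits$label == cl]), numeric(1))
  top <- top[sc == max(sc)]
  top[[1L]]  # order_cls order is the documented tie order
}

#' TE context of an insertion's flanks and breakpoints
#'
#' The insertion is extended by `te_flank` reference bases on each side
#' (clipped at chromosome ends) and the extended sequence re-annotated.
#' `flanked_*` flags a TE hit overlapping the flank; `crossing_*` flags a
#' single TE hit covering at least one base on both sides of the insertion
#' edge.
#'
#' @param insertion one-row data.frame with chrom, pos, seq.
#' @param genome named character vector (the reference).
#' @param repeat_library data.frame with name, te_class, seq.
#' @param params [pipeline_params()].
#' @return list of four logical flags.
#' @export
flank_te_analysis <- function(insertion, genome, repeat_library,
                              params = pipeline_params()) {
  chrom <- genome[[insertion$chrom]]
  pos <- insertion$pos
  fl <- params$te_flank
  left <- substr(chrom, max(1L, pos - fl + 1L), pos)
  right <- substr(chrom, pos + 1L, min(nchar(chrom), pos + fl))
  ext <- paste0(left, insertion$seq, right)
  ann <- annotate_repeats(ext, repeat_library, params)
  hits <- ann$hits
  te <- hits[hits$label != "LOW_COMPLEXITY", , drop = FALSE]
  ledge <- nchar(left)
  redge <- nchar(left) + nchar(insertion$seq)
  list(
    flanked_left = any(te$start < ledge & te$end > 0),
    flanked_right = any(te$start < nchar(ext) & te$end > redge),
    crossing_left = any(te$start < ledge & te$end > ledge),
    crossing_right = any(te$start < redge & te$end > redge)
  )
}

#' Repeat composition summary of a call set
#'
#' @param annotations list of [annotate_repeats()] results, one per call.
#' @param major optional precomputed major-TE labels (recomputed otherwise).
#' @return list with `class_fraction` (per-class bp fraction of total bp,
#'   including LOW_COMPLEXITY and the masked total), and `size_bins`
#'   (major-TE tallies for size classes <200, 200--1000, >1000 bp).
#' @export
repeat_summary <- function(annotations, major = NULL) {
  classes <- c("LINE", "SINE", "LTR", "DNA", "LOW_COMPLEXITY")
  if (!length(annotations)) {
    return(list(
      class_fraction = stats::setNames(rep(0, length(classes) + 1L),
                                       c(classes, "masked_total")),
      size_bins = matrix(0L, nrow = 3, ncol = 6,
                         dimnames = list(c("<200", "200-1000", ">1000"),
                                         c("LINE", "SINE", "LTR", "DNA",
                                           "NONE", "total")))))
  }
  lens <- vapply(annotations, `[[`, numeric(1), "length")
  bp <- sapply(annotations, `[[`, "class_bp")   # classes x calls
  total <- sum(lens)
  class_fraction <- rowSums(bp) / total
  class_fraction <- c(class_fraction, masked_total = sum(bp) / total)
  if (is.null(major)) major <- vapply(annotations, major_te, character(1))
  bin <- cut(lens, c(-Inf, 199.5, 1000.5, Inf),
             labels = c("<200", "200-1000", ">1000"))
  tab <- table(bin, factor(major, levels = c("LINE", "SINE", "LTR", "DNA",
                                             "NONE")))
  size_bins <- cbind(unclass(tab), total = rowSums(tab))
  list(class_fraction = class_fraction, size_bins = size_bins)
}
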