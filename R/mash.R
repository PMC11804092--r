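# MinHash sketching and the Mash distance, used to order assemblies before
# incremental graph augmentation.

#' Bottom-s MinHash sketch of a sequence
#'
#' Canonical k-mers are hashed to 53-bit values (so sketches are exact R
#' doubles) and the `s` smallest distinct hashes are kept.
#'
#' @param seq a single nucleotide sequence.
#' @param k k-mer size (default 21).
#' @param s sketch size (default 1000).
#' @return An object of class `minhash_sketch` (sorted hash vector with
#'   attributes `k` and `s`).
#' @export
mash_sketch <- function(seq, k = 21L, s = 1000L) {
  stopifnot(is.character(seq), length(seq) == 1)
  h <- cpp_minhash(seq, as.integer(k), as.integer(s))
  structure(h, k = as.integer(k), s = as.integer(s), class = "minhash_sketch")
}

#' Mash distance between two sketches
#'
#' The Jaccard index is estimated over the `s` smallest hashes of the sketch
#' union, then converted with `d = -(1/k) * log(2J / (1 + J))`. A Jaccard of
#' zero maps to the capped distance 1.
#'
#' @param a,b sketches from [mash_sketch()] built with the same `k` and `s`.
#' @return Numeric distance in `[0, 1]`.
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "minhash_sketch"), inherits(b, "minhash_sketch"))
  if (attr(a, "k") != attr(b, "k")) stop("sketches built with different k")
  if (attr(a, "s") != attr(b, "s")) stop("sketches built with different s")
  s <- attr(a, "s")
  u <- sort(unique(c(unclass(a), unclass(b))))
  if (length(u) > s) u <- u[seq_len(s)]
  shared <- sum(u %in% a & u %in% b)
  J <- if (length(u)) shared / length(u) else 0
  mash_from_jaccard(J, attr(a, "k"))
}

# distance formula shared with the exact-Jaccard oracle used in tests
mash_from_jaccard <- function(J, k) {
  if (J <= 0) return(1.0)
  d <- -(1 / k) * log(2 * J / (1 + J))
  min(d, 1.0)
}
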