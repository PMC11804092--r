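# Independent oracles used across the suite. These re-derive expected values
# from definitions (full dynamic programming, direct scoring, exact k-mer
# sets, brute-force search) without touching the engine's code paths.

rand_seq <- function(n, prob = NULL) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# substitution-only mutation used to construct diverged copies
mutate_at_rate <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# --- full global alignment oracle (Biostrings): same scoring scheme,
# gap of length L costs 6 + (L - 1)
nw_submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -4,
                                                      baseOnly = TRUE)
oracle_global_identity <- function(q, t) {
  a <- Biostrings::pairwiseAlignment(q, t, type = "global",
                                     substitutionMatrix = nw_submat,
                                     gapOpening = 5, gapExtension = 1)
  c(identity = Biostrings::nmatch(a) / Biostrings::nchar(a),
    columns = Biostrings::nchar(a),
    matches = Biostrings::nmatch(a),
    score = Biostrings::score(a))
}

oracle_local_score <- function(q, t) {
  a <- Biostrings::pairwiseAlignment(q, t, type = "local",
                                     substitutionMatrix = nw_submat,
                                     gapOpening = 5, gapExtension = 1)
  Biostrings::score(a)
}

# --- exact canonical k-mer Jaccard (no sketching)
oracle_kmer_set <- function(s, k = 21) {
  n <- nchar(s)
  if (n < k) return(character(0))
  subs <- substring(s, 1:(n - k + 1), k:n)
  subs <- subs[!grepl("N", subs, fixed = TRUE)]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(subs)))
  unique(pmin(subs, rc))
}
oracle_exact_jaccard <- function(s1, s2, k = 21) {
  a <- oracle_kmer_set(s1, k)
  b <- oracle_kmer_set(s2, k)
  length(intersect(a, b)) / length(union(a, b))
}

# --- DUST oracles -----------------------------------------------------------
# direct scoring of one interval from scratch (definition)
dust_interval_score <- function(tri, i, j) {
  w <- j - i + 1
  if (w < 3) return(0)
  tt <- tri[i:(j - 2)]
  tt <- tt[!is.na(tt)]
  if (!length(tt)) return(0)
  ct <- table(tt)
  sum(ct * (ct - 1) / 2) / (w - 2)
}

dust_triplets <- function(seq) {
  b <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T")) - 1
  n <- length(b)
  if (n < 3) return(integer(0))
  v <- b[1:(n - 2)] * 16 + b[2:(n - 1)] * 4 + b[3:n]
  v  # NA where any base was not ACGT
}

# score every interval of length <= W, then apply the perfect-interval
# definition via the max-over-subintervals recurrence; returns merged maximal
# perfect intervals as a 2-column matrix (0-based half-open)
oracle_sdust <- function(seq, W = 64, thr = 2) {
  n <- nchar(seq)
  if (n < 3) return(matrix(numeric(0), ncol = 2))
  tri <- dust_triplets(seq)
  maxlen <- min(W, n)
  S <- matrix(0, nrow = n, ncol = maxlen)   # S[i, len], 1-based start
  for (i in 1:n) {
    cnt <- integer(64)
    raw <- 0
    lim <- min(maxlen, n - i + 1)
    len <- 3
    while (len <= lim) {
      t <- tri[i + len - 3]
      if (!is.na(t)) { raw <- raw + cnt[t + 1]; cnt[t + 1] <- cnt[t + 1] + 1 }
      S[i, len] <- raw / (len - 2)
      len <- len + 1
    }
  }
  perfect <- NULL
  Mprev <- rep(0, n)
  for (len in 3:maxlen) {
    idx <- 1:(n - len + 1)
    if (length(idx) < 1 || n - len + 1 < 1) break
    msub <- if (len == 3) rep(0, length(idx)) else
      pmax(Mprev[idx], Mprev[idx + 1])
    s <- S[idx, len]
    hit <- which(s > thr & s >= msub)
    if (length(hit)) {
      perfect <- rbind(perfect, cbind(idx[hit] - 1, idx[hit] - 1 + len))
    }
    Mcur <- rep(0, n)
    Mcur[idx] <- pmax(s, msub)
    Mprev <- Mcur
  }
  if (is.null(perfect)) return(matrix(numeric(0), ncol = 2))
  perfect <- perfect[order(perfect[, 1], -perfect[, 2]), , drop = FALSE]
  keep <- NULL; maxe <- -1
  for (r in seq_len(nrow(perfect))) {
    if (perfect[r, 2] > maxe) { keep <- rbind(keep, perfect[r, ]); maxe <- perfect[r, 2] }
  }
  out <- keep[1, , drop = FALSE]
  for (r in seq_len(nrow(keep))[-1]) {
    if (keep[r, 1] < out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], keep[r, 2])
    } else out <- rbind(out, keep[r, ])
  }
  unname(out)
}

# fully brute-force variant (every subinterval rescored from scratch);
# only feasible for short strings
oracle_sdust_brute <- function(seq, W = 64, thr = 2) {
  n <- nchar(seq)
  if (n < 3) return(matrix(numeric(0), ncol = 2))
  tri <- dust_triplets(seq)
  perfect <- NULL
  for (i in 1:(n - 2)) {
    for (len in 3:min(W, n - i + 1)) {
      j <- i + len - 1
      s <- dust_interval_score(tri, i, j)
      if (s <= thr) next
      ok <- TRUE
      for (ii in i:(j - 2)) {
        for (jj in (ii + 2):j) {
          if (ii == i && jj == j) next
          if (dust_interval_score(tri, ii, jj) > s) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) perfect <- rbind(perfect, c(i - 1, j))
    }
  }
  if (is.null(perfect)) return(matrix(numeric(0), ncol = 2))
  perfect <- perfect[order(perfect[, 1], -perfect[, 2]), , drop = FALSE]
  keep <- NULL; maxe <- -1
  for (r in seq_len(nrow(perfect))) {
    if (perfect[r, 2] > maxe) { keep <- rbind(keep, perfect[r, ]); maxe <- perfect[r, 2] }
  }
  out <- keep[1, , drop = FALSE]
  for (r in seq_len(nrow(keep))[-1]) {
    if (keep[r, 1] < out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], keep[r, 2])
    } else out <- rbind(out, keep[r, ])
  }
  unname(out)
}

sdust_as_matrix <- function(df) {
  m <- matrix(as.numeric(unlist(df)), ncol = 2)
  unname(m)
}

# --- brute-force best bidirectional hits over full-DP local scores ----------
oracle_bbh <- function(setA, setB, identity = 0.95, coverage = 0.95) {
  score_tab <- function(qs, ts) {
    out <- matrix(NA_real_, length(qs), length(ts),
                  dimnames = list(names(qs), names(ts)))
    for (i in seq_along(qs)) {
      for (j in seq_along(ts)) {
        a <- Biostrings::pairwiseAlignment(qs[[i]], ts[[j]], type = "local",
                                           substitutionMatrix = nw_submat,
                                           gapOpening = 5, gapExtension = 1)
        id <- Biostrings::nmatch(a) / Biostrings::nchar(a)
        cov <- (Biostrings::width(Biostrings::pattern(a))) / nchar(qs[[i]])
        out[i, j] <- if (id >= identity && cov >= coverage)
          Biostrings::score(a) else NA_real_
      }
    }
    out
  }
  ab <- score_tab(setA, setB)
  ba <- score_tab(setB, setA)
  bestA <- apply(ab, 1, function(x) if (all(is.na(x))) NA_character_ else
    colnames(ab)[which.max(x)])
  bestB <- apply(ba, 1, function(x) if (all(is.na(x))) NA_character_ else
    colnames(ba)[which.max(x)])
  keep <- !is.na(bestA) & !is.na(bestB[bestA]) & bestB[bestA] == names(setA)
  data.frame(a = names(setA)[keep], b = unname(bestA[keep]),
             stringsAsFactors = FALSE)
}
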