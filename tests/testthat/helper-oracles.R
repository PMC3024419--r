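# Independent brute-force oracles used across tests. These deliberately use
# naive per-position algorithms, distinct from the package's IRanges /
# seed-and-extend implementations.

# random DNA string
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

base_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# positions (1..L) spanned by a possibly wrapping interval, by walking
walk_positions <- function(start, end, L) {
  pos <- start
  out <- start
  while (pos != end) {
    pos <- if (pos == L) 1L else pos + 1L
    out <- c(out, pos)
  }
  out
}

# O(L^2) enumeration of all shared W-mers (direct + inverted), canonical form
oracle_seed_pairs <- function(g, W) {
  L <- g$length
  n <- L - W + 1L
  words <- substring(g$seq, 1:n, W:L)
  rcwords <- vapply(words, base_revcomp, character(1), USE.NAMES = FALSE)
  direct <- list()
  inv <- list()
  for (i in 1:n) {
    for (j in 1:n) {
      if (j > i && words[i] == words[j])
        direct[[length(direct) + 1L]] <- c(i, j)
      if (words[i] == rcwords[j] && i != j)
        inv[[length(inv) + 1L]] <- c(min(i, j), max(i, j))
    }
  }
  d <- if (length(direct)) unique(do.call(rbind, direct)) else
    matrix(integer(), 0, 2)
  iv <- if (length(inv)) unique(do.call(rbind, inv)) else
    matrix(integer(), 0, 2)
  out <- data.frame(pos1 = c(d[, 1], iv[, 1]), pos2 = c(d[, 2], iv[, 2]),
                    strand = rep(c("+", "-"), c(nrow(d), nrow(iv))))
  out[order(out$strand == "-", out$pos1, out$pos2), , drop = FALSE]
}

# per-position bitmap oracle for coverage_profile
oracle_coverage <- function(hits, L, threshold) {
  short <- logical(L)
  large <- logical(L)
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      pos <- c(walk_positions(hits$start1[i], hits$end1[i], L),
               walk_positions(hits$start2[i], hits$end2[i], L))
      if (hits$length[i] < threshold) short[pos] <- TRUE
      else large[pos] <- TRUE
    }
  }
  list(covered_short_only = sum(short & !large),
       covered_large_only = sum(large & !short),
       covered_short_within_large = sum(short & large),
       non_repetitive = sum(!short & !large),
       percent_covered = 100 * sum(short | large) / L)
}

# a minimal hits data frame from raw coordinates
make_hits <- function(start1, end1, start2, end2,
                      orientation = "direct", length = NULL,
                      identity = 100, score = NULL, evalue = 0) {
  n <- base::length(start1)
  if (is.null(length)) length <- end1 - start1 + 1L
  if (is.null(score)) score <- length
  h <- data.frame(start1 = as.integer(start1), end1 = as.integer(end1),
                  start2 = as.integer(start2), end2 = as.integer(end2),
                  orientation = rep_len(orientation, n),
                  length = rep_len(as.integer(length), n),
                  identity = rep_len(identity, n),
                  score = rep_len(score, n),
                  evalue = rep_len(evalue, n))
  class(h) <- c("repeat_hits", "data.frame")
  h
}

# genome with k identical planted copies of one word, distinct guard contexts
# (pairwise-distant 3-mers on both sides) so every pairwise alignment has the
# exact planted coordinates
plant_family <- function(k, copy_len = 60, L = 4000, seed = 99) {
  set.seed(seed)
  stopifnot(k <= 6)
  guards <- c("AAA", "CCC", "GGG", "TTT", "ACG", "CAT")
  v <- strsplit(rand_dna(L), "")[[1]]
  copy <- strsplit(rand_dna(copy_len), "")[[1]]
  starts <- round(seq(300, L - 300 - copy_len, length.out = k))
  for (i in seq_len(k)) {
    s <- starts[i]
    v[(s - 3):(s - 1)] <- strsplit(guards[i], "")[[1]]
    v[s:(s + copy_len - 1)] <- copy
    v[(s + copy_len):(s + copy_len + 2)] <-
      rev(strsplit(guards[i], "")[[1]])
  }
  list(genome = circular_genome(paste(v, collapse = ""), id = "family"),
       starts = starts, copy_len = copy_len)
}
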