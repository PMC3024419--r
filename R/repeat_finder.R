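## Dispersed-repeat discovery by genome self-alignment: exact word seeding,
## banded affine-gap X-drop extension (src/xdrop.cpp), Karlin-Altschul
## E-value filtering, and canonicalisation of mirror-duplicate hits.

#' Alignment parameters for repeat discovery
#'
#' Defaults follow the WU-BLAST-style settings used for organelle-genome
#' self-comparison: match +1, mismatch -3, gap open 3, gap extend 3, word
#' size 7, and an E-value cutoff of 1. A gap of length g costs `Q + g * R`.
#' `lambda` and `K` are the Karlin-Altschul parameters; the defaults are the
#' standard ungapped values for the +1/-3 scoring scheme.
#'
#' @param word_size exact-match seed length W (nt), >= 4.
#' @param match match score M (> 0).
#' @param mismatch mismatch score N (< 0).
#' @param gap_open gap opening penalty Q (>= 0).
#' @param gap_extend per-position gap extension penalty R (>= 0).
#' @param lambda Karlin-Altschul lambda (nats per score unit, > 0).
#' @param K Karlin-Altschul K (> 0).
#' @param e_cutoff E-value cutoff; hits with E <= cutoff are kept.
#' @param x_drop X-drop termination threshold for extension (score units).
#' @param max_extend cap on extension length per direction (nt).
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(word_size = 7L, match = 1L, mismatch = -3L,
                             gap_open = 3L, gap_extend = 3L,
                             lambda = 1.374, K = 0.711, e_cutoff = 1,
                             x_drop = 20L, max_extend = 10000L) {
  stopifnot(word_size >= 4, match > 0, mismatch < 0, gap_open >= 0,
            gap_extend >= 0, lambda > 0, K > 0, e_cutoff > 0, x_drop > 0)
  structure(list(word_size = as.integer(word_size), match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), lambda = lambda, K = K,
                 e_cutoff = e_cutoff, x_drop = as.integer(x_drop),
                 max_extend = as.integer(max_extend)),
            class = "alignment_params")
}

## integer-encode a DNA string: A=0 C=1 G=2 T=3 N=4
.encode_dna <- function(seq) {
  code <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T", "N")) - 1L
  if (anyNA(code)) stop("sequence contains characters outside {A,C,G,T,N}")
  code
}

.empty_hits <- function() {
  out <- data.frame(start1 = integer(), end1 = integer(), start2 = integer(),
                    end2 = integer(), orientation = character(),
                    length = integer(), identity = numeric(),
                    score = integer(), evalue = numeric())
  class(out) <- c("repeat_hits", "data.frame")
  out
}

#' Exact word seeds shared between a genome and itself
#'
#' Enumerates all exact W-mer matches between the genome and itself, on the
#' forward-forward (`direct`) and forward-reverse-complement (`inverted`)
#' strand combinations. The trivial identity diagonal (a position paired with
#' its own footprint) is excluded, and each unordered pair is reported once,
#' canonically with `pos1 <= pos2`. `pos2` is always the plus-strand start of
#' the second footprint. Words containing `N` are skipped.
#'
#' @param g a [circular_genome()].
#' @param W word size (nt).
#' @return A data frame with columns `pos1`, `pos2`, `strand`
#'   (`"+"` direct, `"-"` inverted).
#' @export
seed_matches <- function(g, W) {
  W <- as.integer(W)
  L <- g$length
  if (L < W) stop("genome shorter than the word size")
  n <- L - W + 1L
  starts <- seq_len(n)
  words <- substring(g$seq, starts, starts + W - 1L)
  ok <- !grepl("N", words, fixed = TRUE)
  ## direct: all unordered position pairs sharing a word
  fwd_idx <- split(starts[ok], words[ok])
  fwd_idx <- fwd_idx[lengths(fwd_idx) > 1L]
  direct <- if (length(fwd_idx)) {
    pr <- lapply(fwd_idx, function(p) {
      cb <- utils::combn(p, 2L)
      cbind(cb[1L, ], cb[2L, ])
    })
    do.call(rbind, pr)
  } else matrix(integer(), 0L, 2L)
  ## inverted: words of the forward strand matched against words of the
  ## reverse complement; rc position p has plus-strand footprint starting
  ## at L - p - W + 2
  rcseq <- revcomp(g$seq)
  rcwords <- substring(rcseq, starts, starts + W - 1L)
  rcok <- !grepl("N", rcwords, fixed = TRUE)
  fw_by <- split(starts[ok], words[ok])
  rc_by <- split(starts[rcok], rcwords[rcok])
  shared <- intersect(names(fw_by), names(rc_by))
  inv <- if (length(shared)) {
    pr <- lapply(shared, function(wd) {
      i <- fw_by[[wd]]
      p <- rc_by[[wd]]
      cbind(rep(i, each = length(p)), rep(L - p - W + 2L, length(i)))
    })
    do.call(rbind, pr)
  } else matrix(integer(), 0L, 2L)
  if (nrow(inv)) {
    inv <- inv[inv[, 1L] != inv[, 2L], , drop = FALSE]  # palindromic self
    inv <- cbind(pmin(inv[, 1L], inv[, 2L]), pmax(inv[, 1L], inv[, 2L]))
    inv <- unique(inv)
  }
  out <- data.frame(
    pos1 = c(direct[, 1L], inv[, 1L]),
    pos2 = c(direct[, 2L], inv[, 2L]),
    strand = rep(c("+", "-"), c(nrow(direct), nrow(inv))))
  out[order(out$strand == "-", out$pos1, out$pos2), , drop = FALSE]
}

## collapse seeds lying on the same alignment diagonal into runs and return
## one representative seed per run. Works in (pos1, partner-coordinate) space
## where the partner coordinate is colinear with pos1 along a repeat.
.collapse_seed_runs <- function(pos1, pos2, W, max_gap = NULL) {
  if (is.null(max_gap)) max_gap <- W
  if (length(pos1) == 0L) return(integer())
  d <- pos2 - pos1
  o <- order(d, pos1)
  newrun <- c(TRUE, diff(d[o]) != 0L | diff(pos1[o]) > max_gap)
  o[newrun]
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` in a comparison of sequences of lengths
#' `m` and `n`.
#'
#' @param score alignment score(s), >= 0.
#' @param m,n sequence lengths (nt); for a genome self-comparison both equal
#'   the genome length.
#' @param p an [alignment_params()] supplying `lambda` and `K`.
#' @return Numeric E-value(s).
#' @examples
#' p <- alignment_params()
#' evalue(20, 401262, 401262, p)
#' @export
evalue <- function(score, m, n, p) {
  if (any(score < 0)) stop("score must be >= 0")
  if (m <= 0 || n <= 0) stop("m and n must be positive")
  p$K * m * n * exp(-p$lambda * score)
}

## core extension of a batch of seeds; seeds as data.frame(pos1, pos2, strand)
## with pos2 the plus-strand footprint start. Returns raw hit rows.
.extend_seeds <- function(g, seeds, p) {
  L <- g$length
  W <- p$word_size
  enc <- .encode_dna(g$seq)
  hit_rows <- list()
  for (str in c("+", "-")) {
    sd <- seeds[seeds$strand == str, , drop = FALSE]
    if (nrow(sd) == 0L) next
    if (str == "+") {
      s2 <- enc
      j0 <- sd$pos2
    } else {
      s2 <- .encode_dna(revcomp(g$seq))
      ## rc coordinate of the partner footprint start
      j0 <- L - sd$pos2 - W + 2L
    }
    keep <- .collapse_seed_runs(sd$pos1, j0, W)
    res <- xdrop_batch_cpp(enc, s2, sd$pos1[keep], j0[keep], W,
                           p$match, p$mismatch, p$gap_open, p$gap_extend,
                           p$x_drop, p$max_extend)
    res <- as.data.frame(res)
    if (str == "-") {
      js <- res$start2; je <- res$end2
      res$start2 <- L - je + 1L
      res$end2 <- L - js + 1L
    }
    res$orientation <- if (str == "+") "direct" else "inverted"
    hit_rows[[str]] <- res
  }
  if (length(hit_rows) == 0L) return(NULL)
  do.call(rbind, hit_rows)
}

.finalize_hits <- function(raw, L, p) {
  if (is.null(raw) || nrow(raw) == 0L) return(.empty_hits())
  hits <- data.frame(
    start1 = raw$start1, end1 = raw$end1, start2 = raw$start2,
    end2 = raw$end2, orientation = raw$orientation, length = raw$columns,
    identity = 100 * raw$matches / raw$columns, score = raw$score,
    evalue = evalue(raw$score, L, L, p))
  class(hits) <- c("repeat_hits", "data.frame")
  filter_and_canonicalize(hits, p)
}

#' Extend a single seed into a local alignment hit
#'
#' Gapped extension in both directions from an exact word seed, maximising
#' the score under the affine scheme of `p`, with X-drop termination.
#'
#' @param g a [circular_genome()].
#' @param seed a single row of [seed_matches()] output (or a list with
#'   `pos1`, `pos2`, `strand`).
#' @param p an [alignment_params()].
#' @return A one-row `repeat_hits` data frame (zero rows if the hit fails
#'   the E-value cutoff).
#' @export
extend_hit <- function(g, seed, p = alignment_params()) {
  seeds <- data.frame(pos1 = as.integer(seed$pos1),
                      pos2 = as.integer(seed$pos2),
                      strand = as.character(seed$strand))
  .finalize_hits(.extend_seeds(g, seeds, p), g$length, p)
}

#' Filter and canonicalise repeat hits
#'
#' Keeps hits with `evalue <= e_cutoff`, removes self hits (a copy paired
#' with itself, including the full-length identity alignment), merges mirror
#' duplicates (a hit reported as A-B and B-A counts once) by enforcing
#' `start1 <= start2`, and sorts by `start1`.
#'
#' @param hits a `repeat_hits` data frame.
#' @param p an [alignment_params()] supplying `e_cutoff`.
#' @return The filtered, canonically ordered `repeat_hits` data frame.
#' @export
filter_and_canonicalize <- function(hits, p = alignment_params()) {
  if (nrow(hits) == 0L) return(.empty_hits())
  swap <- hits$start2 < hits$start1 |
    (hits$start2 == hits$start1 & hits$end2 < hits$end1)
  tmp_s <- hits$start1[swap]; tmp_e <- hits$end1[swap]
  hits$start1[swap] <- hits$start2[swap]
  hits$end1[swap] <- hits$end2[swap]
  hits$start2[swap] <- tmp_s
  hits$end2[swap] <- tmp_e
  self <- hits$start1 == hits$start2 & hits$end1 == hits$end2
  hits <- hits[!self & hits$evalue <= p$e_cutoff, , drop = FALSE]
  hits <- unique(hits)
  hits <- hits[order(hits$start1, hits$start2, hits$end1), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("repeat_hits", "data.frame")
  hits
}

## circular containment: is iv (s,e) contained in IV (S,E) on a circle of
## length L? Both may wrap (start > end).
.circ_contains <- function(S, E, s, e, L) {
  lenIV <- (E - S + 1L) + if (S > E) L else 0L
  leniv <- (e - s + 1L) + if (s > e) L else 0L
  off <- (s - S) %% L
  off + leniv <= lenIV
}

## drop hits redundant with a higher-scoring hit of the same orientation:
## either both copies contained in the other's copies (truncated re-findings
## of origin-spanning hits), or both copies overlapping on essentially the
## same alignment diagonal (lower-scoring gapped variants of one copy pair,
## reached from off-diagonal chance seeds). Greedy by score, so the
## maximal-scoring alignment of a region always survives. Tandem-array hits
## live on well-separated diagonals and are untouched.
.drop_contained <- function(hits, L, diag_tol = 8L) {
  n <- nrow(hits)
  if (n <= 1L) return(hits)
  # alignment diagonal: constant along a direct pair (offset between copies)
  # and along an inverted pair (sum of forward start and partner end)
  diag_of <- function(i) {
    if (hits$orientation[i] == "direct")
      (hits$start2[i] - hits$start1[i]) %% L
    else (hits$start1[i] + hits$end2[i]) %% L
  }
  redundant_with <- function(i, j) {
    if (hits$orientation[i] != hits$orientation[j]) return(FALSE)
    pair_rel <- function(sA, eA, sB, eB) {
      # containment of (sB, eB) in (sA, eA), or mere overlap
      if (.circ_contains(sA, eA, sB, eB, L)) "contains"
      else if (.circ_overlap(sA, eA, sB, eB, L)) "overlaps"
      else "disjoint"
    }
    for (swap in c(FALSE, TRUE)) {
      s1 <- if (swap) hits$start2[i] else hits$start1[i]
      e1 <- if (swap) hits$end2[i] else hits$end1[i]
      s2 <- if (swap) hits$start1[i] else hits$start2[i]
      e2 <- if (swap) hits$end1[i] else hits$end2[i]
      r1 <- pair_rel(hits$start1[j], hits$end1[j], s1, e1)
      r2 <- pair_rel(hits$start2[j], hits$end2[j], s2, e2)
      if (r1 == "contains" && r2 == "contains") return(TRUE)
      if (r1 != "disjoint" && r2 != "disjoint" && !swap) {
        d <- abs(diag_of(i) - diag_of(j))
        if (min(d, L - d) <= diag_tol) return(TRUE)
      }
    }
    FALSE
  }
  ord <- order(-hits$score, hits$start1, hits$start2)
  kept <- integer()
  for (i in ord) {
    if (!any(vapply(kept, function(j) redundant_with(i, j), logical(1))))
      kept <- c(kept, i)
  }
  hits[sort(kept), , drop = FALSE]
}

#' Discover dispersed repeats by genome self-alignment
#'
#' Runs the full seed-extend-filter pipeline: exact word seeding
#' ([seed_matches()]), gapped X-drop extension, E-value filtering and
#' canonicalisation ([filter_and_canonicalize()]). For circular genomes the
#' search runs on the doubled genome (the sequence concatenated with itself,
#' excluding the trivial offset-L self diagonal), so every repeat -- in
#' particular one spanning the origin -- appears intact in at least one
#' image; coordinates are mapped back modulo L (wrapping copies get
#' `start > end`) and image duplicates removed. E-values are always computed
#' against the original genome length.
#'
#' @param g a [circular_genome()].
#' @param p an [alignment_params()].
#' @return A `repeat_hits` data frame: one canonical hit per row with columns
#'   `start1`, `end1`, `start2`, `end2`, `orientation` (direct/inverted),
#'   `length` (alignment columns), `identity` (percent), `score`, `evalue`.
#' @export
find_repeats <- function(g, p = alignment_params()) {
  L <- g$length
  if (g$circular) {
    gd <- circular_genome(paste0(g$seq, g$seq), id = g$id, circular = FALSE)
    seeds <- seed_matches(gd, p$word_size)
    seeds <- seeds[!(seeds$strand == "+" & seeds$pos2 - seeds$pos1 == L), ,
                   drop = FALSE]
    raw <- .extend_seeds(gd, seeds, p)
    if (!is.null(raw))
      for (col in c("start1", "end1", "start2", "end2"))
        raw[[col]] <- .wrap_pos(raw[[col]], L)
    hits <- .finalize_hits(raw, L, p)
  } else {
    hits <- .finalize_hits(.extend_seeds(g, seed_matches(g, p$word_size), p),
                           L, p)
  }
  hits <- .drop_contained(hits, L)
  rownames(hits) <- NULL
  class(hits) <- c("repeat_hits", "data.frame")
  hits
}

#' @export
print.repeat_hits <- function(x, ...) {
  cat(sprintf("<repeat_hits> %d canonical hit(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("  ... and", nrow(x) - 10L, "more\n")
  invisible(x)
}
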