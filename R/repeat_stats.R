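## Non-redundant repeat-content statistics: per-position coverage classes
## (short / large / short-within-large), unique begin-end coordinate counts,
## size-class bounds for repeat families, and repeat-length histograms.

## IRanges of the linear pieces covered by one hit copy (wrap split in two)
.copy_ranges <- function(start, end, L) {
  pieces <- mapply(function(s, e) .iv_pieces(s, e, L), start, end,
                   SIMPLIFY = FALSE)
  m <- do.call(rbind, pieces)
  if (is.null(m)) IRanges::IRanges()
  else IRanges::IRanges(start = m[, "start"], end = m[, "end"])
}

## reduced position set (IRanges) covered by both copies of the given hits
.hits_ranges <- function(hits, L) {
  IRanges::reduce(c(.copy_ranges(hits$start1, hits$end1, L),
                    .copy_ranges(hits$start2, hits$end2, L)))
}

#' Non-redundant repeat coverage profile
#'
#' Marks every genomic position covered by at least one repeat copy, counting
#' each position once regardless of how many repeats cover it, and classifies
#' positions as covered by short repeats only (length below `size_threshold`),
#' by large repeats only, or by both (short repeats partly or entirely
#' contained within large ones). The four classes (including non-repetitive)
#' partition the genome exactly.
#'
#' @param repeats a `repeat_hits` data frame (see [find_repeats()]).
#' @param L genome length (nt).
#' @param size_threshold length (nt) separating short from large repeats;
#'   a hit contributes to the class of its own alignment length.
#' @return A list of class `repeat_coverage_profile` with fields
#'   `genome_length`, `covered_short_only`, `covered_large_only`,
#'   `covered_short_within_large`, `non_repetitive`, `n_hits_short`,
#'   `n_hits_large`, `percent_covered`.
#' @export
coverage_profile <- function(repeats, L, size_threshold = 1000L) {
  if (size_threshold <= 0) stop("size_threshold must be positive")
  L <- as.integer(L)
  if (nrow(repeats)) {
    bad <- repeats$start1 > L | repeats$end1 > L |
      repeats$start2 > L | repeats$end2 > L
    if (any(bad)) stop("repeat interval outside [1, L]")
    ## a hit listed twice is one repeat: the profile (and its hit counts)
    ## must be invariant under duplication of the input list
    repeats <- unique(repeats[, c("start1", "end1", "start2", "end2",
                                  "length"), drop = FALSE])
  }
  short <- repeats[repeats$length < size_threshold, , drop = FALSE]
  large <- repeats[repeats$length >= size_threshold, , drop = FALSE]
  S <- .hits_ranges(short, L)
  B <- .hits_ranges(large, L)
  both <- IRanges::intersect(S, B)
  s_only <- sum(IRanges::width(IRanges::setdiff(S, B)))
  l_only <- sum(IRanges::width(IRanges::setdiff(B, S)))
  within <- sum(IRanges::width(both))
  non_rep <- L - s_only - l_only - within
  structure(list(
    genome_length = L,
    covered_short_only = as.integer(s_only),
    covered_large_only = as.integer(l_only),
    covered_short_within_large = as.integer(within),
    non_repetitive = as.integer(non_rep),
    n_hits_short = nrow(short),
    n_hits_large = nrow(large),
    percent_covered = 100 * (L - non_rep) / L
  ), class = "repeat_coverage_profile")
}

#' @export
print.repeat_coverage_profile <- function(x, ...) {
  cat(sprintf(
    paste0("<repeat_coverage_profile> L = %s nt; %.2f%% covered\n",
           "  short-only %d | large-only %d | short-within-large %d |",
           " non-repetitive %d\n  hits: %d short, %d large\n"),
    format(x$genome_length, big.mark = ","), x$percent_covered,
    x$covered_short_only, x$covered_large_only,
    x$covered_short_within_large, x$non_repetitive,
    x$n_hits_short, x$n_hits_large))
  invisible(x)
}

#' Number of unique begin-end hit coordinates
#'
#' Counts the distinct `(start, end)` coordinate pairs over all hit copies
#' (both copies of every hit contribute), the repeat-number estimate used for
#' genome-scale repeat surveys. For imperfect multi-copy families this
#' over-estimates the true copy number (see [family_coordinate_bounds()]).
#'
#' @param hits a `repeat_hits` data frame.
#' @return Integer count of distinct coordinates.
#' @export
count_unique_coordinates <- function(hits) {
  if (nrow(hits) == 0L) return(0L)
  coords <- rbind(cbind(hits$start1, hits$end1),
                  cbind(hits$start2, hits$end2))
  nrow(unique(coords))
}

#' Bounds on unique coordinates for a k-copy repeat family
#'
#' For a family of `k` repeat copies, every unordered copy pair yields one
#' pairwise local alignment with one begin-end coordinate on each copy. The
#' bounds are derived by enumerating all pairs: the minimum (a perfect
#' family, every alignment on a copy has identical coordinates) and the
#' maximum (imperfect, variably sized copies, every alignment coordinate
#' distinct).
#'
#' @param k number of copies (>= 2).
#' @return Named integer vector `c(min = , max = )`; for `k = 6` this is
#'   `(6, 30)`.
#' @export
family_coordinate_bounds <- function(k) {
  if (k < 2) stop("a repeat family needs at least 2 copies")
  k <- as.integer(k)
  pairs <- utils::combn(k, 2L)
  ## minimum: each pair's alignment lies at the copy's single shared
  ## coordinate -> one coordinate per copy
  min_coords <- unique(c(pairs))
  ## maximum: each pair contributes a distinct coordinate on each of its two
  ## copies -> label coordinates by (pair, side) and count
  max_coords <- unique(c(paste0(seq_len(ncol(pairs)), "a"),
                         paste0(seq_len(ncol(pairs)), "b")))
  c(min = length(min_coords), max = length(max_coords))
}

#' Histogram of repeat lengths
#'
#' Bins the alignment lengths of canonical hits into intervals
#' `[i * bin_width, (i + 1) * bin_width)`.
#'
#' @param repeats a `repeat_hits` data frame.
#' @param bin_width bin width in nt (>= 1).
#' @return A data frame with columns `bin_start`, `bin_end` (half-open
#'   bounds) and `count`; total count equals the number of hits.
#' @export
length_histogram <- function(repeats, bin_width) {
  if (bin_width < 1) stop("bin_width must be >= 1")
  if (nrow(repeats) == 0L)
    return(data.frame(bin_start = integer(), bin_end = integer(),
                      count = integer()))
  bin <- repeats$length %/% bin_width
  tab <- table(factor(bin, levels = 0:max(bin)))
  data.frame(bin_start = as.integer(names(tab)) * bin_width,
             bin_end = (as.integer(names(tab)) + 1L) * bin_width,
             count = as.integer(tab))
}
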