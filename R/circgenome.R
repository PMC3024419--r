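## Core circular-genome types and coordinate primitives.
##
## Coordinates are 1-based inclusive throughout, matching how organelle
## genome papers print repeat tables; conversion to 0-based half-open
## happens only inside the BED writer. An interval with start > end wraps
## through the origin (position L is adjacent to position 1).

#' Construct a circular genome object
#'
#' A light container for a single DNA sequence with 1-based inclusive
#' circular coordinates. Input is case-normalised to uppercase; characters
#' outside `{A, C, G, T, N}` are rejected.
#'
#' @param seq DNA sequence as a single character string (or a
#'   [Biostrings::DNAString]).
#' @param id text label for the record.
#' @param circular logical; is the molecule circular? Circularity controls
#'   whether intervals may wrap through the origin.
#' @return An object of class `circular_genome`: a list with elements `id`,
#'   `seq` (uppercase character string), `length`, `circular`.
#' @examples
#' g <- circular_genome("acgtACGT", id = "toy")
#' g$length
#' @export
circular_genome <- function(seq, id = "genome", circular = TRUE) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || nchar(seq) < 1L)
    stop("'seq' must be a single non-empty string")
  bad <- gsub("[ACGTN]", "", seq)
  if (nchar(bad) > 0L)
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  structure(
    list(id = as.character(id), seq = seq, length = nchar(seq),
         circular = isTRUE(circular)),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %s nt, %s\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Construct a circular interval
#'
#' 1-based inclusive coordinates; `start > end` encodes an interval wrapping
#' through the origin. Negative coordinates are never used.
#'
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @return A list of class `circ_interval` with elements `start`, `end`,
#'   `strand`.
#' @export
circ_interval <- function(start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < 1L)
    stop("coordinates must be positive integers")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(start = start, end = end, strand = strand),
            class = "circ_interval")
}

.check_iv <- function(iv, L) {
  if (iv$start > L || iv$end > L)
    stop("coordinate outside [1, ", L, "]")
  invisible(TRUE)
}

#' Length of a circular interval
#'
#' @param iv a [circ_interval()].
#' @param L genome length in nt.
#' @return Interval length `end - start + 1`, plus `L` when the interval
#'   wraps the origin (`start > end`).
#' @examples
#' interval_length(circ_interval(120320, 120494), 401262)  # 175
#' @export
interval_length <- function(iv, L) {
  .check_iv(iv, L)
  len <- iv$end - iv$start + 1L
  if (iv$start > iv$end) len <- len + as.integer(L)
  len
}

## positions (1-based) spanned by an interval, in molecule order
.iv_positions <- function(iv, L) {
  if (iv$start <= iv$end) iv$start:iv$end
  else c(iv$start:L, 1:iv$end)
}

#' Reverse-complement a DNA string
#'
#' @param seq character string over `{A,C,G,T,N}`.
#' @return The reverse complement, as a character string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract a subsequence from a circular genome
#'
#' Wrapping intervals (`start > end`) are allowed only on circular genomes.
#' Minus-strand intervals return the reverse complement.
#'
#' @param g a [circular_genome()].
#' @param iv a [circ_interval()].
#' @return Character string of length [interval_length()].
#' @examples
#' g <- circular_genome("AACCGGTT")
#' extract_subseq(g, circ_interval(7, 2))  # "TTAA"
#' @export
extract_subseq <- function(g, iv) {
  .check_iv(iv, g$length)
  if (iv$start > iv$end && !g$circular)
    stop("wrapping interval requested on a non-circular genome")
  s <- if (iv$start <= iv$end) {
    substr(g$seq, iv$start, iv$end)
  } else {
    paste0(substr(g$seq, iv$start, g$length), substr(g$seq, 1L, iv$end))
  }
  if (iv$strand == "-") s <- revcomp(s)
  s
}

#' GC content of a DNA sequence
#'
#' `N` characters are excluded from both numerator and denominator.
#'
#' @param seq character string over `{A,C,G,T,N}`.
#' @return Percent GC, `100 * (G + C) / (A + C + G + T)`.
#' @examples
#' gc_content("GGGCCCAT")  # 75
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) < 1L) stop("empty sequence")
  n <- table(factor(strsplit(seq, "")[[1]], levels = c("A", "C", "G", "T", "N")))
  acgt <- sum(n[c("A", "C", "G", "T")])
  if (acgt == 0L) stop("sequence contains no A/C/G/T characters")
  100 * sum(n[c("G", "C")]) / acgt
}

#' Rotate a circular genome
#'
#' Returns the genome re-linearised so that original position `shift + 1`
#' becomes position 1.
#'
#' @param g a circular [circular_genome()].
#' @param shift number of positions to rotate by.
#' @return A rotated `circular_genome`.
#' @keywords internal
rotate_genome <- function(g, shift) {
  if (!g$circular) stop("cannot rotate a non-circular genome")
  shift <- as.integer(shift %% g$length)
  if (shift == 0L) return(g)
  seq <- paste0(substr(g$seq, shift + 1L, g$length), substr(g$seq, 1L, shift))
  circular_genome(seq, id = g$id, circular = TRUE)
}
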