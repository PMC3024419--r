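## Prediction of recombinant genome configurations across dispersed repeats,
## layout of the PCR assays that would detect them, and detection /
## quantification of chimeric reads supporting recombinant junctions.
##
## Geometry, for canonical copies with start1 < start2 on a circle
##   [A] R1 [B] R2 [D]   (A upstream of copy 1, B between copies, D after
##                        copy 2, wrapping back to A):
## a crossover between the copies of a direct repeat resolves the circle into
## two subgenomic circles, R+B and R+D+A, creating novel junctions labelled
## C->B (upstream flank of copy 2 joined through the repeat to the downstream
## flank of copy 1) and A->D. For an inverted repeat the segment B between
## the copies is reverse-complemented in place (genome size unchanged),
## creating junctions E->G and F->H.

.circ_shift <- function(pos, delta, L) ((pos - 1L + delta) %% L) + 1L

## circular interval strictly between two positions: (after, before)
.seg_iv <- function(from, to, strand, L) {
  circ_interval(.circ_shift(from, 0L, L), .circ_shift(to, 0L, L), strand)
}

## do two circular intervals share any position?
.circ_overlap <- function(s1, e1, s2, e2, L) {
  len1 <- (e1 - s1 + 1L) + if (s1 > e1) L else 0L
  len2 <- (e2 - s2 + 1L) + if (s2 > e2) L else 0L
  off <- (s2 - s1) %% L
  off < len1 || (L - off) %% L < len2
}

#' Predict recombinant configurations across a repeat
#'
#' For a direct repeat with canonical copy starts `s1 < s2`, crossover
#' resolves the genome into two subgenomic circles of sizes `s2 - s1` and
#' `L - (s2 - s1)`, each retaining one repeat copy. For an inverted repeat
#' the segment between the copies is reverse-complemented in place and the
#' genome size is unchanged. Each novel junction is returned as a sequence
#' containing one full repeat copy flanked by `flank` nt of unique sequence,
#' together with the genomic segments it was built from. Junction labels:
#' direct `"A->D"` / `"C->B"`, inverted `"E->G"` / `"F->H"` (flank letters
#' A/B upstream/downstream of copy 1, C/D of copy 2).
#'
#' The repeat copy appearing in each junction is the copy physically retained
#' in that product (copy 2 in the A->D subcircle, copy 1 in C->B); for
#' imperfect repeats the observed recombinant may instead carry the partner
#' copy's variant sites (crossover-position ambiguity), so the retained copy
#' index is surfaced as `repeat_copy` metadata on every junction.
#'
#' @param g a [circular_genome()].
#' @param r one repeat hit: a single-row `repeat_hits` data frame or a list
#'   with `start1`, `end1`, `start2`, `end2`, `orientation`.
#' @param flank flank length (nt) for junction sequences, >= 1.
#' @return A list of class `recombinant_config`: `repeat` (the input hit),
#'   `kind` (`"two_subcircles"` or `"inversion"`), `product_sizes`,
#'   `products` (named sequences), `junctions` (named list with `label`,
#'   `seq`, `left`, `rep`, `right` segment intervals, `repeat_copy`), and
#'   `flank`.
#' @export
predict_products <- function(g, r, flank) {
  L <- g$length
  flank <- as.integer(flank)
  if (flank < 1L) stop("flank must be >= 1")
  s1 <- as.integer(r$start1); e1 <- as.integer(r$end1)
  s2 <- as.integer(r$start2); e2 <- as.integer(r$end2)
  orientation <- as.character(r$orientation)
  if (.circ_overlap(s1, e1, s2, e2, L))
    stop("geometry error: repeat copies overlap")
  ## gaps between the copies (nt strictly between them, circularly)
  gapB <- (s2 - e1 - 1L) %% L    # segment B: copy1 -> copy2
  gapDA <- (s1 - e2 - 1L) %% L   # segment D..A: copy2 -> copy1
  if (flank > gapB || flank > gapDA)
    stop("flank error: flank overruns the partner repeat copy")
  seg <- function(iv) extract_subseq(g, iv)
  jun <- function(label, left, rep_iv, right, copy) {
    list(label = label, seq = paste0(seg(left), seg(rep_iv), seg(right)),
         left = left, rep = rep_iv, right = right, repeat_copy = copy)
  }
  ivA <- .seg_iv(.circ_shift(s1, -flank, L), .circ_shift(s1, -1L, L), "+", L)
  ivB <- .seg_iv(.circ_shift(e1, 1L, L), .circ_shift(e1, flank, L), "+", L)
  ivC <- .seg_iv(.circ_shift(s2, -flank, L), .circ_shift(s2, -1L, L), "+", L)
  ivD <- .seg_iv(.circ_shift(e2, 1L, L), .circ_shift(e2, flank, L), "+", L)
  cp1 <- circ_interval(s1, e1, "+")
  cp2 <- circ_interval(s2, e2, "+")
  if (orientation == "direct") {
    size_CB <- (s2 - s1) %% L
    size_AD <- L - size_CB
    prod_CB <- seg(.seg_iv(s1, .circ_shift(s2, -1L, L), "+", L))
    prod_AD <- seg(.seg_iv(s2, .circ_shift(s1, -1L, L), "+", L))
    junctions <- list(
      `A->D` = jun("A->D", ivA, cp2, ivD, 2L),
      `C->B` = jun("C->B", ivC, cp1, ivB, 1L))
    out <- list(kind = "two_subcircles",
                product_sizes = c(`A->D` = size_AD, `C->B` = size_CB),
                products = c(`A->D` = prod_AD, `C->B` = prod_CB),
                junctions = junctions)
  } else if (orientation == "inverted") {
    ## invert segment B in place
    segB_iv <- .seg_iv(.circ_shift(e1, 1L, L), .circ_shift(s2, -1L, L),
                       "+", L)
    inv_seq <- paste0(
      substr(g$seq, 1L, e1),
      if (gapB > 0L) revcomp(seg(segB_iv)) else "",
      substr(g$seq, s2, L))
    ## this construction assumes the copies do not wrap the origin
    if (s1 > e1 || s2 > e2)
      stop("geometry error: inversion prediction requires non-wrapping copies")
    junctions <- list(
      `E->G` = jun("E->G", ivA, cp1,
                   .seg_iv(.circ_shift(s2, -flank, L),
                           .circ_shift(s2, -1L, L), "-", L), 1L),
      `F->H` = jun("F->H",
                   .seg_iv(.circ_shift(e1, 1L, L),
                           .circ_shift(e1, flank, L), "-", L),
                   cp2, ivD, 2L))
    out <- list(kind = "inversion",
                product_sizes = c(inversion = L),
                products = c(inversion = inv_seq),
                junctions = junctions)
  } else stop("unknown orientation: ", orientation)
  out$`repeat` <- r
  out$flank <- flank
  structure(out[c("repeat", "kind", "product_sizes", "products",
                  "junctions", "flank")],
            class = "recombinant_config")
}

#' @export
print.recombinant_config <- function(x, ...) {
  cat(sprintf("<recombinant_config> %s; product size(s): %s\n", x$kind,
              paste(format(x$product_sizes, big.mark = ","),
                    collapse = ", ")))
  cat("  junctions:", paste(names(x$junctions), collapse = ", "), "\n")
  invisible(x)
}

## number of occurrences of a pattern in a circular genome (both strands)
.count_occurrences <- function(g, pattern) {
  D <- paste0(g$seq, substr(g$seq, 1L, min(nchar(pattern) - 1L, g$length)))
  cnt <- function(subject, pat) {
    length(Biostrings::matchPattern(Biostrings::DNAString(pat),
                                    Biostrings::DNAString(subject)))
  }
  cnt(D, pattern) + cnt(D, revcomp(pattern))
}

## first match position of read in circular genome (+ strand then -), exact;
## returns list(start, end, strand) in 1..L coordinates, or NULL
.locate_read <- function(read, g) {
  L <- g$length
  D <- paste0(g$seq, substr(g$seq, 1L, min(nchar(read) - 1L, L)))
  p <- regexpr(read, D, fixed = TRUE)
  if (p > 0L && p <= L)
    return(list(start = as.integer(p),
                end = .circ_shift(as.integer(p), nchar(read) - 1L, L),
                strand = "+"))
  p <- regexpr(revcomp(read), D, fixed = TRUE)
  if (p > 0L && p <= L)
    return(list(start = as.integer(p),
                end = .circ_shift(as.integer(p), nchar(read) - 1L, L),
                strand = "-"))
  NULL
}

#' Design a PCR assay detecting a recombinant configuration
#'
#' For each junction of a predicted configuration, places a primer pair in
#' the unique flanks immediately adjacent to the repeat, oriented so the pair
#' yields a product only on the recombinant template: the expected product
#' spans primer + repeat + primer. Primer windows whose sequence occurs more
#' than once in the genome (either strand, circularly) are rejected as design
#' failures, as is any primer layout that would also amplify a product of at
#' most `max_product` nt from the reference configuration.
#'
#' @param g a [circular_genome()].
#' @param cfg a [predict_products()] result.
#' @param primer_len primer length (nt), >= 15; must not exceed the
#'   configuration's flank length.
#' @param max_product maximum PCR product size (nt) considered amplifiable.
#' @return A data frame with one row per junction: `label`, `primer_fwd`,
#'   `primer_rev`, `product_size`, `unique_fwd`, `unique_rev`,
#'   `reference_product` (NA when the reference yields no product), `valid`,
#'   and `reason` for failures.
#' @export
design_assay <- function(g, cfg, primer_len = 20L, max_product = 2000L) {
  primer_len <- as.integer(primer_len)
  if (primer_len < 15L) stop("primer_len must be >= 15")
  if (primer_len > cfg$flank)
    stop("primer_len exceeds the configuration's flank length")
  rep_len <- interval_length(cfg$junctions[[1]]$rep, g$length)
  rows <- lapply(cfg$junctions, function(j) {
    flank <- cfg$flank
    fwd <- substr(j$seq, flank - primer_len + 1L, flank)
    rev_site <- substr(j$seq, flank + rep_len + 1L,
                       flank + rep_len + primer_len)
    rev <- revcomp(rev_site)
    u_f <- .count_occurrences(g, fwd) == 1L
    u_r <- .count_occurrences(g, rev) == 1L
    product_size <- 2L * primer_len + rep_len
    ## would this pair amplify from the *reference* configuration? the pair
    ## yields a reference product only if the fwd site is followed (within
    ## max_product, rightwards on the same strand) by the rev site.
    ref_prod <- NA_integer_
    pf <- .locate_read(fwd, g)
    pr <- .locate_read(rev_site, g)
    if (!is.null(pf) && !is.null(pr) && pf$strand == pr$strand) {
      d <- if (pf$strand == "+") (pr$end - pf$start) %% g$length
           else (pf$end - pr$start) %% g$length
      if (d + 1L <= max_product) ref_prod <- d + 1L
    }
    valid <- u_f && u_r && product_size <= max_product && is.na(ref_prod)
    reason <- if (valid) "" else if (!u_f || !u_r) "non-unique primer site"
      else if (product_size > max_product) "product exceeds max_product"
      else "amplifies from reference configuration"
    data.frame(label = j$label, primer_fwd = fwd, primer_rev = rev,
               product_size = product_size, unique_fwd = u_f,
               unique_rev = u_r, reference_product = ref_prod,
               valid = valid, reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## map a sub-range [a, b] of a junction segment (local 1-based coordinates
## along the junction) back to a genomic circ_interval
.map_segment_range <- function(seg_iv, seg_len, a, b, L) {
  if (seg_iv$strand == "+") {
    circ_interval(.circ_shift(seg_iv$start, a - 1L, L),
                  .circ_shift(seg_iv$start, b - 1L, L), "+")
  } else {
    ## local coordinate 1 corresponds to the segment's genomic end
    circ_interval(.circ_shift(seg_iv$end, -(b - 1L), L),
                  .circ_shift(seg_iv$end, -(a - 1L), L), "-")
  }
}

#' Detect chimeric reads supporting recombinant junctions
#'
#' A read consistent with the main assembly (it, or its reverse complement,
#' occurs contiguously in the circular reference with at most `max_mismatch`
#' mismatches) yields nothing. Any other read is compared against every
#' predicted recombinant junction; a read matching a junction with anchors of
#' at least `min_anchor` nt in the unique flanks on *both* sides of the
#' repeat is reported as evidence for that configuration.
#'
#' @param reads named character vector of read sequences.
#' @param g a [circular_genome()].
#' @param repeats a `repeat_hits` data frame of candidate repeats.
#' @param min_anchor minimum anchor length (nt) in each unique flank.
#' @param max_mismatch maximum mismatches tolerated in matching.
#' @return A data frame (class `chimera_evidence`) with one row per
#'   supporting read: `read_id`, `repeat_idx`, `label`, anchor coordinates
#'   (`anchor1_start/end`, `anchor2_start/end`), `mismatches`.
#' @export
detect_chimeric_reads <- function(reads, g, repeats, min_anchor = 20L,
                                  max_mismatch = 0L) {
  L <- g$length
  min_anchor <- as.integer(min_anchor)
  empty <- data.frame(read_id = character(), repeat_idx = integer(),
                      label = character(), anchor1_start = integer(),
                      anchor1_end = integer(), anchor2_start = integer(),
                      anchor2_end = integer(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (length(reads) == 0L || nrow(repeats) == 0L) return(empty)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  max_rl <- max(nchar(reads))
  ## junction catalogue, one configuration per repeat; flank long enough for
  ## any read to be fully contained in a junction window
  cfgs <- lapply(seq_len(nrow(repeats)), function(i) {
    r <- repeats[i, ]
    gapB <- (r$start2 - r$end1 - 1L) %% L
    gapDA <- (r$start1 - r$end2 - 1L) %% L
    flank <- min(max_rl, gapB, gapDA)
    if (flank < min_anchor) return(NULL)
    predict_products(g, r, flank = flank)
  })
  D <- paste0(g$seq, substr(g$seq, 1L, max_rl - 1L))
  Drc <- revcomp(D)
  ref_match <- function(read) {
    if (max_mismatch == 0L)
      return(grepl(read, D, fixed = TRUE) || grepl(read, Drc, fixed = TRUE))
    pat <- Biostrings::DNAString(read)
    length(Biostrings::matchPattern(pat, Biostrings::DNAString(D),
                                    max.mismatch = max_mismatch)) > 0L ||
      length(Biostrings::matchPattern(pat, Biostrings::DNAString(Drc),
                                      max.mismatch = max_mismatch)) > 0L
  }
  jn_match <- function(read, jseq) {
    ## returns c(start, mismatches) of the best match of read (either
    ## orientation) in the junction sequence, or NULL
    for (rd in c(read, revcomp(read))) {
      if (max_mismatch == 0L) {
        p <- regexpr(rd, jseq, fixed = TRUE)
        if (p > 0L) return(c(as.integer(p), 0L))
      } else {
        m <- Biostrings::matchPattern(Biostrings::DNAString(rd),
                                      Biostrings::DNAString(jseq),
                                      max.mismatch = max_mismatch)
        if (length(m)) {
          st <- Biostrings::start(m)[1]
          mm <- Biostrings::neditAt(Biostrings::DNAString(rd),
                                    Biostrings::DNAString(jseq), at = st)
          return(c(st, mm))
        }
      }
    }
    NULL
  }
  rows <- list()
  for (ri in seq_along(reads)) {
    read <- unname(reads[ri])
    if (ref_match(read)) next
    for (i in seq_along(cfgs)) {
      cfg <- cfgs[[i]]
      if (is.null(cfg)) next
      flank <- cfg$flank
      rep_len <- interval_length(cfg$junctions[[1]]$rep, L)
      for (j in cfg$junctions) {
        m <- jn_match(read, j$seq)
        if (is.null(m)) next
        ms <- m[1]; me <- ms + nchar(read) - 1L
        ## anchors must reach >= min_anchor into both unique flanks
        if (ms > flank - min_anchor + 1L) next
        if (me < flank + rep_len + min_anchor) next
        a1 <- .map_segment_range(j$left, flank, ms, flank, L)
        a2 <- .map_segment_range(j$right, flank, 1L,
                                 me - flank - rep_len, L)
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = names(reads)[ri], repeat_idx = i, label = j$label,
          anchor1_start = a1$start, anchor1_end = a1$end,
          anchor2_start = a2$start, anchor2_end = a2$end,
          mismatches = m[2], stringsAsFactors = FALSE)
        break  # one evidence record per read per repeat
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  class(out) <- c("chimera_evidence", "data.frame")
  out
}

#' Quantify reference vs recombinant configuration support
#'
#' For each repeat, counts reads supporting the reference junctions (reads
#' matching the main assembly and spanning one repeat copy plus at least
#' `min_anchor` nt of flank on both sides) and reads supporting recombinant
#' junctions (rows of `evidence`), and reports their ratio. The ratio is the
#' fold under-abundance of the recombinant configuration relative to the main
#' assembly; it is flagged undefined when no recombinant read was observed.
#'
#' @param evidence a [detect_chimeric_reads()] result.
#' @param reads named character vector of read sequences.
#' @param g a [circular_genome()].
#' @param repeats the `repeat_hits` data frame used for detection.
#' @param min_anchor minimum flank anchor (nt), matching the detection call.
#' @return A data frame with one row per repeat: `repeat_idx`, `ref_reads`,
#'   `recombinant_reads`, `ratio`, `undefined`.
#' @export
quantify_configurations <- function(evidence, reads, g, repeats,
                                    min_anchor = 20L) {
  L <- g$length
  min_anchor <- as.integer(min_anchor)
  ## reference-spanning counts per repeat copy
  ref_counts <- integer(nrow(repeats))
  for (read in reads) {
    loc <- .locate_read(read, g)
    if (is.null(loc)) next
    for (i in seq_len(nrow(repeats))) {
      r <- repeats[i, ]
      spans <- function(s, e) {
        .circ_contains(loc$start, loc$end,
                       .circ_shift(s, -min_anchor, L),
                       .circ_shift(e, min_anchor, L), L)
      }
      if (spans(r$start1, r$end1) || spans(r$start2, r$end2))
        ref_counts[i] <- ref_counts[i] + 1L
    }
  }
  rec_counts <- if (nrow(evidence))
    tabulate(evidence$repeat_idx, nbins = nrow(repeats)) else
    integer(nrow(repeats))
  data.frame(repeat_idx = seq_len(nrow(repeats)), ref_reads = ref_counts,
             recombinant_reads = rec_counts,
             ratio = ifelse(rec_counts > 0, ref_counts / rec_counts, NA_real_),
             undefined = rec_counts == 0L)
}
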