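## File-format interfaces: FASTA/FASTQ via Biostrings, plus small GFF3/BED/TSV
## emitters for repeat tables. The GFF dialect writes one feature per repeat
## copy carrying orientation and percent-similarity attributes, the layout
## used for repeat survey supplements in organelle genome papers.

#' Read genomes from a FASTA file
#'
#' @param path FASTA file (single- or multi-record).
#' @param circular logical, recycled over records: circularity is not part of
#'   FASTA, so it is declared out-of-band per record.
#' @return A list of [circular_genome()] objects, named by record id.
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  circular <- rep_len(circular, length(ss))
  out <- lapply(seq_along(ss), function(i) {
    id <- sub("\\s.*$", "", names(ss)[i])
    circular_genome(as.character(ss[[i]]), id = id, circular = circular[i])
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Write genomes to a FASTA file
#'
#' @param genomes a [circular_genome()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "circular_genome")) genomes <- list(genomes)
  ss <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "seq"))
  names(ss) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read reads from FASTA or FASTQ
#'
#' @param path input file; format guessed from the extension
#'   (`.fastq`/`.fq` vs FASTA).
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

## split a possibly wrapping interval into 1 or 2 linear (start, end) rows
.iv_pieces <- function(start, end, L) {
  if (start <= end) cbind(start = start, end = end)
  else cbind(start = c(start, 1L), end = c(L, end))
}

#' Write repeat hits as GFF3
#'
#' One feature per repeat copy; `orientation` and `identity` attributes follow
#' the repeat-survey supplement layout. Copies wrapping the origin are split
#' into two features sharing an `ID`.
#'
#' @param hits a `repeat_hits` data frame (see [find_repeats()]).
#' @param path output path.
#' @param seqid sequence name for column 1.
#' @param L genome length (needed to split wrapping copies).
#' @return `path`, invisibly.
#' @export
write_repeats_gff <- function(hits, path, seqid = "genome", L = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(hits) == 0L) return(invisible(path))
  if (is.null(L)) L <- max(hits$end1, hits$end2)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    rid <- sprintf("rep%03d", i)
    for (copy in 1:2) {
      s <- h[[paste0("start", copy)]]; e <- h[[paste0("end", copy)]]
      strand <- if (h$orientation == "inverted" && copy == 2L) "-" else "+"
      pieces <- .iv_pieces(s, e, L)
      for (p in seq_len(nrow(pieces))) {
        attrs <- sprintf(
          "ID=%s.copy%d;repeat=%s;orientation=%s;identity=%.1f;length=%d;evalue=%.3g",
          rid, copy, rid, h$orientation, h$identity, h$length, h$evalue)
        writeLines(paste(seqid, "mitorecomb", "dispersed_repeat",
                         pieces[p, "start"], pieces[p, "end"], h$score,
                         strand, ".", attrs, sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Read repeat hits from a GFF3 written by [write_repeats_gff()]
#'
#' @param path GFF3 path.
#' @param L genome length, used to re-join features split across the origin.
#' @return A `repeat_hits` data frame.
#' @export
read_repeats_gff <- function(path, L = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(.empty_hits())
  f <- do.call(rbind, strsplit(lines, "\t"))
  attr_get <- function(a, key)
    sub(paste0(".*", key, "=([^;]+).*"), "\\1", a)
  df <- data.frame(
    id = attr_get(f[, 9], "ID"),
    rep = attr_get(f[, 9], "repeat"),
    start = as.integer(f[, 4]), end = as.integer(f[, 5]),
    score = as.numeric(f[, 6]), strand = f[, 7],
    orientation = attr_get(f[, 9], "orientation"),
    identity = as.numeric(attr_get(f[, 9], "identity")),
    length = as.integer(attr_get(f[, 9], "length")),
    evalue = as.numeric(attr_get(f[, 9], "evalue")),
    stringsAsFactors = FALSE)
  hits <- lapply(split(df, df$rep), function(d) {
    copy_iv <- function(copy) {
      dc <- d[grepl(paste0("copy", copy, "$"), d$id), , drop = FALSE]
      if (nrow(dc) == 2L) {
        ## split wrap: the piece ending at L comes first
        i <- which(dc$end == max(dc$end))
        c(start = dc$start[i], end = dc$end[-i])
      } else c(start = dc$start[1], end = dc$end[1])
    }
    c1 <- copy_iv(1); c2 <- copy_iv(2)
    data.frame(start1 = c1["start"], end1 = c1["end"],
               start2 = c2["start"], end2 = c2["end"],
               orientation = d$orientation[1], length = d$length[1],
               identity = d$identity[1], score = d$score[1],
               evalue = d$evalue[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out <- out[order(out$start1, out$start2), , drop = FALSE]
  class(out) <- c("repeat_hits", "data.frame")
  out
}

#' Write repeat copies as BED
#'
#' BED is 0-based half-open; this is the only place coordinates leave the
#' 1-based inclusive convention. Wrapping copies are split in two.
#'
#' @inheritParams write_repeats_gff
#' @return `path`, invisibly.
#' @export
write_repeats_bed <- function(hits, path, seqid = "genome", L = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(hits) == 0L) return(invisible(path))
  if (is.null(L)) L <- max(hits$end1, hits$end2)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    for (copy in 1:2) {
      s <- h[[paste0("start", copy)]]; e <- h[[paste0("end", copy)]]
      strand <- if (h$orientation == "inverted" && copy == 2L) "-" else "+"
      pieces <- .iv_pieces(s, e, L)
      for (p in seq_len(nrow(pieces)))
        writeLines(paste(seqid, pieces[p, "start"] - 1L, pieces[p, "end"],
                         sprintf("rep%03d.copy%d", i, copy), h$score, strand,
                         sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write a repeat table as TSV
#'
#' Columns mirror the printed repeat-survey layout: length, orientation,
#' percent identity, and start/end of each copy.
#'
#' @inheritParams write_repeats_gff
#' @return `path`, invisibly.
#' @export
write_repeats_tsv <- function(hits, path) {
  out <- data.frame(
    repeat_id = if (nrow(hits)) sprintf("rep%03d", seq_len(nrow(hits))) else character(),
    length = hits$length, orientation = hits$orientation,
    percent_identity = hits$identity,
    copy1_start = hits$start1, copy1_end = hits$end1,
    copy2_start = hits$start2, copy2_end = hits$end2,
    score = hits$score, evalue = hits$evalue)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
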