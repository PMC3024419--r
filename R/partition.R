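## Mutually exclusive genome-content partition: every position is assigned to
## exactly one top-level category by precedence, and category counts sum to
## the genome length exactly. Sub-features (exons, introns, rRNA, tRNA) are
## reported informationally and excluded from the exactness invariant.

.default_precedence <- c("conserved_syntenic", "chloroplast_like",
                         "nuclear_like", "mitochondrial_like")

## intervals (data.frame with start, end; start > end wraps) -> reduced
## IRanges of linear pieces
.feature_ranges <- function(df, L) {
  if (is.null(df) || nrow(df) == 0L) return(IRanges::IRanges())
  if (any(df$start > L | df$end > L | df$start < 1L | df$end < 1L))
    stop("feature interval outside [1, L]")
  IRanges::reduce(.copy_ranges(df$start, df$end, L))
}

#' Percent of genome, printed-table style
#'
#' @param count nucleotide count, `0 <= count <= L`.
#' @param L genome length.
#' @param digits decimal places to round to.
#' @param mode `"half_up"` rounds 0.05 upward (printed-table convention);
#'   `"banker"` uses R's round-half-even.
#' @return `100 * count / L`, rounded.
#' @examples
#' percent_of_genome(2093, 401262)  # 0.5
#' @export
percent_of_genome <- function(count, L, digits = 1L,
                              mode = c("half_up", "banker")) {
  mode <- match.arg(mode)
  if (L <= 0) stop("L must be positive")
  if (any(count < 0 | count > L)) stop("count must be in [0, L]")
  x <- 100 * count / L
  if (mode == "half_up") floor(x * 10^digits + 0.5) / 10^digits
  else round(x, digits)
}

.new_partition_report <- function(L, counts, sub_counts, mode) {
  counts <- c(counts, uncharacterized = L - sum(counts))
  if (counts[["uncharacterized"]] < 0)
    stop("category counts exceed genome length")
  structure(list(
    genome_length = L,
    counts = counts,
    percents = vapply(counts, percent_of_genome, numeric(1), L = L,
                      mode = mode),
    sub_counts = sub_counts,
    sub_percents = if (length(sub_counts))
      vapply(sub_counts, percent_of_genome, numeric(1), L = L, mode = mode)
    else numeric(),
    rounding = mode), class = "partition_report")
}

#' Partition a genome into mutually exclusive content categories
#'
#' Assigns every position to exactly one top-level category: categories are
#' claimed in `precedence` order (default: conserved syntenic, then
#' chloroplast-like, then nuclear-like, then mitochondrial-like), a position
#' already claimed is never re-assigned, and whatever remains is
#' uncharacterized. Sub-feature sets (e.g. protein exons, cis-spliced
#' introns, rRNA, tRNA) are tallied informationally and take no part in the
#' partition.
#'
#' @param L genome length (nt).
#' @param feature_sets named list of interval data frames (columns `start`,
#'   `end`, 1-based inclusive; `start > end` wraps). Every name must appear
#'   in `precedence`.
#' @param precedence character vector of category labels, highest first.
#' @param sub_features optional named list of interval data frames counted
#'   informationally.
#' @param mode rounding mode for percents, see [percent_of_genome()].
#' @return A `partition_report`: `genome_length`, `counts` (incl.
#'   `uncharacterized`), `percents`, `sub_counts`, `sub_percents`.
#' @export
partition_genome <- function(L, feature_sets,
                             precedence = .default_precedence,
                             sub_features = list(),
                             mode = c("half_up", "banker")) {
  mode <- match.arg(mode)
  L <- as.integer(L)
  unknown <- setdiff(names(feature_sets), precedence)
  if (length(unknown))
    stop("unknown category label(s): ", paste(unknown, collapse = ", "))
  assigned <- IRanges::IRanges()
  counts <- stats::setNames(integer(length(precedence)), precedence)
  for (lab in precedence) {
    r <- .feature_ranges(feature_sets[[lab]], L)
    own <- IRanges::setdiff(r, assigned)
    counts[[lab]] <- sum(IRanges::width(own))
    assigned <- IRanges::reduce(c(assigned, own))
  }
  sub_counts <- vapply(sub_features, function(df)
    sum(IRanges::width(.feature_ranges(df, L))), integer(1))
  .new_partition_report(L, counts, sub_counts, mode)
}

#' Partition report from pre-classified category totals
#'
#' Builds a `partition_report` directly from per-category nucleotide counts
#' (e.g. a published genome-coverage table), recomputing percents from the
#' counts. The counts plus the uncharacterized remainder sum exactly to `L`.
#'
#' @param counts named numeric vector of top-level category counts; an
#'   `uncharacterized` element, if present, is checked against the remainder.
#' @param L genome length (nt).
#' @param sub_counts optional named numeric vector of informational
#'   sub-feature counts.
#' @param mode rounding mode, see [percent_of_genome()].
#' @return A `partition_report`.
#' @export
partition_from_counts <- function(counts, L, sub_counts = numeric(),
                                  mode = c("half_up", "banker")) {
  mode <- match.arg(mode)
  if (is.null(names(counts))) stop("counts must be named")
  if ("uncharacterized" %in% names(counts)) {
    rest <- counts[names(counts) != "uncharacterized"]
    if (sum(rest) + counts[["uncharacterized"]] != L)
      stop("counts do not sum to the genome length")
    counts <- rest
  }
  .new_partition_report(as.integer(L), counts, sub_counts, mode)
}

#' @export
print.partition_report <- function(x, ...) {
  cat(sprintf("<partition_report> genome length %s nt\n",
              format(x$genome_length, big.mark = ",")))
  df <- data.frame(feature = names(x$counts),
                   nucleotides = format(unname(x$counts), big.mark = ","),
                   percent = sprintf("%.1f", unname(x$percents)))
  print.data.frame(df, row.names = FALSE, right = FALSE)
  if (length(x$sub_counts)) {
    cat("  sub-features (informational):\n")
    df2 <- data.frame(feature = names(x$sub_counts),
                      nucleotides = format(unname(x$sub_counts),
                                           big.mark = ","),
                      percent = sprintf("%.1f", unname(x$sub_percents)))
    print.data.frame(df2, row.names = FALSE, right = FALSE)
  }
  invisible(x)
}

#' Write a partition report as TSV
#'
#' Three columns (`feature`, `nucleotides`, `percent_genome`), top-level
#' categories first, then informational sub-features.
#'
#' @param report a `partition_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(report, path) {
  df <- data.frame(
    feature = c(names(report$counts), names(report$sub_counts)),
    nucleotides = c(unname(report$counts), unname(report$sub_counts)),
    percent_genome = c(unname(report$percents),
                       unname(report$sub_percents)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
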