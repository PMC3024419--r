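## In-silico control for PCR-mediated (in vitro) recombination: discovery of
## surrogate repeats (near-identical regions shared between two genomes with
## flanks unique within and between genomes), construction of the expected
## bi-species chimeric products, and a template-switching simulator.

#' Find surrogate repeats shared between two genomes
#'
#' Cross-genome local alignment with the same seed-and-extend engine as
#' [find_repeats()]: regions of length at least `min_len` and identity at
#' least `min_identity` shared between genomes A and B, whose flanks pass a
#' uniqueness test (each flank occurs exactly once within its own genome and
#' has no near-identical counterpart in the other genome). Such regions act
#' as "repeats" spanning two genomes: any PCR product joining their flanks
#' across species can only arise in vitro.
#'
#' @param gA,gB [circular_genome()] objects.
#' @param min_len minimum region length (nt).
#' @param min_identity minimum percent identity.
#' @param flank_len flank length (nt) used for the uniqueness test.
#' @param p an [alignment_params()].
#' @return A data frame (class `surrogate_repeats`): `startA`, `endA`,
#'   `startB`, `endB`, `orientation`, `length`, `identity`, `score`,
#'   `evalue`, `flanks_unique`.
#' @export
find_surrogate_repeats <- function(gA, gB, min_len = 50L, min_identity = 94,
                                   flank_len = 100L,
                                   p = alignment_params()) {
  W <- p$word_size
  LA <- gA$length; LB <- gB$length
  wordset <- function(seq, L) {
    n <- L - W + 1L
    st <- seq_len(n)
    w <- substring(seq, st, st + W - 1L)
    split(st[!grepl("N", w, fixed = TRUE)], w[!grepl("N", w, fixed = TRUE)])
  }
  wA <- wordset(gA$seq, LA)
  encA <- .encode_dna(gA$seq)
  rows <- list()
  for (str in c("+", "-")) {
    seqB <- if (str == "+") gB$seq else revcomp(gB$seq)
    wB <- wordset(seqB, LB)
    shared <- intersect(names(wA), names(wB))
    if (!length(shared)) next
    pr <- lapply(shared, function(wd) {
      i <- wA[[wd]]; j <- wB[[wd]]
      cbind(rep(i, each = length(j)), rep(j, length(i)))
    })
    m <- do.call(rbind, pr)
    keep <- .collapse_seed_runs(m[, 1L], m[, 2L], W)
    res <- as.data.frame(xdrop_batch_cpp(
      encA, .encode_dna(seqB), m[keep, 1L], m[keep, 2L], W,
      p$match, p$mismatch, p$gap_open, p$gap_extend, p$x_drop, p$max_extend))
    if (str == "-") {
      js <- res$start2; je <- res$end2
      res$start2 <- LB - je + 1L
      res$end2 <- LB - js + 1L
    }
    res$orientation <- if (str == "+") "direct" else "inverted"
    rows[[str]] <- res
  }
  if (!length(rows)) return(.empty_surrogates())
  raw <- unique(do.call(rbind, rows))
  out <- data.frame(
    startA = raw$start1, endA = raw$end1, startB = raw$start2,
    endB = raw$end2, orientation = raw$orientation, length = raw$columns,
    identity = 100 * raw$matches / raw$columns, score = raw$score,
    evalue = evalue(raw$score, LA, LB, p))
  out <- out[out$evalue <= p$e_cutoff, , drop = FALSE]
  if (nrow(out) > 1L) {
    ## greedy by score: drop alignments contained in higher-scoring ones
    ord <- order(-out$score, out$startA)
    kept <- integer()
    for (i in ord) {
      contained <- any(vapply(kept, function(j)
        .circ_contains(out$startA[j], out$endA[j],
                       out$startA[i], out$endA[i], LA) &&
          .circ_contains(out$startB[j], out$endB[j],
                         out$startB[i], out$endB[i], LB), logical(1)))
      if (!contained) kept <- c(kept, i)
    }
    out <- out[sort(kept), , drop = FALSE]
  }
  out <- out[out$length >= min_len & out$identity >= min_identity, ,
             drop = FALSE]
  ## flank uniqueness: exact within own genome, no near-match in the other
  max_mm <- max(0L, floor(flank_len * (1 - min_identity / 100)))
  near_match <- function(pattern, g) {
    D <- paste0(g$seq, substr(g$seq, 1L, nchar(pattern) - 1L))
    length(Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                    Biostrings::DNAString(D),
                                    max.mismatch = max_mm)) > 0L ||
      length(Biostrings::matchPattern(
        Biostrings::DNAString(revcomp(pattern)), Biostrings::DNAString(D),
        max.mismatch = max_mm)) > 0L
  }
  out$flanks_unique <- vapply(seq_len(nrow(out)), function(i) {
    fl <- function(g, s, e) {
      L <- g$length
      list(extract_subseq(g, .seg_iv(.circ_shift(s, -flank_len, L),
                                     .circ_shift(s, -1L, L), "+", L)),
           extract_subseq(g, .seg_iv(.circ_shift(e, 1L, L),
                                     .circ_shift(e, flank_len, L), "+", L)))
    }
    fA <- fl(gA, out$startA[i], out$endA[i])
    fB <- fl(gB, out$startB[i], out$endB[i])
    all(vapply(fA, function(x) .count_occurrences(gA, x) == 1L &&
                 !near_match(x, gB), logical(1))) &&
      all(vapply(fB, function(x) .count_occurrences(gB, x) == 1L &&
                   !near_match(x, gA), logical(1)))
  }, logical(1))
  out <- out[out$flanks_unique, , drop = FALSE]
  out <- out[order(out$startA), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("surrogate_repeats", "data.frame")
  out
}

.empty_surrogates <- function() {
  out <- data.frame(startA = integer(), endA = integer(), startB = integer(),
                    endB = integer(), orientation = character(),
                    length = integer(), identity = numeric(),
                    score = integer(), evalue = numeric(),
                    flanks_unique = logical())
  class(out) <- c("surrogate_repeats", "data.frame")
  out
}

#' Expected bi-species chimeric PCR products
#'
#' Constructs both cross-species junction sequences for a surrogate repeat:
#' the A-side flank joined through the shared region to the B-side flank, and
#' vice versa. The shared-region sequence used is the copy of the genome
#' contributing the upstream flank (the template the polymerase started on).
#' Each product is a sequence absent, as a contiguous string, from both input
#' genomes.
#'
#' @param s one row of a [find_surrogate_repeats()] result.
#' @param gA,gB the two genomes.
#' @param flank flank length (nt) on each side.
#' @return Named character vector with elements `"A->B"` and `"B->A"`.
#' @export
expected_chimeric_products <- function(s, gA, gB, flank) {
  flank <- as.integer(flank)
  LA <- gA$length; LB <- gB$length
  if (flank < 1L) stop("flank must be >= 1")
  lenA <- (s$endA - s$startA + 1L) + if (s$startA > s$endA) LA else 0L
  if (flank >= LA - lenA || flank >= LB -
      ((s$endB - s$startB + 1L) + if (s$startB > s$endB) LB else 0L))
    stop("flank error: flank exceeds available unique sequence")
  upA <- extract_subseq(gA, .seg_iv(.circ_shift(s$startA, -flank, LA),
                                    .circ_shift(s$startA, -1L, LA), "+", LA))
  dnA <- extract_subseq(gA, .seg_iv(.circ_shift(s$endA, 1L, LA),
                                    .circ_shift(s$endA, flank, LA), "+", LA))
  upB <- extract_subseq(gB, .seg_iv(.circ_shift(s$startB, -flank, LB),
                                    .circ_shift(s$startB, -1L, LB), "+", LB))
  dnB <- extract_subseq(gB, .seg_iv(.circ_shift(s$endB, 1L, LB),
                                    .circ_shift(s$endB, flank, LB), "+", LB))
  repA <- extract_subseq(gA, circ_interval(s$startA, s$endA, "+"))
  repB <- extract_subseq(gB, circ_interval(s$startB, s$endB, "+"))
  c(`A->B` = paste0(upA, repA, dnB), `B->A` = paste0(upB, repB, dnA))
}

#' Construct a PCR template pool
#'
#' Templates are tracked as molecule counts per species (and, once cycling
#' starts, per left/right flank species for chimeras). The switching model is
#' a single per-extension template exchange: when extension crosses a shared
#' region, with probability `p_switch * n/(n + k_half)` (where `n` is the
#' current number of template molecules of the other species) the growing
#' strand re-anneals to a template of the other species and is completed
#' there. `k_half = 0` gives the pure Bernoulli model; `k_half > 0` makes
#' exchange a bimolecular encounter, producing the template-concentration
#' dependence seen in PCR-recombination experiments. With `n_shared_regions`
#' regions the per-extension switch probability is
#' `1 - (1 - p_eff)^n_shared_regions`.
#'
#' @param weights named numeric vector of initial template molecule counts,
#'   names are species tags (e.g. `c(A = 700, B = 700)`).
#' @param cycles number of PCR cycles (default 35).
#' @param p_switch per-crossing template-exchange probability in `[0, 1]`.
#' @param k_half half-saturation constant (molecules) for the bimolecular
#'   encounter factor; 0 disables concentration dependence.
#' @param n_shared_regions number of shared regions crossed per extension.
#' @param max_molecules plateau capacity (total molecules), emulating
#'   reagent exhaustion.
#' @return A list of class `pcr_pool`.
#' @export
pcr_pool <- function(weights, cycles = 35L, p_switch = 0.02, k_half = 0,
                     n_shared_regions = 1L, max_molecules = 5000) {
  stopifnot(length(weights) == 2L, !is.null(names(weights)),
            all(weights >= 0), cycles >= 1, p_switch >= 0, p_switch <= 1,
            k_half >= 0, n_shared_regions >= 1)
  structure(list(weights = weights, cycles = as.integer(cycles),
                 p_switch = p_switch, k_half = k_half,
                 n_shared_regions = as.integer(n_shared_regions),
                 max_molecules = max_molecules),
            class = "pcr_pool")
}

#' Simulate PCR with template switching
#'
#' Count-based stochastic simulation of `pool$cycles` PCR cycles. Each cycle,
#' every template whose left flank matches the forward primer's species is
#' primed (up to the capacity plateau); each new strand, when its extension
#' crosses the shared region, switches templates with the probability
#' described in [pcr_pool()] and is completed on a template of the other
#' species, yielding a chimeric molecule. Same-species template exchange is
#' molecularly silent and therefore folded into non-switching. A crossing is
#' *informative* when the strand is synthesised on a pure-species template
#' while at least one other-species template is present (re-amplification of
#' an already-chimeric molecule reports nothing new about switching); at
#' `p_switch = 1` every informative product is chimeric. With
#' species-specific primers, any amplifiable product in a two-species pool
#' is chimeric.
#'
#' @param pool a [pcr_pool()].
#' @param primers length-2 character vector of species tags,
#'   `c(forward = , reverse = )`: the species whose flank each primer
#'   matches. A primer matching both species is an assay-design error.
#' @param seed RNG seed for reproducibility.
#' @return A list of class `pcr_tally`: `products` (counts by left/right
#'   species type), `chimeric`, `non_chimeric`, `informative`,
#'   `chimera_fraction` (chimeric / all full-length products; 0 when no
#'   products), `chimera_fraction_informative`, `detectable` (products
#'   amplifiable by the primer pair).
#' @export
simulate_pcr <- function(pool, primers = c(forward = names(pool$weights)[1],
                                           reverse = names(pool$weights)[2]),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- names(pool$weights)
  if (any(!primers %in% sp))
    stop("assay-design error: each primer must match exactly one species (",
         paste(sp, collapse = "/"), ")")
  fwd <- unname(primers[1]); rev <- unname(primers[2])
  types <- c(outer(sp, sp, paste0))  # left-right species combinations
  n <- stats::setNames(numeric(length(types)), types)
  n[paste0(sp[1], sp[1])] <- round(pool$weights[[1]])
  n[paste0(sp[2], sp[2])] <- round(pool$weights[[2]])
  prod <- stats::setNames(numeric(length(types)), types)
  informative <- 0
  chim_informative <- 0
  left_of <- substr(types, 1L, 1L)
  right_of <- substr(types, 2L, 2L)
  pure <- left_of == right_of
  for (cyc in seq_len(pool$cycles)) {
    total <- sum(n)
    room <- pool$max_molecules - total
    if (room <= 0) break
    elig <- n[left_of == fwd]
    n_new_tot <- sum(elig)
    if (n_new_tot == 0) break
    scale <- min(1, room / n_new_tot)
    ## all strands synthesised this cycle see the previous cycle's pool;
    ## new molecules join the pool only at the end of the cycle
    add <- stats::setNames(numeric(length(types)), types)
    for (t in names(elig)) {
      n_new <- round(elig[[t]] * scale)
      if (n_new < 1) next
      rsp <- substr(t, 2L, 2L)
      other <- setdiff(sp, rsp)
      n_other <- sum(n[right_of == other])
      if (n_other > 0) {
        ## informative crossings: synthesis on a pure-species template with
        ## the other species available; re-amplification of an existing
        ## chimera reports nothing new about switching
        if (pure[match(t, types)]) informative <- informative + n_new
        p_eff <- pool$p_switch * n_other / (n_other + pool$k_half)
        p_ext <- 1 - (1 - p_eff)^pool$n_shared_regions
        n_sw <- stats::rbinom(1L, n_new, p_ext)
        if (pure[match(t, types)]) chim_informative <- chim_informative + n_sw
      } else n_sw <- 0
      if (n_sw > 0) {
        t_sw <- paste0(substr(t, 1L, 1L), other)
        add[t_sw] <- add[t_sw] + n_sw
      }
      if (n_new - n_sw > 0) add[t] <- add[t] + (n_new - n_sw)
    }
    n <- n + add
    prod <- prod + add
  }
  chim <- sum(prod[left_of != right_of])
  nonchim <- sum(prod[left_of == right_of])
  detectable <- sum(prod[left_of == fwd & right_of == rev])
  structure(list(
    products = prod, chimeric = chim, non_chimeric = nonchim,
    informative = informative,
    chimera_fraction = if (chim + nonchim > 0) chim / (chim + nonchim) else 0,
    chimera_fraction_informative =
      if (informative > 0) chim_informative / informative else 0,
    detectable = detectable), class = "pcr_tally")
}

#' @export
print.pcr_tally <- function(x, ...) {
  cat(sprintf(
    "<pcr_tally> %.0f products: %.0f chimeric, %.0f non-chimeric (fraction %.3f); %.0f detectable\n",
    x$chimeric + x$non_chimeric, x$chimeric, x$non_chimeric,
    x$chimera_fraction, x$detectable))
  invisible(x)
}

#' Chimera formation across a template dilution series
#'
#' Runs [simulate_pcr()] over a series of template concentrations (the base
#' pool's weights scaled by each dilution factor) with a fixed switching
#' probability, returning the chimera fraction per assay. With a positive
#' `k_half`, the expected chimera fraction is non-decreasing in template
#' concentration: dilute, total-DNA-like templates yield chimeras in only a
#' minority of assays while concentrated, amplicon-like templates yield them
#' in essentially all.
#'
#' @param pool a [pcr_pool()]; its `k_half` should be positive for a
#'   concentration effect to exist.
#' @param dilutions numeric vector of template scale factors (>= 2 values),
#'   e.g. `c(1, 70)`.
#' @param replicates seeded replicates per dilution.
#' @param seed base RNG seed; replicate r at dilution d uses a distinct
#'   derived seed.
#' @param primers passed to [simulate_pcr()].
#' @return A data frame: `dilution`, `replicate`, `chimera_fraction`,
#'   `chimeric`, `detectable`.
#' @export
concentration_response <- function(pool, dilutions, replicates = 1L,
                                   seed = 1L,
                                   primers = c(forward = names(pool$weights)[1],
                                               reverse = names(pool$weights)[2])) {
  if (length(dilutions) < 2L) stop("need at least 2 dilution levels")
  rows <- list()
  for (di in seq_along(dilutions)) {
    for (r in seq_len(replicates)) {
      pl <- pool
      pl$weights <- pool$weights * dilutions[di]
      tl <- simulate_pcr(pl, primers = primers,
                         seed = (seed + 7919L * di + r) %% .Machine$integer.max)
      rows[[length(rows) + 1L]] <- data.frame(
        dilution = dilutions[di], replicate = r,
        chimera_fraction = tl$chimera_fraction, chimeric = tl$chimeric,
        detectable = tl$detectable)
    }
  }
  do.call(rbind, rows)
}
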