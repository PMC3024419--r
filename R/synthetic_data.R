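## Fixture generators with full ground truth: circular genomes with planted
## repeat pairs and labelled segments, recombinant molecule pools at defined
## under-abundance ratios, error-free labelled read sets, and bi-species
## genome pairs sharing only planted surrogate-repeat regions.
##
## Two generator conventions keep planted coordinates well-defined:
## substitutions realising sub-100% identity are placed away from copy ends
## (a terminal mismatch would be trimmed by any maximal-scoring local
## alignment, silently shortening the repeat), and the few bases flanking
## each copy are forced to differ between the two copy contexts (otherwise a
## chance flank match makes the true repeat longer than its nominal plant).

.base_alphabet <- c("A", "C", "G", "T")
.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Specification of a repeat to plant
#'
#' @param length repeat length (nt), >= 20.
#' @param identity percent identity between the copies, in `[80, 100]`;
#'   realised as the nearest achievable substitution count.
#' @param orientation `"direct"` or `"inverted"`.
#' @param positions `"random"`, or fixed integer starts `c(start1, start2)`.
#' @return A list of class `repeat_spec`.
#' @export
repeat_spec <- function(length, identity = 100, orientation = "direct",
                        positions = "random") {
  stopifnot(length >= 20, identity >= 80, identity <= 100,
            orientation %in% c("direct", "inverted"))
  structure(list(length = as.integer(length), identity = identity,
                 orientation = orientation, positions = positions),
            class = "repeat_spec")
}

## sample background sequence at a given GC percent
.sample_background <- function(L, gc) {
  p <- c((100 - gc) / 200, gc / 200, gc / 200, (100 - gc) / 200)
  sample(.base_alphabet, L, replace = TRUE, prob = p)
}

## wrap a (possibly out-of-range) position vector onto 1..L
.wrap_pos <- function(pos, L) ((pos - 1L) %% L) + 1L

## sample substitution offsets such that the planted alignment is its own
## maximal-scoring local alignment: every prefix and suffix must keep a
## strictly positive score under (match +1, mismatch -3), i.e. the k-th
## substitution from either end must sit at offset >= 4k + 1. Otherwise a
## trimmed alignment outscores the full planted one and the recovered
## coordinates would (correctly) differ from the plant.
.sample_sub_offsets <- function(len, k_sub, end_margin, max_tries = 500L) {
  if (k_sub == 0L) return(integer())
  allowed <- (end_margin + 1L):(len - end_margin)
  if (k_sub > length(allowed))
    stop("placement error: too many substitutions for the copy interior")
  for (i in seq_len(max_tries)) {
    subs <- sort(sample(allowed, k_sub))
    lead_ok <- all(subs >= 4L * seq_len(k_sub) + 1L)
    tail_ok <- all((len + 1L - rev(subs)) >= 4L * seq_len(k_sub) + 1L)
    if (lead_ok && tail_ok) return(subs)
  }
  stop("placement error: could not realise the identity with ",
       "alignment-stable substitution positions")
}

#' Generate a circular genome with planted repeats and labelled segments
#'
#' Background sequence is i.i.d. at the requested GC content. For every
#' [repeat_spec()], copy 1 is the background at its position and copy 2 is
#' derived from it by exactly the number of substitutions realising the
#' requested identity (reverse-complemented for inverted repeats).
#' Substitutions are confined to the copy interior (`end_margin` nt from each
#' end) and `boundary_guard` bases flanking each copy are forced to mismatch
#' between the copy contexts, so the planted coordinates are exactly the
#' maximal-alignment coordinates. Segment specs plant labelled intervals
#' (e.g. chloroplast-like/nuclear-like) recorded in the truth only.
#'
#' @param L genome length (nt).
#' @param specs list of [repeat_spec()] objects.
#' @param segment_specs named list: label -> vector of segment lengths.
#' @param gc background GC percent.
#' @param seed RNG seed; the generated genome is a pure function of
#'   `(parameters, seed)`.
#' @param min_gap minimum separation (nt) between planted features.
#' @param boundary_guard number of forced-mismatch bases at each copy
#'   boundary.
#' @param end_margin substitution-free margin (nt) inside each copy end.
#' @param max_tries placement retries before a placement error.
#' @return A list with elements `genome` (a [circular_genome()]) and `truth`
#'   (class `synthetic_truth`: planted repeat coordinates, realised
#'   identities, substitution offsets, planted segments, seed).
#' @export
generate_genome <- function(L, specs = list(), segment_specs = list(),
                            gc = 45.1, seed = NULL, min_gap = 200L,
                            boundary_guard = 3L, end_margin = 4L,
                            max_tries = 200L) {
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(L)
  planted_total <- sum(vapply(specs, function(s) 2L * s$length, integer(1))) +
    sum(unlist(segment_specs))
  if (planted_total >= L)
    stop("placement error: total planted length must be below L")
  v <- .sample_background(L, gc)
  occupied <- matrix(integer(), 0L, 2L)  # non-wrapping intervals
  occ_rows <- function(s, e) {
    if (e > L) rbind(c(s, L), c(1L, e - L)) else cbind(s, e)
  }
  overlaps_occ <- function(s, e) {
    any(occupied[, 1L] <= e + min_gap & occupied[, 2L] >= s - min_gap)
  }
  place <- function(len) {
    for (i in seq_len(max_tries)) {
      s <- sample.int(L - len + 1L, 1L)
      if (!overlaps_occ(s, s + len - 1L)) return(s)
    }
    stop("placement error: could not place a ", len,
         "-nt feature after ", max_tries, " tries")
  }
  rep_rows <- list()
  sub_positions <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    len <- sp$length
    if (identical(sp$positions, "random") || is.null(sp$positions)) {
      s1 <- place(len)
      occupied <- rbind(occupied, occ_rows(s1, s1 + len - 1L))
      s2 <- place(len)
      occupied <- rbind(occupied, occ_rows(s2, s2 + len - 1L))
      if (s2 < s1) { tmp <- s1; s1 <- s2; s2 <- tmp }
    } else {
      s1 <- as.integer(sp$positions[1]); s2 <- as.integer(sp$positions[2])
      occupied <- rbind(occupied, occ_rows(s1, s1 + len - 1L),
                        occ_rows(s2, s2 + len - 1L))
    }
    e1 <- s1 + len - 1L; e2 <- s2 + len - 1L
    copy1 <- v[.wrap_pos(s1:e1, L)]
    ## substitutions realising the requested identity, interior only
    k_sub <- round(len * (1 - sp$identity / 100))
    subs <- .sample_sub_offsets(len, k_sub, end_margin)
    copy2 <- copy1
    for (pp in subs)
      copy2[pp] <- sample(setdiff(.base_alphabet, copy2[pp]), 1L)
    if (sp$orientation == "inverted")
      copy2 <- rev(unname(.comp[copy2]))
    v[.wrap_pos(s2:e2, L)] <- copy2
    ## boundary guards: force the flanking contexts of the two copies apart
    for (d in seq_len(boundary_guard)) {
      if (sp$orientation == "direct") {
        iL1 <- .wrap_pos(s1 - d, L); iL2 <- .wrap_pos(s2 - d, L)
        if (v[iL2] == v[iL1])
          v[iL2] <- sample(setdiff(.base_alphabet, v[iL1]), 1L)
        iR1 <- .wrap_pos(e1 + d, L); iR2 <- .wrap_pos(e2 + d, L)
        if (v[iR2] == v[iR1])
          v[iR2] <- sample(setdiff(.base_alphabet, v[iR1]), 1L)
      } else {
        ## copy1 left flank aligns with the reverse complement of copy2's
        ## right flank, and vice versa
        iL1 <- .wrap_pos(s1 - d, L); iR2 <- .wrap_pos(e2 + d, L)
        if (v[iR2] == .comp[[v[iL1]]])
          v[iR2] <- sample(setdiff(.base_alphabet, .comp[[v[iL1]]]), 1L)
        iR1 <- .wrap_pos(e1 + d, L); iL2 <- .wrap_pos(s2 - d, L)
        if (v[iL2] == .comp[[v[iR1]]])
          v[iL2] <- sample(setdiff(.base_alphabet, .comp[[v[iR1]]]), 1L)
      }
    }
    rep_rows[[k]] <- data.frame(
      spec_id = k, length = len, orientation = sp$orientation,
      identity_requested = sp$identity,
      identity_realized = 100 * (len - k_sub) / len,
      n_substitutions = k_sub,
      start1 = s1, end1 = e1, start2 = s2, end2 = e2)
    sub_positions[[k]] <- subs
  }
  seg_rows <- list()
  for (lab in names(segment_specs)) {
    for (len in segment_specs[[lab]]) {
      s <- place(as.integer(len))
      occupied <- rbind(occupied, occ_rows(s, s + as.integer(len) - 1L))
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        label = lab, start = s, end = s + as.integer(len) - 1L)
    }
  }
  gid <- sprintf("synth_L%d_seed%s", L, if (is.null(seed)) "NA" else seed)
  genome <- circular_genome(paste(v, collapse = ""), id = gid,
                            circular = TRUE)
  truth <- structure(list(
    genome_id = gid, seed = seed, gc = gc,
    repeats = if (length(rep_rows)) do.call(rbind, rep_rows) else
      data.frame(),
    sub_positions = sub_positions,
    segments = if (length(seg_rows)) do.call(rbind, seg_rows) else
      data.frame()), class = "synthetic_truth")
  list(genome = genome, truth = truth)
}

#' Recombinant molecule pool at a defined under-abundance ratio
#'
#' Emits the reference genome plus the predicted recombinant product(s) of
#' one planted repeat, with concentration weights `ratio[1]` (reference) and
#' `ratio[2]` (each recombinant product). Direct repeats yield three
#' molecules (reference plus two subgenomic circles), inverted repeats two
#' (reference plus the inversion).
#'
#' @param g the reference [circular_genome()].
#' @param truth the matching `synthetic_truth`.
#' @param repeat_id row index into `truth$repeats`.
#' @param ratio reference:recombinant weights; a single number `x` means
#'   `x : 1`.
#' @return A list of class `molecule_pool`: `molecules` (data frame with
#'   `name`, `kind`, `weight`, `length`), `seqs` (named sequences),
#'   `junctions` (per-molecule repeat windows used for read labelling),
#'   `repeat_id`, `config`.
#' @export
generate_recombinant_molecules <- function(g, truth, repeat_id, ratio) {
  if (length(ratio) == 1L) ratio <- c(ratio, 1)
  if (!repeat_id %in% seq_len(nrow(truth$repeats)))
    stop("unknown repeat id: ", repeat_id)
  r <- truth$repeats[repeat_id, ]
  mol <- data.frame(name = "reference", kind = "reference",
                    weight = ratio[1], length = g$length)
  seqs <- list(reference = g$seq)
  junctions <- list(reference = data.frame(
    start = c(r$start1, r$start2), end = c(r$end1, r$end2),
    label = c("ref1", "ref2")))
  cfg <- NULL
  if (ratio[2] > 0) {
    cfg <- predict_products(g, r, flank = 1L)
    if (cfg$kind == "two_subcircles") {
      rl1 <- r$end1 - r$start1 + 1L
      rl2 <- r$end2 - r$start2 + 1L
      mol <- rbind(mol,
                   data.frame(name = "A->D", kind = "subcircle",
                              weight = ratio[2],
                              length = nchar(cfg$products[["A->D"]])),
                   data.frame(name = "C->B", kind = "subcircle",
                              weight = ratio[2],
                              length = nchar(cfg$products[["C->B"]])))
      seqs[["A->D"]] <- cfg$products[["A->D"]]
      seqs[["C->B"]] <- cfg$products[["C->B"]]
      ## each subcircle starts at its retained repeat copy
      junctions[["A->D"]] <- data.frame(start = 1L, end = rl2,
                                        label = "A->D")
      junctions[["C->B"]] <- data.frame(start = 1L, end = rl1,
                                        label = "C->B")
    } else {
      mol <- rbind(mol, data.frame(name = "inversion", kind = "inversion",
                                   weight = ratio[2], length = g$length))
      seqs[["inversion"]] <- cfg$products[["inversion"]]
      junctions[["inversion"]] <- data.frame(
        start = c(r$start1, r$start2), end = c(r$end1, r$end2),
        label = c("E->G", "F->H"))
    }
  }
  structure(list(molecules = mol, seqs = seqs, junctions = junctions,
                 repeat_id = repeat_id, config = cfg),
            class = "molecule_pool")
}

#' Generate an error-free labelled read set from a molecule pool
#'
#' Read counts per molecule are Poisson with mean
#' `depth * (weight / reference weight) * length / read_len`, so `depth` is
#' the fold-coverage of the reference molecule; start positions are uniform
#' on each circular molecule (reads wrap). Labels record the source molecule
#' and, for reads covering a repeat window plus `min_anchor` nt on both
#' sides, the junction label they span.
#'
#' @param pool a [generate_recombinant_molecules()] pool, or a
#'   [circular_genome()] (treated as a reference-only pool).
#' @param depth fold-coverage of the reference molecule.
#' @param read_len read length (nt); must be below the shortest molecule.
#' @param seed RNG seed.
#' @param min_anchor flank length (nt) required on both sides of a repeat
#'   window for a read to be labelled as spanning its junction.
#' @param error_rate per-base substitution probability (0 = error-free).
#' @return A list: `reads` (named character vector) and `labels` (data frame
#'   `read_id`, `molecule`, `kind`, `start`, `end`, `junction`,
#'   `recombinant_junction`).
#' @export
generate_reads <- function(pool, depth, read_len, seed = NULL,
                           min_anchor = 20L, error_rate = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(pool, "circular_genome")) {
    pool <- structure(list(
      molecules = data.frame(name = "reference", kind = "reference",
                             weight = 1, length = pool$length),
      seqs = list(reference = pool$seq),
      junctions = list(reference = data.frame(start = integer(),
                                              end = integer(),
                                              label = character()))),
      class = "molecule_pool")
  }
  read_len <- as.integer(read_len)
  if (depth > 0 && read_len >= min(pool$molecules$length))
    stop("read_len must be below the shortest molecule")
  w_ref <- pool$molecules$weight[pool$molecules$kind == "reference"][1]
  reads <- character(0)
  labels <- list()
  empty <- data.frame(read_id = character(), molecule = character(),
                      kind = character(), start = integer(),
                      end = integer(), junction = character(),
                      recombinant_junction = logical(),
                      stringsAsFactors = FALSE)
  if (depth <= 0) return(list(reads = character(0), labels = empty))
  for (m in seq_len(nrow(pool$molecules))) {
    len <- pool$molecules$length[m]
    name <- pool$molecules$name[m]
    lambda <- depth * (pool$molecules$weight[m] / w_ref) * len / read_len
    n <- stats::rpois(1L, lambda)
    if (n == 0L) next
    doubled <- paste0(pool$seqs[[name]],
                      substr(pool$seqs[[name]], 1L, read_len - 1L))
    starts <- sample.int(len, n, replace = TRUE)
    seqs <- substring(doubled, starts, starts + read_len - 1L)
    if (error_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        b <- strsplit(s, "")[[1]]
        hit <- which(stats::runif(length(b)) < error_rate)
        for (h in hit) b[h] <- sample(setdiff(.base_alphabet, b[h]), 1L)
        paste(b, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    ends <- .wrap_pos(starts + read_len - 1L, len)
    jw <- pool$junctions[[name]]
    jlab <- rep(NA_character_, n)
    if (!is.null(jw) && nrow(jw)) {
      for (j in seq_len(nrow(jw))) {
        es <- .wrap_pos(jw$start[j] - min_anchor, len)
        ee <- .wrap_pos(jw$end[j] + min_anchor, len)
        cov <- vapply(seq_len(n), function(i)
          .circ_contains(starts[i], ends[i], es, ee, len), logical(1))
        jlab[cov & is.na(jlab)] <- jw$label[j]
      }
    }
    ids <- sprintf("%s_read%05d", gsub("[^A-Za-z0-9]", "", name),
                   seq_along(seqs) + length(reads))
    reads <- c(reads, stats::setNames(seqs, ids))
    labels[[m]] <- data.frame(
      read_id = ids, molecule = name, kind = pool$molecules$kind[m],
      start = starts, end = ends, junction = jlab,
      recombinant_junction =
        !is.na(jlab) & pool$molecules$kind[m] != "reference",
      stringsAsFactors = FALSE)
  }
  lab <- if (length(labels)) do.call(rbind, labels) else empty
  rownames(lab) <- NULL
  list(reads = reads, labels = lab)
}

#' Generate a bi-species fixture sharing only planted surrogate regions
#'
#' Two unrelated random backgrounds that share exactly the specified planted
#' regions (direct orientation), each region flanked by sequence unique
#' within and between the genomes. Boundary guards force the flanking
#' contexts apart so the planted coordinates are the alignment coordinates.
#'
#' @param shared_lengths vector of shared-region lengths (nt).
#' @param identities vector of percent identities, same length.
#' @param seed RNG seed.
#' @param genome_length length of each background genome (nt).
#' @param gc background GC percent.
#' @param min_gap minimum separation between planted regions (nt).
#' @param boundary_guard,end_margin as in [generate_genome()].
#' @return A list: `genomeA`, `genomeB` ([circular_genome()]s) and `truth`
#'   (data frame of planted coordinates and realised identities).
#' @export
generate_bispecies_fixture <- function(shared_lengths, identities,
                                       seed = NULL, genome_length = 6000L,
                                       gc = 45.1, min_gap = 400L,
                                       boundary_guard = 3L,
                                       end_margin = 4L) {
  if (length(shared_lengths) != length(identities))
    stop("shared_lengths and identities must have equal length")
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(genome_length)
  vA <- .sample_background(L, gc)
  vB <- .sample_background(L, gc)
  occA <- matrix(integer(), 0L, 2L)
  occB <- matrix(integer(), 0L, 2L)
  place <- function(len, occ) {
    for (i in seq_len(200L)) {
      s <- sample.int(L - len + 1L, 1L)
      if (!any(occ[, 1L] <= s + len - 1L + min_gap &
                 occ[, 2L] >= s - min_gap)) return(s)
    }
    stop("placement error: could not place a shared region")
  }
  rows <- list()
  for (k in seq_along(shared_lengths)) {
    len <- as.integer(shared_lengths[k])
    idy <- identities[k]
    sA <- place(len, occA); occA <- rbind(occA, c(sA, sA + len - 1L))
    sB <- place(len, occB); occB <- rbind(occB, c(sB, sB + len - 1L))
    eA <- sA + len - 1L; eB <- sB + len - 1L
    region <- vA[sA:eA]
    k_sub <- round(len * (1 - idy / 100))
    subs <- .sample_sub_offsets(len, k_sub, end_margin)
    copyB <- region
    for (pp in subs)
      copyB[pp] <- sample(setdiff(.base_alphabet, copyB[pp]), 1L)
    vB[sB:eB] <- copyB
    for (d in seq_len(boundary_guard)) {
      iA <- .wrap_pos(sA - d, L); iB <- .wrap_pos(sB - d, L)
      if (vB[iB] == vA[iA])
        vB[iB] <- sample(setdiff(.base_alphabet, vA[iA]), 1L)
      iA <- .wrap_pos(eA + d, L); iB <- .wrap_pos(eB + d, L)
      if (vB[iB] == vA[iA])
        vB[iB] <- sample(setdiff(.base_alphabet, vA[iA]), 1L)
    }
    rows[[k]] <- data.frame(
      length = len, identity_requested = idy,
      identity_realized = 100 * (len - k_sub) / len,
      startA = sA, endA = eA, startB = sB, endB = eB)
  }
  list(genomeA = circular_genome(paste(vA, collapse = ""), id = "speciesA"),
       genomeB = circular_genome(paste(vB, collapse = ""), id = "speciesB"),
       truth = do.call(rbind, rows))
}
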