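params <- alignment_params()

test_that("seed_matches equals the brute-force word-pair oracle", {
  # planted tandem word
  g <- circular_genome("ACGTACGT", circular = FALSE)
  sm <- seed_matches(g, 4)
  expect_true(any(sm$pos1 == 1 & sm$pos2 == 5 & sm$strand == "+"))
  # triple tandem and random genomes, full equality with the O(L^2) oracle
  for (gg in list(circular_genome("ACGTACGTACGT", circular = FALSE),
                  circular_genome(rand_dna(400, seed = 2), circular = FALSE),
                  circular_genome(paste0(rand_dna(150, seed = 3),
                                         substr(rand_dna(150, seed = 3), 40, 80),
                                         rand_dna(60)), circular = FALSE))) {
    got <- seed_matches(gg, 4)
    want <- oracle_seed_pairs(gg, 4)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("Karlin-Altschul E-values follow the closed form", {
  p <- alignment_params()
  # algebraic identity: lambda * S = ln(K m n)  =>  E = 1
  m <- 401262
  s <- log(p$K * m * m) / p$lambda
  expect_equal(evalue(s, m, m, p), 1.0, tolerance = 1e-12)
  # large score limit
  expect_lt(evalue(1000, m, m, p), 1e-300)
  # independent evaluation of the closed form in log space
  e <- evalue(20, m, m, p)
  log_e <- log(0.711) + 2 * log(401262) - 1.374 * 20
  expect_equal(log(e), log_e, tolerance = 1e-10)
  # doubling the genome length increases E exactly 4-fold (E ~ m*n)
  expect_equal(evalue(20, 2 * m, 2 * m, p) / evalue(20, m, m, p), 4)
  # monotonically decreasing in score
  ev <- evalue(10:30, m, m, p)
  expect_true(all(diff(ev) < 0))
  expect_error(evalue(10, 0, m, p), "positive")
  expect_error(evalue(-1, m, m, p), ">= 0")
})

test_that("extend_hit recovers planted perfect and imperfect repeats", {
  # perfect 100-nt copies: identity 100, score = 100 * M
  fx <- generate_genome(3000, specs = list(repeat_spec(100, 100, "direct")),
                        seed = 21)
  r <- fx$truth$repeats
  seed <- list(pos1 = r$start1 + 10, pos2 = r$start2 + 10, strand = "+")
  h <- extend_hit(fx$genome, seed, params)
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 100)
  expect_equal(h$score, 100 * params$match)
  expect_equal(c(h$start1, h$end1, h$start2, h$end2),
               c(r$start1, r$end1, r$start2, r$end2))
  # 80-nt copies with 5 substitutions: identity 93.75
  fx2 <- generate_genome(3000, specs = list(repeat_spec(80, 93.75, "direct")),
                         seed = 22)
  r2 <- fx2$truth$repeats
  expect_equal(r2$n_substitutions, 5)
  # seed offset chosen so the word avoids every substitution position
  subs <- fx2$truth$sub_positions[[1]]
  W <- params$word_size
  off <- which(vapply(0:(80 - W), function(o)
    !any(subs > o & subs <= o + W), logical(1)))[1] - 1
  h2 <- extend_hit(fx2$genome,
                   list(pos1 = r2$start1 + off, pos2 = r2$start2 + off,
                        strand = "+"), params)
  expect_equal(h2$identity, 93.75, tolerance = 0.2)
  expect_equal(c(h2$start1, h2$end1), c(r2$start1, r2$end1))
})

test_that("an inverted 80-nt repeat at 93 percent identity is detected as such", {
  fx <- generate_genome(5000, specs = list(repeat_spec(80, 93, "inverted")),
                        seed = 23)
  hits <- find_repeats(fx$genome, params)
  r <- fx$truth$repeats
  i <- which(hits$start1 == r$start1 & hits$start2 == r$start2)
  expect_length(i, 1)
  expect_equal(hits$orientation[i], "inverted")
  expect_equal(hits$length[i], 80)
  expect_equal(hits$identity[i], r$identity_realized)
})

test_that("filter_and_canonicalize enforces the cutoff and merges mirrors", {
  h <- make_hits(c(100, 400), c(149, 449), c(400, 100), c(449, 149),
                 evalue = c(1e-5, 1e-5))
  out <- filter_and_canonicalize(h, params)
  expect_equal(nrow(out), 1)  # mirror duplicates collapse
  expect_lte(out$start1, out$start2)
  # cutoff below the hit's E-value empties the list
  h$evalue <- 10
  expect_equal(nrow(filter_and_canonicalize(h, params)), 0)
  # a copy paired with itself is removed
  self <- make_hits(100, 149, 100, 149)
  expect_equal(nrow(filter_and_canonicalize(self, params)), 0)
})

test_that("perfect repeat families yield all pairwise canonical hits", {
  # four copies: flanking bases can be made pairwise distinct, so every
  # pairwise maximal alignment has exactly the planted coordinates
  fam4 <- plant_family(4)
  hits4 <- find_repeats(fam4$genome, params)
  fh4 <- hits4[hits4$length == fam4$copy_len, ]
  expect_equal(nrow(fh4), choose(4, 2))
  expect_true(all(fh4$identity == 100))
  expect_equal(count_unique_coordinates(fh4), 4)
  expect_setequal(unique(fh4$start1), fam4$starts[1:3])
  # six copies: on a 4-letter alphabet some copies must share flanking
  # bases, so some maximal alignments legitimately extend past the plant;
  # all 15 pairs are still found and the unique-coordinate count lies
  # within the theoretical family bounds
  fam6 <- plant_family(6)
  hits6 <- find_repeats(fam6$genome, params)
  fh6 <- hits6[hits6$length >= fam6$copy_len, ]
  expect_equal(nrow(fh6), choose(6, 2))
  cu <- count_unique_coordinates(fh6)
  b <- family_coordinate_bounds(6)
  expect_gte(cu, unname(b["min"]))
  expect_lte(cu, unname(b["max"]))
})

test_that("surviving hits respect the E-value cutoff and never self-pair", {
  for (sd in 1:3) {
    fx <- generate_genome(6000,
                          specs = list(repeat_spec(60, 100, "direct"),
                                       repeat_spec(45, 95, "inverted")),
                          seed = 100 + sd)
    hits <- find_repeats(fx$genome, params)
    expect_true(all(hits$evalue <= params$e_cutoff))
    expect_false(any(hits$start1 == hits$start2 & hits$end1 == hits$end2))
    expect_true(all(hits$start1 <= hits$start2))
  }
})

test_that("alignment parameter invariants are enforced", {
  expect_error(alignment_params(word_size = 3))
  expect_error(alignment_params(match = 0))
  expect_error(alignment_params(mismatch = 1))
  expect_error(alignment_params(e_cutoff = 0))
})
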