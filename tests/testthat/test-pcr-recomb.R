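test_that("a single planted shared region is recovered exactly", {
  bs <- generate_bispecies_fixture(148, 100, seed = 41)
  sur <- find_surrogate_repeats(bs$genomeA, bs$genomeB, min_len = 50,
                                min_identity = 94)
  expect_equal(nrow(sur), 1)
  expect_equal(sur$length, 148)
  expect_equal(sur$identity, 100)
  expect_equal(c(sur$startA, sur$endA, sur$startB, sur$endB),
               c(bs$truth$startA, bs$truth$endA, bs$truth$startB,
                 bs$truth$endB))
})

test_that("four planted regions spanning the surrogate size range are all recovered", {
  bs <- generate_bispecies_fixture(c(55, 90, 148, 639), c(100, 100, 94, 99),
                                   seed = 11)
  # the 148-nt region at a requested 94% realises 93.92% (9 substitutions,
  # nearest achievable), hence the slightly lower identity floor
  sur <- find_surrogate_repeats(bs$genomeA, bs$genomeB, min_len = 50,
                                min_identity = 93.5)
  expect_equal(nrow(sur), 4)
  expect_setequal(sur$length, c(55, 90, 148, 639))
  ord <- order(sur$length)
  tr <- bs$truth[order(bs$truth$length), ]
  expect_equal(sur$startA[ord], tr$startA)
  expect_equal(sur$endA[ord], tr$endA)
  expect_equal(sur$identity[ord], tr$identity_realized)
})

test_that("a shared region whose flank also matches the other genome is excluded", {
  bs <- generate_bispecies_fixture(148, 100, seed = 42)
  # copy the region's A-side upstream flank into genome B
  vB <- strsplit(bs$genomeB$seq, "")[[1]]
  src <- strsplit(bs$genomeA$seq, "")[[1]][
    (bs$truth$startA - 100):(bs$truth$startA - 1)]
  vB[5500:5599] <- src
  gB2 <- circular_genome(paste(vB, collapse = ""), id = "speciesB")
  sur <- find_surrogate_repeats(bs$genomeA, gB2, min_len = 50,
                                min_identity = 94)
  expect_equal(nrow(sur), 0)
})

test_that("expected chimeric products are hand-buildable and absent from both genomes", {
  bs <- generate_bispecies_fixture(c(148, 90), c(100, 94), seed = 43)
  tr <- bs$truth[1, ]
  s <- data.frame(startA = tr$startA, endA = tr$endA, startB = tr$startB,
                  endB = tr$endB)
  chim <- expected_chimeric_products(s, bs$genomeA, bs$genomeB, flank = 150)
  segA <- function(a, b) substr(bs$genomeA$seq, a, b)
  segB <- function(a, b) substr(bs$genomeB$seq, a, b)
  expect_identical(unname(chim["A->B"]),
                   paste0(segA(tr$startA - 150, tr$endA),
                          segB(tr$endB + 1, tr$endB + 150)))
  expect_identical(unname(chim["B->A"]),
                   paste0(segB(tr$startB - 150, tr$endB),
                          segA(tr$endA + 1, tr$endA + 150)))
  for (x in chim) {
    expect_false(grepl(x, paste0(bs$genomeA$seq, bs$genomeA$seq),
                       fixed = TRUE))
    expect_false(grepl(x, paste0(bs$genomeB$seq, bs$genomeB$seq),
                       fixed = TRUE))
  }
  # a 94%-identity region yields two variants differing only inside it
  tr2 <- bs$truth[2, ]
  s2 <- data.frame(startA = tr2$startA, endA = tr2$endA,
                   startB = tr2$startB, endB = tr2$endB)
  chim2 <- expected_chimeric_products(s2, bs$genomeA, bs$genomeB, flank = 50)
  repA <- substr(chim2[["A->B"]], 51, 50 + tr2$length)
  repB <- substr(chim2[["B->A"]], 51, 50 + tr2$length)
  nmis <- sum(strsplit(repA, "")[[1]] != strsplit(repB, "")[[1]])
  expect_equal(nmis, round(tr2$length * (1 - tr2$identity_requested / 100)))
  expect_error(expected_chimeric_products(s, bs$genomeA, bs$genomeB,
                                          flank = 10000), "flank")
})

test_that("switching limits behave: none at 0, all informative at 1, none alone", {
  expect_equal(simulate_pcr(pcr_pool(c(A = 50, B = 50), p_switch = 0),
                            seed = 1)$chimeric, 0)
  t1 <- simulate_pcr(pcr_pool(c(A = 50, B = 50), p_switch = 1), seed = 1)
  expect_gt(t1$informative, 0)
  expect_equal(t1$chimera_fraction_informative, 1)
  # a single template molecule has no partner to switch to
  expect_equal(simulate_pcr(pcr_pool(c(A = 1, B = 0), p_switch = 1),
                            seed = 1)$chimeric, 0)
  expect_error(simulate_pcr(pcr_pool(c(A = 10, B = 10)),
                            primers = c(forward = "X", reverse = "B")),
               "assay-design")
})

test_that("the simulation is reproducible under a fixed seed", {
  pl <- pcr_pool(c(A = 40, B = 40), p_switch = 0.3)
  t1 <- simulate_pcr(pl, seed = 99)
  t2 <- simulate_pcr(pl, seed = 99)
  expect_identical(t1$products, t2$products)
  t3 <- simulate_pcr(pl, seed = 100)
  expect_false(identical(t1$products, t3$products))
})

# deterministic expected-value recursion of the same cycle dynamics,
# independent of the stochastic simulator's sampling
oracle_pcr_fraction <- function(weights, cycles, p_switch, k_half = 0,
                                n_regions = 1, max_molecules = 5000,
                                fwd = "A") {
  sp <- names(weights)
  types <- c(outer(sp, sp, paste0))
  n <- setNames(numeric(4), types)
  n[paste0(sp[1], sp[1])] <- weights[[1]]
  n[paste0(sp[2], sp[2])] <- weights[[2]]
  prod <- setNames(numeric(4), types)
  left_of <- substr(types, 1, 1)
  right_of <- substr(types, 2, 2)
  for (cyc in seq_len(cycles)) {
    room <- max_molecules - sum(n)
    if (room <= 0) break
    elig <- n[left_of == fwd]
    if (sum(elig) == 0) break
    scale <- min(1, room / sum(elig))
    add <- setNames(numeric(4), types)
    for (t in names(elig)) {
      n_new <- elig[[t]] * scale
      rsp <- substr(t, 2, 2)
      other <- setdiff(sp, rsp)
      n_other <- sum(n[right_of == other])
      p_eff <- if (n_other > 0)
        p_switch * n_other / (n_other + k_half) else 0
      p_ext <- 1 - (1 - p_eff)^n_regions
      t_sw <- paste0(substr(t, 1, 1), other)
      add[t_sw] <- add[t_sw] + n_new * p_ext
      add[t] <- add[t] + n_new * (1 - p_ext)
    }
    n <- n + add
    prod <- prod + add
  }
  chim <- sum(prod[left_of != right_of])
  chim / sum(prod)
}

test_that("mean chimera fraction matches the branching-process recursion", {
  pl <- pcr_pool(c(A = 200, B = 200), cycles = 35, p_switch = 0.15)
  fr <- vapply(1:40, function(r)
    simulate_pcr(pl, seed = 1000 + r)$chimera_fraction, numeric(1))
  want <- oracle_pcr_fraction(c(A = 200, B = 200), 35, 0.15)
  tol <- 3 * stats::sd(fr) / sqrt(length(fr)) + 0.01
  expect_lt(abs(mean(fr) - want), tol)
})

test_that("expected chimera fraction is monotone in p_switch, cycles and region count", {
  base <- function(p = 0.1, cyc = 35, nr = 1)
    oracle_pcr_fraction(c(A = 100, B = 100), cyc, p, n_regions = nr)
  expect_true(all(diff(vapply(c(0, .1, .3, .6, 1), function(p) base(p = p),
                              numeric(1))) >= 0))
  expect_true(all(diff(vapply(c(5, 15, 35), function(cc) base(cyc = cc),
                              numeric(1))) >= -1e-12))
  expect_true(all(diff(vapply(1:4, function(nr) base(nr = nr),
                              numeric(1))) >= 0))
})

test_that("chimera formation increases with template concentration", {
  pl <- pcr_pool(c(A = 5, B = 5), p_switch = 0.02, k_half = 1000)
  cr <- concentration_response(pl, dilutions = c(1, 10, 70),
                               replicates = 30, seed = 77)
  m <- tapply(cr$chimera_fraction, cr$dilution, mean)
  expect_true(all(diff(m[order(as.numeric(names(m)))]) >= 0))
  expect_gt(m[["70"]], m[["1"]])
  expect_error(concentration_response(pl, dilutions = 1), "2 dilution")
})
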