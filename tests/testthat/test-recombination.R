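direct_fixture <- function(L = 20000, len = 175, seed = 7) {
  generate_genome(L, specs = list(repeat_spec(len, 100, "direct")),
                  seed = seed)
}

test_that("direct-repeat products have complementary sizes summing to L", {
  fx <- direct_fixture()
  g <- fx$genome
  r <- fx$truth$repeats
  cfg <- predict_products(g, r, flank = 300)
  expect_equal(cfg$kind, "two_subcircles")
  expect_equal(sum(cfg$product_sizes), g$length)
  expect_equal(unname(cfg$product_sizes["C->B"]), r$start2 - r$start1)
  expect_equal(nchar(cfg$products[["A->D"]]),
               unname(cfg$product_sizes["A->D"]))
  # each junction window is present in its own product (circularly) and
  # absent from the reference
  for (lab in c("A->D", "C->B")) {
    prod2 <- paste0(cfg$products[[lab]], cfg$products[[lab]])
    expect_true(grepl(cfg$junctions[[lab]]$seq, prod2, fixed = TRUE))
    expect_false(grepl(cfg$junctions[[lab]]$seq, paste0(g$seq, g$seq),
                       fixed = TRUE))
  }
})

test_that("a repeat separation of exactly L/2 yields two equal circles", {
  fx <- generate_genome(8000, specs = list(
    repeat_spec(100, 100, "direct", positions = c(1000, 5000))), seed = 8)
  cfg <- predict_products(fx$genome, fx$truth$repeats, flank = 100)
  expect_equal(unname(cfg$product_sizes), c(4000, 4000))
})

test_that("inverted-repeat prediction matches a string-built oracle and round-trips", {
  fx <- generate_genome(10000, specs = list(repeat_spec(120, 100, "inverted")),
                        seed = 9)
  g <- fx$genome
  r <- fx$truth$repeats
  cfg <- predict_products(g, r, flank = 200)
  expect_equal(cfg$kind, "inversion")
  expect_equal(unname(cfg$product_sizes), g$length)
  # oracle: A + R1 + revcomp(B) + R2 + D assembled from extracted segments
  seg <- function(a, b) substr(g$seq, a, b)
  want <- paste0(seg(1, r$end1),
                 base_revcomp(seg(r$end1 + 1, r$start2 - 1)),
                 seg(r$start2, g$length))
  expect_identical(cfg$products[["inversion"]], want)
  # double-stranded base composition is conserved: an inversion swaps the
  # segment to the complementary strand, so A+T and G+C totals are invariant
  comp <- function(s) table(factor(strsplit(s, "")[[1]],
                                   levels = c("A", "C", "G", "T")))
  t_inv <- comp(cfg$products[["inversion"]])
  t_ref <- comp(g$seq)
  expect_equal(t_inv[["A"]] + t_inv[["T"]], t_ref[["A"]] + t_ref[["T"]])
  expect_equal(t_inv[["G"]] + t_inv[["C"]], t_ref[["G"]] + t_ref[["C"]])
  # round trip: predicting across the same repeat on the product restores g
  g2 <- circular_genome(cfg$products[["inversion"]], circular = TRUE)
  cfg2 <- predict_products(g2, r, flank = 200)
  expect_identical(cfg2$products[["inversion"]], g$seq)
})

test_that("geometry and flank preconditions are enforced", {
  fx <- direct_fixture(L = 5000, len = 100)
  r <- fx$truth$repeats
  overlapping <- within(r, { start2 <- start1 + 50; end2 <- end1 + 50 })
  expect_error(predict_products(fx$genome, overlapping, flank = 10),
               "geometry")
  gap <- min((r$start2 - r$end1 - 1) %% 5000, (r$start1 - r$end2 - 1) %% 5000)
  expect_error(predict_products(fx$genome, r, flank = gap + 1), "flank")
})

test_that("design_assay places unique junction-flanking primers", {
  fx <- direct_fixture()
  cfg <- predict_products(fx$genome, fx$truth$repeats, flank = 500)
  assay <- design_assay(fx$genome, cfg, primer_len = 20, max_product = 2000)
  expect_true(all(assay$valid))
  rep_len <- fx$truth$repeats$length
  expect_equal(assay$product_size, rep(2 * 20 + rep_len, 2))
  expect_true(all(is.na(assay$reference_product)))
  expect_error(design_assay(fx$genome, cfg, primer_len = 10), ">= 15")
})

test_that("a flank duplicated elsewhere in the genome fails assay design", {
  fx <- direct_fixture(L = 10000, len = 100, seed = 12)
  r <- fx$truth$repeats
  # copy the 60 nt upstream of copy 1 to an unrelated locus
  v <- strsplit(fx$genome$seq, "")[[1]]
  src <- (r$start1 - 60):(r$start1 - 1)
  dst <- 9500:9559
  v[dst] <- v[src]
  g2 <- circular_genome(paste(v, collapse = ""))
  cfg <- predict_products(g2, r, flank = 50)
  assay <- design_assay(g2, cfg, primer_len = 20, max_product = 2000)
  bad <- assay[assay$label == "A->D", ]
  expect_false(bad$valid)
  expect_match(bad$reason, "non-unique")
})

test_that("inverted-repeat assay primers both lie on the reference plus strand", {
  fx <- generate_genome(10000, specs = list(repeat_spec(120, 100, "inverted")),
                        seed = 13)
  cfg <- predict_products(fx$genome, fx$truth$repeats, flank = 400)
  assay <- design_assay(fx$genome, cfg, primer_len = 20, max_product = 2000)
  expect_true(all(assay$valid))
  doubled <- paste0(fx$genome$seq, fx$genome$seq)
  on_plus <- function(s) grepl(s, doubled, fixed = TRUE)
  # on the reference both primers of a pair anneal to the same strand
  # (convergent only after the inversion); for the upstream-copy junction
  # both are plus-strand genomic substrings
  eg <- assay[assay$label == "E->G", ]
  expect_true(on_plus(eg$primer_fwd) && on_plus(eg$primer_rev))
  fh <- assay[assay$label == "F->H", ]
  expect_true(on_plus(base_revcomp(fh$primer_fwd)) &&
                on_plus(base_revcomp(fh$primer_rev)))
})

test_that("chimeric reads are detected exactly and reference reads ignored", {
  fx <- direct_fixture(L = 10000, len = 175, seed = 14)
  g <- fx$genome
  r <- fx$truth$repeats
  cfg <- predict_products(g, r, flank = 300)
  # planted positive: a read copied verbatim from a predicted junction
  jseq <- cfg$junctions[["A->D"]]$seq
  pos_read <- substr(jseq, 300 - 100 + 1, 300 + 175 + 100)  # 100-nt anchors
  # planted negative: a read copied from the reference
  neg_read <- substr(g$seq, 2000, 2374)
  ev <- detect_chimeric_reads(c(pos = pos_read, neg = neg_read), g, r,
                              min_anchor = 20)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$read_id, "pos")
  expect_equal(ev$label, "A->D")
  expect_equal(ev$mismatches, 0)
})

test_that("detection matches generator labels on an error-free pool", {
  fx <- direct_fixture(L = 10000, len = 175, seed = 15)
  pool <- generate_recombinant_molecules(fx$genome, fx$truth, 1, c(20, 1))
  rd <- generate_reads(pool, depth = 150, read_len = 400, seed = 16,
                       min_anchor = 20)
  ev <- detect_chimeric_reads(rd$reads, fx$genome, fx$truth$repeats,
                              min_anchor = 20)
  truth_ids <- rd$labels$read_id[rd$labels$recombinant_junction]
  expect_gt(length(truth_ids), 0)
  expect_setequal(ev$read_id, truth_ids)  # precision = recall = 1
})

test_that("configuration ratios are quantified with an undefined flag", {
  fx <- direct_fixture(L = 10000, len = 175, seed = 17)
  pool <- generate_recombinant_molecules(fx$genome, fx$truth, 1, c(25, 1))
  rd <- generate_reads(pool, depth = 200, read_len = 400, seed = 18)
  ev <- detect_chimeric_reads(rd$reads, fx$genome, fx$truth$repeats)
  q <- quantify_configurations(ev, rd$reads, fx$genome, fx$truth$repeats)
  expect_equal(q$recombinant_reads, nrow(ev))
  expect_gt(q$ref_reads, 0)
  expect_false(q$undefined)
  expect_equal(q$ratio, q$ref_reads / q$recombinant_reads)
  # no recombinant reads: flagged undefined
  q0 <- quantify_configurations(ev[0, ], rd$reads, fx$genome,
                                fx$truth$repeats)
  expect_true(q0$undefined)
  expect_true(is.na(q0$ratio))
})
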