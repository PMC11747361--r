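mk_paf <- function(qname, qlen, qstart, qend, strand, tname, tlen, tstart,
                   tend) {
  data.frame(qname = qname, qlen = qlen, qstart = qstart, qend = qend,
             strand = strand, tname = tname, tlen = tlen, tstart = tstart,
             tend = tend, nmatch = tend - tstart, alen = tend - tstart,
             mapq = 60, stringsAsFactors = FALSE)
}

test_that("bridge detection follows the two-anchor end geometry", {
  bp <- bridge_params(min_anchor = 20000, end_window = 500000, join_gap = 100)
  # B spans A1 tail -> A2 head, both forward
  paf <- rbind(
    mk_paf("B", 200000, 0, 90000, "+", "A1", 1e6, 910000, 1e6),
    mk_paf("B", 200000, 110000, 200000, "+", "A2", 1e6, 0, 90000))
  br <- detect_bridges(paf, bp)
  expect_equal(nrow(br), 1)
  expect_equal(c(br$a1, br$side1, br$orient1), c("A1", "tail", "+"))
  expect_equal(c(br$a2, br$side2, br$orient2), c("A2", "head", "+"))

  # an A2 minus-strand anchor flips the right side to the tail
  paf <- rbind(
    mk_paf("B", 200000, 0, 90000, "+", "A1", 1e6, 910000, 1e6),
    mk_paf("B", 200000, 110000, 200000, "-", "A2", 1e6, 910000, 1e6))
  br <- detect_bridges(paf, bp)
  expect_equal(c(br$a2, br$side2, br$orient2), c("A2", "tail", "-"))

  # a B aligned only to the middle of one A-scaffold is no bridge
  paf <- mk_paf("B", 200000, 0, 90000, "+", "A1", 1e6, 400000, 490000)
  expect_equal(nrow(detect_bridges(paf, bp)), 0)

  # anchors below min_anchor do not qualify
  paf <- rbind(
    mk_paf("B", 200000, 0, 10000, "+", "A1", 1e6, 990000, 1e6),
    mk_paf("B", 200000, 110000, 200000, "+", "A2", 1e6, 0, 90000))
  expect_equal(nrow(detect_bridges(paf, bp)), 0)

  # anchors outside the end window do not qualify
  paf <- rbind(
    mk_paf("B", 200000, 0, 90000, "+", "A1", 2e6, 910000, 1e6),
    mk_paf("B", 200000, 110000, 200000, "+", "A2", 1e6, 0, 90000))
  expect_equal(nrow(detect_bridges(paf, bp)), 0)
})

test_that("bridge application joins with 100 Ns and drops conflicts", {
  set.seed(61)
  a <- c(A1 = random_seq(5000), A2 = random_seq(4000), A3 = random_seq(3000))
  bp <- bridge_params(min_anchor = 100, end_window = 1000, join_gap = 100)
  b1 <- data.frame(bridge_id = "B1", a1 = "A1", side1 = "tail", orient1 = "+",
                   a2 = "A2", side2 = "head", orient2 = "+",
                   support_bases = 5000, stringsAsFactors = FALSE)
  res <- apply_bridges(a, b1, bp)
  expect_equal(length(res$sequences), 2)
  expect_equal(nchar(res$sequences[["superscaffold_0001"]]),
               5000 + 100 + 4000)
  expect_equal(res$sequences[["A3"]], a[["A3"]])

  # two bridges claiming A1 tail with different partners: all dropped
  b2 <- rbind(b1, transform(b1, bridge_id = "B2", a2 = "A3"))
  res <- apply_bridges(a, b2, bp)
  expect_equal(nrow(res$dropped), 2)
  expect_equal(sort(names(res$sequences)), c("A1", "A2", "A3"))

  # consistent chain A1 -> A2 -> A3 becomes one three-part super-scaffold
  b3 <- rbind(b1, data.frame(bridge_id = "B3", a1 = "A2", side1 = "tail",
                             orient1 = "+", a2 = "A3", side2 = "head",
                             orient2 = "+", support_bases = 4000,
                             stringsAsFactors = FALSE))
  res <- apply_bridges(a, b3, bp)
  expect_equal(length(res$sequences), 1)
  expect_equal(nchar(res$sequences[[1]]), 5000 + 100 + 4000 + 100 + 3000)
  expect_equal(count_acgt(res$sequences), count_acgt(a))
})

test_that("bridging reconstructs a known scaffold order with zero errors", {
  truth <- simulate_genome(1, 4e5, seed = 71)
  fa <- fragment_genome(truth, n_contigs = 5, min_gap = 100, max_gap = 400,
                        seed = 72, flip_prob = 0.4, prefix = "A")
  fb <- midpoint_fragmentation(fa)
  paf <- sim_cross_paf(fa, fb, min_block = 1000)
  bp <- bridge_params(min_anchor = 5000, end_window = 200000, join_gap = 100)
  br <- detect_bridges(paf, bp)
  res <- apply_bridges(fa$contigs, br, bp)
  joins <- layout_joins(res$layouts)
  expect_equal(length(joins), nrow(fa$adjacencies))     # every gap bridged
  expect_true(all(joins %in% truth_join_keys(fa)))      # zero errors
  expect_equal(count_acgt(res$sequences), count_acgt(fa$contigs))
})

test_that("bridge application is order-independent and deterministic", {
  truth <- simulate_genome(1, 3e5, seed = 81)
  fa <- fragment_genome(truth, n_contigs = 4, min_gap = 100, max_gap = 300,
                        seed = 82, prefix = "A")
  fb <- midpoint_fragmentation(fa)
  paf <- sim_cross_paf(fa, fb, min_block = 1000)
  bp <- bridge_params(min_anchor = 5000, end_window = 200000, join_gap = 100)
  br <- detect_bridges(paf, bp)
  r1 <- apply_bridges(fa$contigs, br, bp)
  set.seed(83)
  r2 <- apply_bridges(fa$contigs, br[sample(nrow(br)), ], bp)
  expect_identical(r1$layouts, r2$layouts)
  expect_identical(r1$sequences, r2$sequences)
})

test_that("reference anchoring assigns, orients, orders, and reports unplaced", {
  seqs <- c(ss1 = strrep("ACGT", 2500), ss2 = strrep("ACGT", 2500),
            ss3 = strrep("ACGT", 2500))
  paf <- rbind(
    # ss1: 80% of aligned bases on chr2, majority strand -
    mk_paf("ss1", 10000, 0, 8000, "-", "chr2", 5e7, 4e7, 4e7 + 8000),
    mk_paf("ss1", 10000, 8000, 10000, "+", "chr1", 5e7, 0, 2000),
    # ss2: all on chr2, earlier position
    mk_paf("ss2", 10000, 0, 9000, "+", "chr2", 5e7, 5e6, 5e6 + 9000),
    # ss3: 25/25/50 split; only the 50% share passes min_cov_frac
    mk_paf("ss3", 10000, 0, 2500, "+", "chr1", 5e7, 0, 2500),
    mk_paf("ss3", 10000, 2500, 5000, "+", "chr3", 5e7, 0, 2500),
    mk_paf("ss3", 10000, 5000, 10000, "+", "chr4", 5e7, 0, 5000))
  res <- anchor_to_reference(paf, seqs, min_cov_frac = 0.3, join_gap = 100)
  asn <- res$assignments
  expect_equal(asn$chromosome[asn$seq_id == "ss1"], "chr2")
  expect_equal(asn$orientation[asn$seq_id == "ss1"], "-")
  expect_equal(asn$chromosome[asn$seq_id == "ss3"], "chr4")
  # within chr2, ss2 (5 Mb) precedes ss1 (40 Mb)
  chr2 <- res$layouts[res$layouts$scaffold_id == "chr2", ]
  expect_equal(chr2$component, c("ss2", "ss1"))
  expect_equal(nchar(res$sequences[["chr2"]]), 10000 + 100 + 10000)

  # below-threshold sequences are unplaced
  paf2 <- rbind(
    mk_paf("ss1", 10000, 0, 2500, "+", "chr1", 5e7, 0, 2500),
    mk_paf("ss1", 10000, 2500, 5000, "+", "chr2", 5e7, 0, 2500),
    mk_paf("ss1", 10000, 5000, 7400, "+", "chr3", 5e7, 0, 2400),
    mk_paf("ss1", 10000, 7500, 10000, "+", "chr4", 5e7, 0, 2500))
  res2 <- anchor_to_reference(paf2, seqs["ss1"], min_cov_frac = 0.3)
  expect_equal(res2$unplaced, "ss1")
})
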