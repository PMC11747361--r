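# Hand-written VCF for filter tests: 10 samples, sites exercising each rule.
write_test_vcf <- function(path, records, samples = sprintf("s%02d", 1:10)) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
}

gtline <- function(pos, qual, gts, dp = 30, ref = "A", alt = "T") {
  paste(c("chr1", pos, ".", ref, alt, qual, "PASS", ".", "GT:DP",
          paste0(gts, ":", dp)), collapse = "\t")
}

test_that("SNP filtering applies QUAL, frequency, depth, and call-rate rules", {
  f <- withr::local_tempfile(fileext = ".vcf")
  gts_common <- c(rep("0/1", 5), rep("0/0", 5))
  low_freq <- c(rep("0/0", 49), "0/1")  # af 0.01 with 50 samples
  recs <- c(
    gtline(100, 999, gts_common),                    # kept
    gtline(200, 150, gts_common),                    # QUAL 150 < 200
    gtline(300, 999, c(rep("0/1", 1), rep("0/0", 9)),
           dp = 30),                                 # af 0.05: kept (boundary)
    gtline(400, 999, gts_common, dp = 4),            # all DP-masked
    gtline(500, 999, c(rep("0/1:30", 7), rep("./.:30", 3)),
           dp = NULL)                                # call rate 0.7 < 0.8
  )
  # the DP-embedded record needs raw formatting
  recs[5] <- paste(c("chr1", 500, ".", "A", "T", 999, "PASS", ".", "GT:DP",
                     c(rep("0/1:30", 7), rep("./.:30", 3))), collapse = "\t")
  write_test_vcf(f, recs)
  pops <- data.frame(sample = sprintf("s%02d", 1:10),
                     population = rep(c("p1", "p2"), each = 5))
  gm <- filter_snps(f, snp_filter_params(), popmap = pops)
  expect_equal(gm$pos0 + 1, c(100, 300))

  # call rate exactly 0.8 is kept
  recs2 <- paste(c("chr1", 600, ".", "A", "T", 999, "PASS", ".", "GT:DP",
                   c(rep("0/1:30", 8), rep("./.:30", 2))), collapse = "\t")
  write_test_vcf(f, c(recs2))
  gm2 <- filter_snps(f, snp_filter_params(), popmap = pops)
  expect_equal(length(gm2$pos0), 1)

  # low-frequency site removed (alt frequency 0.04 < 0.05)
  f50 <- withr::local_tempfile(fileext = ".vcf")
  s50 <- sprintf("t%02d", 1:50)
  rec_lf <- paste(c("chr1", 700, ".", "A", "T", 999, "PASS", ".", "GT:DP",
                    paste0(c(rep("0/0", 46), rep("0/1", 4)), ":30")),
                  collapse = "\t")
  write_test_vcf(f50, rec_lf, samples = s50)
  gm3 <- filter_snps(f50, snp_filter_params(),
                     popmap = data.frame(sample = s50,
                                         population = rep(c("p1", "p2"), 25)))
  expect_equal(length(gm3$pos0), 0)
})

test_that("SNP filtering output does not depend on record order", {
  sim <- simulate_two_pop_genotypes(200, 10, fst_target = 0.05, seed = 14,
                                    chrom_len = 1e6)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_sim_vcf(sim, f)
  lines <- readLines(f)
  hdr <- grepl("^#", lines)
  f2 <- withr::local_tempfile(fileext = ".vcf")
  set.seed(3)
  writeLines(c(lines[hdr], sample(lines[!hdr])), f2)
  gm1 <- filter_snps(f, popmap = sim$popmap)
  gm2 <- filter_snps(f2, popmap = sim$popmap)
  expect_identical(gm1, gm2)
})

test_that("Tajima's D matches the published worked example and sign rules", {
  # 4 haplotypes AAA, AAT, ATT, TTT: 3 segregating sites
  hap <- matrix(c(0, 0, 0,
                  0, 0, 1,
                  0, 1, 1,
                  1, 1, 1), nrow = 3)
  expect_equal(tajima_d(hap, ploidy = 1), oracle_tajima(hap),
               tolerance = 1e-12)
  expect_equal(tajima_d(hap, ploidy = 1), 0.1676, tolerance = 1e-3)

  # no segregating sites -> missing
  expect_true(is.na(tajima_d(matrix(0, nrow = 4, ncol = 6), ploidy = 1)))

  # 10 haplotypes, 5 singleton sites -> negative
  sing <- matrix(0L, nrow = 5, ncol = 10)
  for (i in 1:5) sing[i, i] <- 1L
  expect_lt(tajima_d(sing, ploidy = 1), 0)
})

test_that("Weir-Cockerham F_ST matches fixed points and the locked fixture", {
  pops <- rep(c("p1", "p2"), each = 10)
  fixed <- matrix(c(rep(2L, 10), rep(0L, 10)), nrow = 1)
  expect_equal(wc_fst(fixed, pops), 1.0)

  mono <- matrix(0L, nrow = 3, ncol = 20)
  expect_true(is.na(wc_fst(mono, pops)))

  expect_error(wc_fst(fixed, rep(c("a", "b", "c"), length.out = 20)),
               "exactly 2")

  # regression fixture: pop1 = 0/0 x3 + 0/1 x2, pop2 = 1/1 x3 + 0/1 x2
  g <- matrix(c(0, 0, 0, 1, 1, 2, 2, 2, 1, 1), nrow = 1)
  p <- rep(c("p1", "p2"), each = 5)
  expect_equal(wc_fst(g, p), oracle_wc_fst(g, p), tolerance = 1e-12)
  expect_equal(wc_fst(g, p), 0.165 / 0.34, tolerance = 1e-12)
})

test_that("D and F_ST agree with brute-force oracles on random windows", {
  set.seed(202)
  for (i in 1:60) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    S <- sample(2:12, 1)
    gt <- matrix(sample(0:2, S * (n1 + n2), replace = TRUE,
                        prob = c(0.5, 0.3, 0.2)), nrow = S)
    pops <- rep(c("a", "b"), c(n1, n2))
    if (i %% 3 == 0) gt[sample(length(gt), S)] <- NA   # missing genotypes
    expect_equal(wc_fst(gt, pops), oracle_wc_fst(gt, pops),
                 tolerance = 1e-9)
    # complete-data haplotype window for the D oracle
    hap <- matrix(sample(0:1, S * 2 * n1, replace = TRUE), nrow = S)
    expect_equal(tajima_d(hap, ploidy = 1), oracle_tajima(hap),
                 tolerance = 1e-9)
  }
})

test_that("F_ST stays within estimator bounds on random inputs", {
  set.seed(303)
  for (i in 1:200) {
    S <- sample(1:10, 1)
    gt <- matrix(sample(0:2, S * 12, replace = TRUE), nrow = S)
    v <- wc_fst(gt, rep(c("a", "b"), each = 6))
    if (!is.na(v)) {
      expect_gte(v, -0.5)
      expect_lte(v, 1)
    }
  }
})

test_that("window tiling follows half-open 100-kb windows with a partial tail", {
  sim <- simulate_two_pop_genotypes(50, 8, seed = 5, chrom_len = 240000)
  gm <- sim$gm
  # place one SNP exactly at position 100,000 (0-based)
  gm$pos0[25] <- 100000
  gm$pos0 <- sort(gm$pos0)
  ws <- window_scan(gm, scan_params(window = 100000),
                    seq_lengths = c(chr_sim = 250000))
  expect_equal(nrow(ws), 3)
  expect_equal(ws$start, c(0, 100000, 200000))
  expect_equal(ws$end, c(100000, 200000, 250000))
  expect_equal(sum(ws$n_snps), 50)
  w2 <- ws$n_snps[2]
  expect_gte(w2, 1)   # the boundary SNP counts in the second window

  # empty matrix: all-missing windows
  gm0 <- gm
  keep <- rep(FALSE, length(gm$pos0))
  gm0$chrom <- gm$chrom[keep]; gm0$pos0 <- gm$pos0[keep]
  gm0$gt <- gm$gt[keep, , drop = FALSE]
  ws0 <- window_scan(gm0, scan_params(window = 100000),
                     seq_lengths = c(chr_sim = 250000))
  expect_true(all(is.na(ws0$fst)))
  expect_true(all(ws0$n_snps == 0))
})

test_that("permutation outliers flag a planted window and honour alpha", {
  sim <- simulate_two_pop_genotypes(
    600, 20, fst_target = 0, seed = 9, chrom_len = 2e6,
    outlier_windows = cbind(500000, 600000))
  sp <- scan_params(window = 1e5, n_perm = 300, alpha = 0.01, seed = 10)
  ws <- window_scan(sim$gm, sp, seq_lengths = c(chr_sim = 2e6))
  planted <- which(ws$start == 500000)
  expect_equal(ws$fst[planted], 1.0)    # fixed differences before testing
  po <- permutation_outliers(ws, sim$gm, sp)
  expect_true(po$flag_fst[planted])
  # planted fixed differences have no within-population variation: low D
  expect_true(po$flag_intersect_pop1[planted] || po$flag_intersect_pop2[planted] ||
                all(is.na(ws[planted, c("tajima_d_pop1", "tajima_d_pop2")])))
  # null windows are mostly unflagged (binomial tolerance at alpha = 0.01)
  expect_lte(sum(po$flag_fst[-planted], na.rm = TRUE), 2)

  # alpha = 1 flags every window with a non-missing statistic
  po1 <- permutation_outliers(ws, sim$gm,
                              scan_params(window = 1e5, n_perm = 50,
                                          alpha = 1, seed = 11))
  expect_true(all(po1$flag_fst[!is.na(po1$p_fst_high)]))
})

test_that("degenerate sample sizes warn and give p = 1", {
  gm <- structure(list(chrom = rep("c", 3), pos0 = c(10, 20, 30),
                       gt = matrix(c(0L, 2L, 1L, 2L, 0L, 1L), nrow = 3,
                                   dimnames = list(NULL, c("x", "y"))),
                       samples = c("x", "y"),
                       pops = c(x = "a", y = "b")),
                  class = "genotype_matrix")
  sp <- scan_params(window = 100, n_perm = 20, alpha = 0.5, seed = 2)
  ws <- window_scan(gm, sp, seq_lengths = c(c = 100))
  expect_warning(po <- permutation_outliers(ws, gm, sp), "permutation")
  expect_true(all(po$p_fst_high[!is.na(po$p_fst_high)] == 1))
})
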