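test_that("genome simulation is deterministic and plants verifiable features", {
  t1 <- simulate_genome(1, 1e5, "TTTAGGG", repeat_density = 0, seed = 7)
  t2 <- simulate_genome(1, 1e5, "TTTAGGG", repeat_density = 0, seed = 7)
  expect_identical(t1, t2)
  t3 <- simulate_genome(1, 1e5, "TTTAGGG", repeat_density = 0, seed = 8)
  expect_false(identical(t1$genome, t3$genome))
  expect_equal(nrow(t1$repeats), 0)

  hits <- telomere_scan(t1$genome)
  expect_setequal(hits$side, c("head", "tail"))

  t4 <- simulate_genome(1, 1e6, repeat_density = 50, seed = 9)
  expect_equal(nrow(t4$repeats), 50)
  # recorded repeat intervals contain the cassette verbatim
  s <- t4$genome[["chr1"]]
  iv <- t4$repeats[1, ]
  cassette <- substr(s, iv$start + 1, iv$end)
  expect_equal(nchar(cassette), 500)
  last <- t4$repeats[nrow(t4$repeats), ]
  # non-overlapping placements carry identical cassette copies
  if (last$start >= iv$end + 500) {
    expect_equal(substr(s, last$start + 1, last$end), cassette)
  }
})

test_that("fragmentation conserves the genome through contigs plus gaps", {
  truth <- simulate_genome(2, 1e5, seed = 12)
  frag <- fragment_genome(truth, n_contigs = 5, min_gap = 50, max_gap = 200,
                          seed = 13)
  expect_equal(nrow(frag$adjacencies), 2 * 4)
  for (cn in names(truth$genome)) {
    m <- frag$map[frag$map$chrom == cn, ]
    m <- m[order(m$gstart), ]
    rebuilt <- character(0)
    pos <- 0
    for (i in seq_len(nrow(m))) {
      expect_equal(m$gstart[i] >= pos, TRUE)
      gap_seq <- substr(truth$genome[[cn]], pos + 1, m$gstart[i])
      seg <- frag$contigs[[m$contig[i]]]
      if (m$flipped[i]) seg <- revcomp(seg)
      rebuilt <- c(rebuilt, gap_seq, seg)
      pos <- m$gend[i]
    }
    rebuilt <- paste(c(rebuilt,
                       substr(truth$genome[[cn]], pos + 1,
                              nchar(truth$genome[[cn]]))), collapse = "")
    expect_identical(rebuilt, truth$genome[[cn]])
  }
  frag2 <- fragment_genome(truth, n_contigs = 5, min_gap = 50, max_gap = 200,
                           seed = 14)
  expect_false(identical(frag$map$gstart, frag2$map$gstart))
  expect_error(fragment_genome(truth, 3, 6e4, 6e4, seed = 1), "exceed")
})

test_that("simulated reads are exact substrings at zero error, noisy otherwise", {
  truth <- simulate_genome(1, 1e5, seed = 17)
  reads <- simulate_long_reads(truth, 20, mean_len = 5000, len_sd = 300,
                               error_rate = 0, seed = 18)
  g <- truth$genome[["chr1"]]
  for (i in seq_len(nrow(reads))) {
    sub <- substr(g, reads$gstart[i] + 1, reads$gend[i])
    want <- if (reads$strand[i] == "-") revcomp(sub) else sub
    expect_identical(reads$sequence[i], unname(want))
  }
  expect_true(all(reads$mean_qv == 60))

  noisy <- simulate_long_reads(truth, 10, mean_len = 5000, error_rate = 0.01,
                               seed = 19)
  expect_true(all(noisy$mean_qv == 20))   # Phred of 1% error
  r1 <- noisy[1, ]
  sub <- substr(g, r1$gstart + 1, r1$gend)
  if (r1$strand == "-") sub <- revcomp(sub)
  mism <- sum(strsplit(r1$sequence, "")[[1]] != strsplit(sub, "")[[1]])
  expect_gt(mism, 0)
  expect_lt(mism / r1$length, 0.05)
})

test_that("gap-spanning read placement covers a true gap with both flanks", {
  truth <- simulate_genome(1, 2e5, seed = 27)
  frag <- fragment_genome(truth, 4, min_gap = 100, max_gap = 400, seed = 28)
  reads <- simulate_long_reads(truth, 30, mean_len = 12000, seed = 29,
                               span_gaps = TRUE, frag = frag, min_flank = 2000)
  gmap <- frag$map
  spans <- vapply(seq_len(nrow(reads)), function(i) {
    any(gmap$gend >= reads$gstart[i] + 2000 &
          gmap$gend <= reads$gend[i] - 2000 &
          gmap$chrom == reads$chrom[i])
  }, logical(1))
  expect_true(all(spans))
})

test_that("genome intervals lift onto contigs through clips and flips", {
  truth <- simulate_genome(1, 1e6, repeat_density = 30, seed = 57)
  frag <- fragment_genome(truth, 6, min_gap = 100, max_gap = 300, seed = 58,
                          flip_prob = 0.5)
  lifted <- lift_to_contigs(frag, truth$repeats)
  expect_gt(nrow(lifted), 0)
  # every fully-contained lifted cassette carries the cassette sequence
  # (up to reverse complement on flipped contigs)
  g <- truth$genome[["chr1"]]
  full <- lifted[lifted$end - lifted$start == 500, , drop = FALSE]
  expect_gt(nrow(full), 0)
  ref <- NULL
  for (i in seq_len(nrow(full))) {
    iv <- full[i, ]
    seg <- substr(frag$contigs[[iv$seq_id]], iv$start + 1, iv$end)
    flipped <- frag$map$flipped[match(iv$seq_id, frag$map$contig)]
    if (flipped) seg <- revcomp(seg)
    if (is.null(ref)) ref <- seg
    expect_identical(unname(seg), unname(ref))
  }
  # repeat-aware target design runs directly on the lifted intervals
  tg <- design_targets(frag$contigs, lifted,
                       target_params(mode = "repeat_aware"))
  expect_true(all(tg$repeat_fraction < 0.5))
})

test_that("Balding-Nichols genotypes hit the target F_ST in expectation", {
  sp <- scan_params(window = 1e5, n_perm = 10, seed = 1)
  sim0 <- simulate_two_pop_genotypes(2000, 50, fst_target = 0, seed = 31,
                                     chrom_len = 5e6)
  ws0 <- window_scan(sim0$gm, sp, seq_lengths = c(chr_sim = 5e6))
  expect_lt(abs(mean(ws0$fst, na.rm = TRUE)), 0.02)

  sim1 <- simulate_two_pop_genotypes(2000, 50, fst_target = 0.1, seed = 32,
                                     chrom_len = 5e6)
  ws1 <- window_scan(sim1$gm, sp, seq_lengths = c(chr_sim = 5e6))
  expect_lt(abs(mean(ws1$fst, na.rm = TRUE) - 0.1), 0.02)

  # planted fixed-difference window reaches theta-hat = 1 by construction
  simo <- simulate_two_pop_genotypes(1000, 20, fst_target = 0, seed = 33,
                                     chrom_len = 1e6,
                                     outlier_windows = cbind(0, 1e5))
  wso <- window_scan(simo$gm, sp, seq_lengths = c(chr_sim = 1e6))
  expect_equal(wso$fst[1], 1.0)
})

test_that("simulator VCF output is deterministic and filter-compatible", {
  sim <- simulate_two_pop_genotypes(100, 8, fst_target = 0.05, seed = 41,
                                    chrom_len = 1e6)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_sim_vcf(sim, f1)
  write_sim_vcf(sim, f2)
  expect_identical(readLines(f1), readLines(f2))
  gm <- filter_snps(f1, popmap = sim$popmap)
  # default QUAL/DP pass the filters; only the frequency rule can drop sites
  kept <- sim$gm$pos0 %in% gm$pos0
  expect_true(all(gm$gt == sim$gm$gt[kept, ]))
})
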