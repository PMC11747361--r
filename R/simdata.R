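# Seeded synthetic-data generators: every pipeline stage gets a truth-known
# input with no external downloads. All generators are pure functions of
# their parameters and seed.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome with telomeres and interspersed repeats
#'
#' Uniform-random DNA with telomere motif arrays at both ends of every
#' chromosome (the tail end carries the reverse-complement array, as on a
#' real forward strand) and a fixed 500-bp repeat cassette copied at
#' `repeat_density` per Mb, with every placement recorded as a repeat
#' interval.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp (>= 50 kb).
#' @param telomere_motif Telomere repeat motif (default the plant repeat
#'   `"TTTAGGG"`).
#' @param repeat_density Cassette copies per Mb (may be 0).
#' @param seed RNG seed.
#' @param telomere_copies Motif copies per telomere array (default 50).
#' @return List of class `sim_genome_truth`: `genome` (named sequences),
#'   `telomeres` (intervals), `repeats` (intervals), `motif`, `params`.
#' @export
simulate_genome <- function(n_chrom, chrom_len, telomere_motif = "TTTAGGG",
                            repeat_density = 0, seed = 1L,
                            telomere_copies = 50) {
  stopifnot(chrom_len >= 50000, n_chrom >= 1, telomere_copies >= 30)
  set.seed(seed)
  tel_head <- strrep(telomere_motif, telomere_copies)
  tel_tail <- strrep(revcomp(telomere_motif), telomere_copies)
  tel_len <- nchar(tel_head)
  cassette <- random_dna(500)
  genome <- character(0)
  tel_rows <- list()
  rep_rows <- list()
  for (ci in seq_len(n_chrom)) {
    cn <- paste0("chr", ci)
    s <- random_dna(chrom_len)
    substr(s, 1, tel_len) <- tel_head
    substr(s, chrom_len - tel_len + 1, chrom_len) <- tel_tail
    n_rep <- round(repeat_density * chrom_len / 1e6)
    if (n_rep > 0) {
      lo <- tel_len + 1
      hi <- chrom_len - tel_len - 500
      pos <- sort(sample(lo:hi, n_rep))
      for (p in pos) {
        substr(s, p, p + 499) <- cassette
        rep_rows[[length(rep_rows) + 1]] <- data.frame(
          seq_id = cn, start = p - 1, end = p + 499, label = "cassette",
          stringsAsFactors = FALSE)
      }
    }
    genome[[cn]] <- s
    tel_rows[[length(tel_rows) + 1]] <- data.frame(
      seq_id = cn, start = c(0, chrom_len - tel_len),
      end = c(tel_len, chrom_len), label = c("tel_head", "tel_tail"),
      stringsAsFactors = FALSE)
  }
  structure(list(
    genome = genome,
    telomeres = do.call(rbind, tel_rows),
    repeats = if (length(rep_rows) > 0) do.call(rbind, rep_rows) else
      data.frame(seq_id = character(0), start = numeric(0), end = numeric(0),
                 label = character(0), stringsAsFactors = FALSE),
    motif = telomere_motif,
    params = list(n_chrom = n_chrom, chrom_len = chrom_len, seed = seed,
                  repeat_density = repeat_density,
                  telomere_copies = telomere_copies)),
    class = "sim_genome_truth")
}

#' Fragment a simulated genome into contigs with withheld gaps
#'
#' Cut points are drawn uniformly (minimum contig length enforced); adjacent
#' contigs are separated by gaps drawn from `[min_gap, max_gap]` whose
#' sequence is withheld from the contigs. The truth records every contig's
#' genome interval, optional reverse-complement flip, and the adjacency list
#' with true gap sizes, so concatenating contigs and gap sequence reproduces
#' the genome exactly.
#'
#' @param truth A `sim_genome_truth` from [simulate_genome()].
#' @param n_contigs Contigs per chromosome (>= 2).
#' @param min_gap,max_gap Gap-size range in bp.
#' @param seed RNG seed.
#' @param flip_prob Probability that a contig is stored reverse-complemented
#'   (default 0).
#' @param prefix Contig-name infix, e.g. `"A"` gives `chr1_A01`.
#' @return List of class `sim_fragmentation`: `contigs` (named sequences),
#'   `map` (contig genome intervals and flips), `adjacencies` (`contig1`,
#'   `side1`, `contig2`, `side2`, `gap`), `truth` (the parent genome truth).
#' @export
fragment_genome <- function(truth, n_contigs, min_gap, max_gap, seed = 1L,
                            flip_prob = 0, prefix = "ctg") {
  stopifnot(inherits(truth, "sim_genome_truth"), n_contigs >= 2,
            min_gap >= 1, max_gap >= min_gap)
  set.seed(seed)
  contigs <- character(0)
  map_rows <- list()
  adj_rows <- list()
  for (cn in names(truth$genome)) {
    s <- truth$genome[[cn]]
    L <- nchar(s)
    gaps <- floor(stats::runif(n_contigs - 1, min_gap, max_gap + 1))
    remaining <- L - sum(gaps)
    if (remaining < n_contigs) {
      stop("gaps exceed chromosome length on ", cn)
    }
    m0 <- min(5000, remaining %/% (2 * n_contigs))
    avail <- remaining - n_contigs * m0
    inner <- if (n_contigs > 1) sort(sample.int(avail - 1, n_contigs - 1)) else numeric(0)
    lens <- m0 + diff(c(0, inner, avail))
    pos <- 0
    flips <- stats::runif(n_contigs) < flip_prob
    ids <- sprintf("%s_%s%02d", cn, prefix, seq_len(n_contigs))
    for (j in seq_len(n_contigs)) {
      seg <- substr(s, pos + 1, pos + lens[j])
      contigs[[ids[j]]] <- if (flips[j]) revcomp(seg) else seg
      map_rows[[length(map_rows) + 1]] <- data.frame(
        contig = ids[j], chrom = cn, gstart = pos, gend = pos + lens[j],
        flipped = flips[j], stringsAsFactors = FALSE)
      if (j < n_contigs) {
        adj_rows[[length(adj_rows) + 1]] <- data.frame(
          contig1 = ids[j], side1 = if (flips[j]) "head" else "tail",
          contig2 = ids[j + 1], side2 = if (flips[j + 1]) "tail" else "head",
          gap = gaps[j], stringsAsFactors = FALSE)
        pos <- pos + lens[j] + gaps[j]
      }
    }
  }
  structure(list(contigs = contigs, map = do.call(rbind, map_rows),
                 adjacencies = do.call(rbind, adj_rows), truth = truth),
            class = "sim_fragmentation")
}

#' Simulate long reads from a genome truth
#'
#' Reads are sampled from the full genome (so some span withheld gaps),
#' lengths are normal-truncated, substitution errors are applied at
#' `error_rate`, the quality string is constant at the Phred equivalent of
#' the error rate (so mean-quality filtering is exact), and strand is
#' random. Each read's origin is recorded in its id and in the returned
#' columns for truth evaluation. With `span_gaps = TRUE` (requires `frag`)
#' read positions are drawn so each read crosses a true inter-contig gap
#' with at least `min_flank` bases on both sides -- the reads gap-targeted
#' sequencing is designed to enrich.
#'
#' @param truth A `sim_genome_truth`.
#' @param n_reads Number of reads.
#' @param mean_len,len_sd Read-length distribution (bp).
#' @param error_rate Per-base substitution rate (0 to < 0.2).
#' @param seed RNG seed.
#' @param span_gaps Place every read across a true gap.
#' @param frag A `sim_fragmentation` (required when `span_gaps`).
#' @param min_flank Minimum read bases on each side of the spanned gap.
#' @return data.frame in [read_fastq()] layout plus origin columns `chrom`,
#'   `gstart`, `gend`, `strand`.
#' @export
simulate_long_reads <- function(truth, n_reads, mean_len, len_sd = 0,
                                error_rate = 0, seed = 1L, span_gaps = FALSE,
                                frag = NULL, min_flank = 3000) {
  stopifnot(inherits(truth, "sim_genome_truth"), mean_len > 0,
            error_rate >= 0, error_rate < 0.2)
  set.seed(seed)
  clens <- nchar(truth$genome)
  q <- if (error_rate == 0) 60L else as.integer(round(-10 * log10(error_rate)))
  qchar <- intToUtf8(q + 33L)

  if (span_gaps) {
    stopifnot(inherits(frag, "sim_fragmentation"))
    adj <- frag$adjacencies
    gmap <- frag$map
    gap_start <- gmap$gend[match(adj$contig1, gmap$contig)]
    gap_end <- gmap$gstart[match(adj$contig2, gmap$contig)]
    gap_chrom <- gmap$chrom[match(adj$contig1, gmap$contig)]
    pick <- rep_len(seq_len(nrow(adj)), n_reads)
  }

  rows <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    len <- max(100, round(stats::rnorm(1, mean_len, len_sd)))
    if (span_gaps) {
      a <- pick[i]
      need <- (gap_end[a] - gap_start[a]) + 2 * min_flank
      len <- max(len, need)
      cn <- gap_chrom[a]
      lo <- max(0, gap_end[a] + min_flank - len)
      hi <- min(clens[[cn]] - len, gap_start[a] - min_flank)
      if (hi < lo) hi <- lo
      start <- floor(stats::runif(1, lo, hi + 1))
    } else {
      cn <- sample(names(clens), 1)
      len <- min(len, clens[[cn]])
      start <- floor(stats::runif(1, 0, clens[[cn]] - len + 1))
    }
    s <- substr(truth$genome[[cn]], start + 1, start + len)
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") s <- revcomp(s)
    if (error_rate > 0) {
      nerr <- stats::rbinom(1, len, error_rate)
      if (nerr > 0) {
        pos <- sample.int(len, nerr)
        ch <- strsplit(s, "")[[1]]
        ch[pos] <- vapply(ch[pos], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
        s <- paste(ch, collapse = "")
      }
    }
    rows[[i]] <- data.frame(
      id = sprintf("read%06d|%s:%d-%d|%s", i, cn, start, start + len, strand),
      sequence = s, quality = strrep(qchar, len), length = len,
      mean_qv = as.numeric(q), chrom = cn, gstart = start,
      gend = start + len, strand = strand, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a toy k-mer multiplicity histogram
#'
#' A spectral model of counting k-mers in reads at a given coverage: each of
#' the genome's distinct k-mers receives a Poisson multiplicity with mean
#' `coverage * (1 - error_rate)^k`, and sequencing errors contribute
#' (approximately unique) k-mers at multiplicity 1. This emulates the
#' histogram a k-mer counter would produce, without counting.
#'
#' @param genome_size Genome size in bp (or a `sim_genome_truth`, whose
#'   total length is used).
#' @param coverage Sequencing depth (fold).
#' @param error_rate Per-base error rate.
#' @param k k-mer length (default 21).
#' @param seed RNG seed.
#' @return A `kmer_histogram`.
#' @export
simulate_kmer_histogram <- function(genome_size, coverage, error_rate = 0,
                                    k = 21, seed = 1L) {
  if (inherits(genome_size, "sim_genome_truth")) {
    genome_size <- sum(nchar(genome_size$genome))
  }
  set.seed(seed)
  lambda <- coverage * (1 - error_rate)^k
  mult <- stats::rpois(genome_size - k + 1, lambda)
  tab <- table(mult[mult > 0])
  m <- as.integer(names(tab))
  cnt <- as.numeric(tab)
  n_err <- round(coverage * genome_size * (1 - (1 - error_rate)^k))
  if (n_err > 0) {
    if (1 %in% m) {
      cnt[m == 1] <- cnt[m == 1] + n_err
    } else {
      m <- c(1L, m)
      cnt <- c(n_err, cnt)
    }
  }
  kmer_histogram(m, cnt, k = k)
}

#' Simulated truth alignments of reads onto contigs
#'
#' Converts known read origins into the PAF records an aligner would report
#' against the fragmented contigs: each overlap of a read's genome interval
#' with a contig's genome interval becomes one alignment block, with query
#' and target coordinates mapped through the read strand and any contig
#' flip.
#'
#' @param frag A `sim_fragmentation`.
#' @param reads Read table from [simulate_long_reads()] (origin columns
#'   required).
#' @param min_block Minimum overlap to report (bp, default 100).
#' @return PAF data.frame ([read_paf()] layout).
#' @export
sim_read_alignments <- function(frag, reads, min_block = 100) {
  gmap <- frag$map
  clens <- nchar(frag$contigs)
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    cand <- gmap[gmap$chrom == r$chrom & gmap$gstart < r$gend &
                 gmap$gend > r$gstart, , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      ct <- cand[j, ]
      os <- max(r$gstart, ct$gstart)
      oe <- min(r$gend, ct$gend)
      if (oe - os < min_block) next
      clen <- clens[[ct$contig]]
      if (!ct$flipped) {
        ts <- os - ct$gstart; te <- oe - ct$gstart
      } else {
        ts <- clen - (oe - ct$gstart); te <- clen - (os - ct$gstart)
      }
      rl <- r$gend - r$gstart
      if (r$strand == "+") {
        qs <- os - r$gstart; qe <- oe - r$gstart
      } else {
        qs <- rl - (oe - r$gstart); qe <- rl - (os - r$gstart)
      }
      strand <- if ((r$strand == "+") != ct$flipped) "+" else "-"
      rows[[length(rows) + 1]] <- data.frame(
        qname = r$id, qlen = rl, qstart = qs, qend = qe, strand = strand,
        tname = ct$contig, tlen = clen, tstart = ts, tend = te,
        nmatch = oe - os, alen = oe - os, mapq = 60,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_paf())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulated whole-assembly alignment between two fragmentations
#'
#' For two fragmentations of the same simulated genome, emits the PAF a
#' whole-genome aligner would produce with B contigs as query and A contigs
#' as target: every genome-interval overlap becomes an alignment block with
#' coordinates mapped through both contigs' flips.
#'
#' @param frag_a,frag_b `sim_fragmentation` objects sharing a genome truth.
#' @param min_block Minimum overlap to report (bp, default 1000).
#' @return PAF data.frame with B contigs as `qname`, A contigs as `tname`.
#' @export
sim_cross_paf <- function(frag_a, frag_b, min_block = 1000) {
  amap <- frag_a$map
  alens <- nchar(frag_a$contigs)
  blens <- nchar(frag_b$contigs)
  rows <- list()
  for (i in seq_len(nrow(frag_b$map))) {
    bc <- frag_b$map[i, ]
    cand <- amap[amap$chrom == bc$chrom & amap$gstart < bc$gend &
                 amap$gend > bc$gstart, , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      ac <- cand[j, ]
      os <- max(bc$gstart, ac$gstart)
      oe <- min(bc$gend, ac$gend)
      if (oe - os < min_block) next
      blen <- blens[[bc$contig]]
      alen_c <- alens[[ac$contig]]
      if (!bc$flipped) {
        qs <- os - bc$gstart; qe <- oe - bc$gstart
      } else {
        qs <- blen - (oe - bc$gstart); qe <- blen - (os - bc$gstart)
      }
      if (!ac$flipped) {
        ts <- os - ac$gstart; te <- oe - ac$gstart
      } else {
        ts <- alen_c - (oe - ac$gstart); te <- alen_c - (os - ac$gstart)
      }
      rows[[length(rows) + 1]] <- data.frame(
        qname = bc$contig, qlen = blen, qstart = qs, qend = qe,
        strand = if (bc$flipped == ac$flipped) "+" else "-",
        tname = ac$contig, tlen = alen_c, tstart = ts, tend = te,
        nmatch = oe - os, alen = oe - os, mapq = 60,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_paf())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lift genome-coordinate intervals onto a fragmentation's contigs
#'
#' Maps intervals recorded in simulated-genome coordinates (for example the
#' repeat annotations of a `sim_genome_truth`) into the local coordinates of
#' a fragmentation's contigs, clipping at contig boundaries and flipping
#' through reverse-complemented contigs.
#'
#' @param frag A `sim_fragmentation`.
#' @param intervals data.frame with `seq_id` (chromosome), `start`, `end`.
#' @return data.frame of intervals with contig `seq_id`s.
#' @export
lift_to_contigs <- function(frag, intervals) {
  rows <- list()
  for (i in seq_len(nrow(intervals))) {
    iv <- intervals[i, ]
    cand <- frag$map[frag$map$chrom == iv$seq_id &
                     frag$map$gstart < iv$end &
                     frag$map$gend > iv$start, , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      ct <- cand[j, ]
      os <- max(iv$start, ct$gstart)
      oe <- min(iv$end, ct$gend)
      len <- ct$gend - ct$gstart
      if (!ct$flipped) {
        s <- os - ct$gstart; e <- oe - ct$gstart
      } else {
        s <- len - (oe - ct$gstart); e <- len - (os - ct$gstart)
      }
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = ct$contig, start = s, end = e,
        label = if ("label" %in% names(iv)) iv$label else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(seq_id = character(0), start = numeric(0),
                      end = numeric(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$seq_id, out$start), , drop = FALSE]
}

#' Simulate two-population diploid genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies are Uniform(0.05, 0.95); each population's
#' frequency is drawn from Beta(p(1-F)/F, (1-p)(1-F)/F) with F the target
#' F_ST (F = 0 means both populations share the ancestral frequency
#' exactly), and diploid genotypes are Binomial(2, p_pop). Sites sit at
#' uniform positions on one synthetic chromosome. Planted outlier windows
#' receive fixed differences (population 1 homozygous reference, population
#' 2 homozygous alternate). QUAL and per-genotype DP are set high enough to
#' pass the default SNP filters.
#'
#' @param n_sites Number of SNP sites.
#' @param n_per_pop Diploid samples per population.
#' @param fst_target Target F_ST in `[0, 1)`.
#' @param outlier_windows Optional 2-column matrix/data.frame of window
#'   `[start, end)` coordinates (bp, 0-based) to plant fixed differences in.
#' @param window Window size used for bookkeeping (bp).
#' @param chrom_len Chromosome length (default 5e6, i.e. 50 windows of
#'   100 kb).
#' @param seed RNG seed.
#' @param pop_names Two population labels.
#' @return List of class `sim_pop_truth`: `gm` (a ready `genotype_matrix`),
#'   `popmap` (data.frame), `p_pop` (per-population site frequencies),
#'   `fst_target`, `outlier_windows`, `chrom`, `chrom_len`.
#' @export
simulate_two_pop_genotypes <- function(n_sites, n_per_pop, fst_target = 0,
                                       outlier_windows = NULL,
                                       window = 100000, chrom_len = 5e6,
                                       seed = 1L,
                                       pop_names = c("pop1", "pop2")) {
  stopifnot(fst_target >= 0, fst_target < 1, n_sites >= 1, n_per_pop >= 1)
  set.seed(seed)
  chrom <- "chr_sim"
  pos0 <- sort(sample.int(chrom_len, n_sites)) - 1
  p <- stats::runif(n_sites, 0.05, 0.95)
  if (fst_target == 0) {
    p1 <- p; p2 <- p
  } else {
    f <- fst_target
    p1 <- stats::rbeta(n_sites, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    p2 <- stats::rbeta(n_sites, p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  if (!is.null(outlier_windows)) {
    ow <- as.matrix(outlier_windows)
    for (r in seq_len(nrow(ow))) {
      inw <- pos0 >= ow[r, 1] & pos0 < ow[r, 2]
      p1[inw] <- 0
      p2[inw] <- 1
    }
  }
  g1 <- matrix(stats::rbinom(n_sites * n_per_pop, 2, rep(p1, n_per_pop)),
               nrow = n_sites)
  g2 <- matrix(stats::rbinom(n_sites * n_per_pop, 2, rep(p2, n_per_pop)),
               nrow = n_sites)
  gt <- cbind(g1, g2)
  samples <- c(sprintf("%s_%03d", pop_names[1], seq_len(n_per_pop)),
               sprintf("%s_%03d", pop_names[2], seq_len(n_per_pop)))
  colnames(gt) <- samples
  pops <- stats::setNames(rep(pop_names, each = n_per_pop), samples)
  gm <- structure(list(chrom = rep(chrom, n_sites), pos0 = pos0,
                       gt = gt, samples = samples, pops = pops),
                  class = "genotype_matrix")
  structure(list(gm = gm,
                 popmap = data.frame(sample = samples, population = pops,
                                     stringsAsFactors = FALSE),
                 p_pop = cbind(p1 = p1, p2 = p2), fst_target = fst_target,
                 outlier_windows = outlier_windows, chrom = chrom,
                 chrom_len = chrom_len, window = window),
            class = "sim_pop_truth")
}

#' Write a simulated genotype set as VCF v4.2 (+ population map)
#'
#' Minimal writer for simulator output: biallelic A>T SNPs with constant
#' QUAL 999 and per-genotype DP 30, which pass the default SNP filters.
#'
#' @param sim A `sim_pop_truth` from [simulate_two_pop_genotypes()].
#' @param vcf_path Output VCF path.
#' @param popmap_path Optional path for the `sample<TAB>population` map.
#' @param qual Site QUAL value (default 999).
#' @param dp Per-genotype depth (default 30).
#' @export
write_sim_vcf <- function(sim, vcf_path, popmap_path = NULL, qual = 999,
                          dp = 30) {
  gm <- sim$gm
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$gt + 1L], nrow = nrow(gm$gt))
  body <- vapply(seq_len(nrow(gm$gt)), function(i) {
    paste(c(gm$chrom[i], gm$pos0[i] + 1, ".", "A", "T", qual, "PASS", ".",
            "GT:DP", paste0(gt_str[i, ], ":", dp)), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", sim$chrom, as.integer(sim$chrom_len)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"))
  writeLines(c(header, body), vcf_path)
  if (!is.null(popmap_path)) {
    writeLines(paste(sim$popmap$sample, sim$popmap$population, sep = "\t"),
               popmap_path)
  }
  invisible(vcf_path)
}
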