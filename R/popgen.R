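# SNP filtering, windowed Tajima's D and Weir-Cockerham F_ST, and
# permutation-based outlier detection for two populations.

#' SNP-filter parameters
#'
#' Defaults are the published thresholds: per-genotype depth >= 5, site
#' quality >= 200, alternate-allele frequency within `[0.05, 0.95]`, call
#' rate >= 0.8, biallelic SNPs only.
#'
#' @param min_dp Minimum per-genotype depth; genotypes below are set missing.
#' @param min_q Minimum site QUAL.
#' @param maf Minimum alternate-allele frequency.
#' @param max_maf Maximum alternate-allele frequency.
#' @param max_missing Minimum call-rate fraction (the share of samples that
#'   must be called after the depth mask).
#' @return List of class `snp_filter_params`.
#' @export
snp_filter_params <- function(min_dp = 5, min_q = 200, maf = 0.05,
                              max_maf = 0.95, max_missing = 0.8) {
  stopifnot(maf >= 0, maf <= 0.5, max_maf >= 0.5, max_maf <= 1,
            max_missing > 0, max_missing <= 1, min_dp >= 0)
  structure(list(min_dp = min_dp, min_q = min_q, maf = maf,
                 max_maf = max_maf, max_missing = max_missing),
            class = "snp_filter_params")
}

#' Window-scan parameters
#'
#' Defaults are the published analysis settings: non-overlapping 100-kb
#' windows and 10,000 permutations at significance level 0.01.
#'
#' @param window Window size in bp.
#' @param n_perm Number of permutations.
#' @param alpha Significance level for flagging windows.
#' @param seed RNG seed for the permutation schemes.
#' @return List of class `scan_params`.
#' @export
scan_params <- function(window = 100000, n_perm = 10000, alpha = 0.01,
                        seed = 1L) {
  stopifnot(window >= 1, n_perm >= 1, alpha > 0, alpha <= 1)
  structure(list(window = window, n_perm = n_perm, alpha = alpha,
                 seed = as.integer(seed)), class = "scan_params")
}

#' Read a VCF and population map into raw genotype data
#'
#' @param vcf Path to a VCF (v4.2, GT and DP per sample) or a `vcfR` object.
#' @param popmap Path to a two-column TSV `sample<TAB>population`, or a
#'   data.frame with those columns, or a named character vector.
#' @return List with `chrom`, `pos0` (0-based), `ref`, `alt`, `qual`, `gt`
#'   (character matrix), `dp` (numeric matrix), `samples`, `pops` (named
#'   vector).
#' @export
read_genotypes <- function(vcf, popmap = NULL) {
  v <- if (inherits(vcf, "vcfR")) vcf else vcfR::read.vcfR(vcf, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  pops <- NULL
  if (!is.null(popmap)) {
    if (is.character(popmap) && length(popmap) == 1 && file.exists(popmap)) {
      pm <- utils::read.table(popmap, header = FALSE, sep = "\t",
                              col.names = c("sample", "population"),
                              stringsAsFactors = FALSE)
    } else if (is.data.frame(popmap)) {
      pm <- popmap
      names(pm)[1:2] <- c("sample", "population")
    } else {
      pm <- data.frame(sample = names(popmap),
                       population = as.character(popmap),
                       stringsAsFactors = FALSE)
    }
    pops <- stats::setNames(pm$population, pm$sample)[colnames(gt)]
    if (anyNA(pops)) {
      stop("population map missing sample(s): ",
           paste(colnames(gt)[is.na(pops)], collapse = ", "))
    }
  }
  list(chrom = as.character(v@fix[, "CHROM"]),
       pos0 = as.numeric(v@fix[, "POS"]) - 1,
       ref = as.character(v@fix[, "REF"]),
       alt = as.character(v@fix[, "ALT"]),
       qual = suppressWarnings(as.numeric(v@fix[, "QUAL"])),
       gt = gt, dp = dp, samples = colnames(gt), pops = pops)
}

#' Filter SNPs to a high-confidence genotype matrix
#'
#' Genotypes with depth below `min_dp` are set missing; sites are kept iff
#' they are biallelic SNPs with `QUAL >= min_q`, a post-mask call rate of at
#' least `max_missing`, and an alternate-allele frequency (on non-missing
#' genotypes) within `[maf, max_maf]`. The output is sorted by coordinate
#' and is identical regardless of input record order.
#'
#' @param x A VCF path, `vcfR` object, or the list from [read_genotypes()].
#' @param params A [snp_filter_params()] object.
#' @param popmap Population map (see [read_genotypes()]); required unless
#'   `x` already carries one.
#' @return Object of class `genotype_matrix`: list with `chrom`, `pos0`,
#'   `gt` (sites x samples integer matrix of alt-allele dosages 0/1/2, NA =
#'   missing), `samples`, `pops`.
#' @export
filter_snps <- function(x, params = snp_filter_params(), popmap = NULL) {
  if (is.character(x) || inherits(x, "vcfR")) {
    x <- read_genotypes(x, popmap)
  } else if (!is.null(popmap)) {
    x$pops <- resolve_popmap(popmap, x$samples)
  }
  dose <- gt_to_dosage(x$gt, x$chrom, x$pos0)
  if (!is.null(x$dp)) {
    dose[!is.na(x$dp) & x$dp < params$min_dp] <- NA_integer_
    dose[is.na(x$dp)] <- NA_integer_
  }
  n <- ncol(dose)
  called <- rowSums(!is.na(dose))
  af <- rowSums(dose, na.rm = TRUE) / (2 * called)
  biallelic <- nchar(x$ref) == 1 & nchar(x$alt) == 1 &
    x$ref %in% c("A", "C", "G", "T") & x$alt %in% c("A", "C", "G", "T")
  keep <- biallelic &
    !is.na(x$qual) & x$qual >= params$min_q &
    called / n >= params$max_missing &
    called > 0 & af >= params$maf & af <= params$max_maf
  keep[is.na(keep)] <- FALSE
  o <- order(x$chrom[keep], x$pos0[keep])
  idx <- which(keep)[o]
  structure(list(chrom = x$chrom[idx], pos0 = x$pos0[idx],
                 gt = dose[idx, , drop = FALSE], samples = x$samples,
                 pops = x$pops),
            class = "genotype_matrix")
}

resolve_popmap <- function(popmap, samples) {
  if (is.data.frame(popmap)) {
    p <- stats::setNames(popmap[[2]], popmap[[1]])
  } else {
    p <- popmap
  }
  out <- p[samples]
  if (anyNA(out)) stop("population map missing sample(s)")
  out
}

# GT strings -> alt-allele dosage; errors name the offending site.
gt_to_dosage <- function(gt, chrom, pos0) {
  g <- gsub("|", "/", gt, fixed = TRUE)
  dose <- matrix(NA_integer_, nrow = nrow(g), ncol = ncol(g),
                 dimnames = dimnames(g))
  dose[g == "0/0"] <- 0L
  dose[g == "0/1" | g == "1/0"] <- 1L
  dose[g == "1/1"] <- 2L
  known <- is.na(g) | g %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
  if (!all(known)) {
    bad <- which(!known, arr.ind = TRUE)[1, ]
    stop("malformed genotype '", g[bad[1], bad[2]], "' at ",
         chrom[bad[1]], ":", pos0[bad[1]] + 1)
  }
  dose
}

# Generalised harmonic sums via digamma/trigamma: exact at integer n and
# smooth in the mean sample size used for windows with missing data.
harmonic1 <- function(n) digamma(n) - digamma(1)              # sum 1/i, i<n
harmonic2 <- function(n) pi^2 / 6 - trigamma(n)               # sum 1/i^2, i<n

tajima_constants <- function(n) {
  a1 <- harmonic1(n)
  a2 <- harmonic2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D for one window of genotypes
#'
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the standard constants
#' computed from the number of sequences. Nucleotide diversity pi and the
#' segregating-site count S accumulate per site using each site's observed
#' sequence count; the constants use the mean observed sequence count over
#' segregating sites (generalised harmonic numbers make this exact at
#' integer n and well-defined otherwise). `NA` when S = 0 or the variance
#' term is non-positive.
#'
#' @param gt Sites x samples matrix of allele dosages; diploid 0/1/2 by
#'   default, haploid 0/1 with `ploidy = 1`. NA = missing.
#' @param ploidy 2 (default) or 1.
#' @param per_site_watterson Accumulate Watterson's estimator per site with
#'   each site's own `a1` instead of `S/a1(mean n)` (alternative
#'   missing-data convention; identical when no data are missing).
#' @return Tajima's D, or `NA_real_`.
#' @export
tajima_d <- function(gt, ploidy = 2, per_site_watterson = FALSE) {
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  ncalled <- rowSums(!is.na(gt)) * ploidy
  j <- rowSums(gt, na.rm = TRUE)
  seg <- ncalled >= 2 & j > 0 & j < ncalled
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  nseg <- ncalled[seg]
  jseg <- j[seg]
  pi_site <- jseg * (nseg - jseg) / (nseg * (nseg - 1) / 2)
  pi <- sum(pi_site)
  nbar <- mean(nseg)
  if (nbar < 2 + 1e-9) return(NA_real_)
  cst <- tajima_constants(nbar)
  theta_w <- if (per_site_watterson) {
    sum(1 / harmonic1(nseg))
  } else {
    S / cst$a1
  }
  v <- cst$e1 * S + cst$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi - theta_w) / sqrt(v)
}

# Weir & Cockerham (1984) per-site variance components for two populations.
# Returns vectors a (among populations) and abc (total); sites where either
# population has fewer than 2 called genotypes get NA.
wc_components <- function(gt, pop1_cols) {
  g1 <- gt[, pop1_cols, drop = FALSE]
  g2 <- gt[, -pop1_cols, drop = FALSE]
  n1 <- rowSums(!is.na(g1))
  n2 <- rowSums(!is.na(g2))
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1L, na.rm = TRUE) / n2
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  ok <- n1 >= 2 & n2 >= 2
  a[!ok] <- NA_real_
  abc <- a + b + cc
  abc[!ok] <- NA_real_
  list(a = a, abc = abc)
}

#' Weir-Cockerham F_ST for one window of genotypes
#'
#' The theta-hat estimator of Weir & Cockerham (1984): per-site variance
#' components a (among populations), b (among individuals within
#' populations), and c (within individuals) from sample sizes, allele
#' frequencies, and observed heterozygosities; the windowed estimate is the
#' ratio of sums `sum(a) / sum(a+b+c)` over sites. `NA` when the denominator
#' is zero (for example, both populations monomorphic). Sites where either
#' population has fewer than two called genotypes are skipped.
#'
#' @param gt Sites x samples matrix of diploid dosages 0/1/2 (NA missing).
#' @param pops Population label per sample (character/factor, exactly two
#'   levels).
#' @return The windowed theta-hat, or `NA_real_`.
#' @export
wc_fst <- function(gt, pops) {
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  lv <- sort(unique(as.character(pops)))
  if (length(lv) != 2) {
    stop("wc_fst requires exactly 2 populations, got ", length(lv))
  }
  comp <- wc_components(gt, which(as.character(pops) == lv[1]))
  num <- sum(comp$a, na.rm = TRUE)
  den <- sum(comp$abc, na.rm = TRUE)
  if (!is.finite(den) || den == 0 || all(is.na(comp$abc))) return(NA_real_)
  num / den
}

# Window id per site: non-overlapping tiles [0,w), [w,2w), ... per seq_id.
window_index <- function(chrom, pos0, window, seq_lengths = NULL) {
  chroms <- sort(unique(c(chrom, names(seq_lengths))))
  rows <- list()
  for (cn in chroms) {
    len <- if (!is.null(seq_lengths) && cn %in% names(seq_lengths)) {
      seq_lengths[[cn]]
    } else {
      max(pos0[chrom == cn]) + 1
    }
    if (!is.finite(len)) next
    nw <- max(ceiling(len / window), 1)
    starts <- (seq_len(nw) - 1) * window
    rows[[length(rows) + 1]] <- data.frame(
      seq_id = cn, start = starts, end = pmin(starts + window, len),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    wins <- data.frame(seq_id = character(0), start = numeric(0),
                       end = numeric(0), wid = integer(0))
    return(list(windows = wins, site_wid = integer(0)))
  }
  wins <- do.call(rbind, rows)
  wins$wid <- seq_len(nrow(wins))
  site_wid <- integer(length(pos0))
  for (cn in chroms) {
    sel <- chrom == cn
    w0 <- wins$wid[wins$seq_id == cn][1]
    site_wid[sel] <- w0 + pos0[sel] %/% window
  }
  list(windows = wins, site_wid = site_wid)
}

#' Windowed Tajima's D and F_ST scan
#'
#' Tiles every sequence with non-overlapping windows (including the trailing
#' partial window) and computes, per window: the SNP count, Tajima's D
#' within each population, and Weir-Cockerham F_ST between the two
#' populations. Windows without SNPs carry missing statistics.
#'
#' @param gm A `genotype_matrix` from [filter_snps()] (with `pops` set).
#' @param params A [scan_params()] object.
#' @param seq_lengths Optional named vector of sequence lengths; defaults to
#'   the last SNP position + 1 per sequence.
#' @return data.frame with `seq_id`, `start`, `end`, `n_snps`,
#'   `tajima_d_<pop>` per population, and `fst`.
#' @export
window_scan <- function(gm, params = scan_params(), seq_lengths = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), !is.null(gm$pops))
  lv <- sort(unique(as.character(gm$pops)))
  wi <- window_index(gm$chrom, gm$pos0, params$window, seq_lengths)
  wins <- wi$windows
  out <- wins[, c("seq_id", "start", "end")]
  out$n_snps <- as.integer(tabulate(wi$site_wid, nbins = nrow(wins)))
  for (p in lv) out[[paste0("tajima_d_", p)]] <- NA_real_
  out$fst <- NA_real_
  for (w in wins$wid[out$n_snps > 0]) {
    rows <- which(wi$site_wid == w)
    sub <- gm$gt[rows, , drop = FALSE]
    for (p in lv) {
      out[[paste0("tajima_d_", p)]][w] <-
        tajima_d(sub[, gm$pops == p, drop = FALSE])
    }
    if (length(lv) == 2) out$fst[w] <- wc_fst(sub, gm$pops)
  }
  out
}

#' Permutation outlier detection on windowed statistics
#'
#' Two null schemes, both seeded. F_ST: sample-to-population labels are
#' permuted `n_perm` times and every window's F_ST recomputed;
#' `p_fst_high = (1 + #{perm >= obs}) / (n_perm + 1)` (add-one estimator, so
#' p is never 0). Tajima's D is a single-population statistic where label
#' permutation is undefined, so its null resamples sites without replacement
#' into pseudo-windows of matched SNP count;
#' `p_d_low_<pop> = (1 + #{perm <= obs}) / (n_perm + 1)`. Windows with
#' `p_fst_high < alpha` are flagged as differentiated; within each
#' population the intersection with `p_d_low < alpha` marks regions of
#' increased within-cultivar uniformity.
#'
#' @param stats Window table from [window_scan()].
#' @param gm The `genotype_matrix` the statistics were computed from.
#' @param params A [scan_params()] object (`n_perm`, `alpha`, `seed`).
#' @return `stats` with added columns `p_fst_high`, `p_d_low_<pop>`,
#'   `flag_fst`, `flag_low_d_<pop>`, `flag_intersect_<pop>`.
#' @export
permutation_outliers <- function(stats, gm, params = scan_params()) {
  stopifnot(inherits(gm, "genotype_matrix"), !is.null(gm$pops))
  lv <- sort(unique(as.character(gm$pops)))
  stopifnot(length(lv) == 2)
  nw <- nrow(stats)
  B <- params$n_perm
  set.seed(params$seed)

  # site -> window-row mapping against the caller's window table (rows are
  # ordered by seq_id then start, as window_scan emits them)
  nsite <- nrow(gm$gt)
  wid_of_site <- integer(nsite)
  for (cn in unique(gm$chrom)) {
    w0 <- which(stats$seq_id == cn)[1]
    sel <- gm$chrom == cn
    wid_of_site[sel] <- w0 + gm$pos0[sel] %/% params$window
  }

  nsamp <- ncol(gm$gt)
  n1 <- sum(gm$pops == lv[1])
  n_distinct <- choose(nsamp, n1)
  if (2 * n1 == nsamp) n_distinct <- n_distinct / 2
  degenerate <- n_distinct < 2
  if (degenerate) {
    warning("too few samples for distinct label permutations; ",
            "F_ST permutation p-values reported as 1")
  }

  # --- F_ST null: label permutation ---------------------------------------
  obs_fst <- stats$fst
  ge_count <- integer(nw)
  valid <- !is.na(obs_fst)
  if (!degenerate && any(valid)) {
    for (b in seq_len(B)) {
      perm_cols <- sample.int(nsamp)
      comp <- wc_components(gm$gt, perm_cols[seq_len(n1)])
      a_w <- rowsum_by(comp$a, wid_of_site, nw)
      abc_w <- rowsum_by(comp$abc, wid_of_site, nw)
      fst_b <- ifelse(abc_w == 0, NA_real_, a_w / abc_w)
      ge_count <- ge_count + ifelse(valid & !is.na(fst_b) &
                                      fst_b >= obs_fst, 1L, 0L)
    }
  }
  stats$p_fst_high <- ifelse(valid,
                             if (degenerate) 1 else (1 + ge_count) / (B + 1),
                             NA_real_)

  # --- Tajima's D null: SNP-count-matched site resampling -----------------
  for (p in lv) {
    colp <- gm$pops == p
    gtp <- gm$gt[, colp, drop = FALSE]
    ncalled <- rowSums(!is.na(gtp)) * 2
    j <- rowSums(gtp, na.rm = TRUE)
    seg <- ncalled >= 2 & j > 0 & j < ncalled
    pi_site <- ifelse(seg, j * (ncalled - j) /
                        pmax(ncalled * (ncalled - 1) / 2, 1), 0)
    obs_d <- stats[[paste0("tajima_d_", p)]]
    le_count <- integer(nw)
    validd <- !is.na(obs_d)
    for (w in which(validd)) {
      S_w <- stats$n_snps[w]
      idx <- matrix(replicate(B, sample.int(nsite, S_w)), nrow = S_w)
      perm_d <- vapply(seq_len(B), function(b) {
        ii <- idx[, b]
        d_from_parts(sum(pi_site[ii]), sum(seg[ii]),
                     ncalled[ii][seg[ii]])
      }, numeric(1))
      le_count[w] <- sum(!is.na(perm_d) & perm_d <= obs_d[w])
    }
    stats[[paste0("p_d_low_", p)]] <- ifelse(validd,
                                             (1 + le_count) / (B + 1),
                                             NA_real_)
  }

  # alpha = 1 is the degenerate threshold: add-one p-values can equal 1
  # exactly, so every window with a defined statistic is flagged
  thr <- if (params$alpha >= 1) Inf else params$alpha
  stats$flag_fst <- !is.na(stats$p_fst_high) & stats$p_fst_high < thr
  for (p in lv) {
    low <- !is.na(stats[[paste0("p_d_low_", p)]]) &
      stats[[paste0("p_d_low_", p)]] < thr
    stats[[paste0("flag_low_d_", p)]] <- low
    stats[[paste0("flag_intersect_", p)]] <- stats$flag_fst & low
  }
  stats
}

# Tajima's D from accumulated parts (pi sum, S, per-site n of segregating
# sites) -- shared by the observed and resampled paths.
d_from_parts <- function(pi, S, nseg) {
  if (S == 0 || length(nseg) == 0) return(NA_real_)
  nbar <- mean(nseg)
  if (nbar < 2 + 1e-9) return(NA_real_)
  cst <- tajima_constants(nbar)
  v <- cst$e1 * S + cst$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi - S / cst$a1) / sqrt(v)
}

# Sum v by integer group id (NA values ignored), fixed group count.
rowsum_by <- function(v, g, n) {
  ok <- !is.na(v)
  out <- numeric(n)
  if (any(ok)) {
    s <- rowsum(v[ok], g[ok])
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}
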