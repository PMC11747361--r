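# Independent brute-force oracles, coded directly from the published
# formulas and kept free of any package internals.

# Tajima (1989) D from a complete haplotype matrix (sites x n, values 0/1).
oracle_tajima <- function(hap) {
  n <- ncol(hap)
  counts <- rowSums(hap)
  seg <- counts > 0 & counts < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  # pi: mean pairwise differences by explicit pair enumeration
  pairs <- utils::combn(n, 2)
  pi <- 0
  for (p in seq_len(ncol(pairs))) {
    pi <- pi + sum(hap[, pairs[1, p]] != hap[, pairs[2, p]])
  }
  pi <- pi / ncol(pairs)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi - S / a1) / sqrt(v)
}

# Weir & Cockerham (1984) theta-hat for r = 2 populations from a diploid
# dosage matrix (0/1/2, NA missing), per-site a, b, c summed site by site.
oracle_wc_fst <- function(gt, pops) {
  lv <- sort(unique(as.character(pops)))
  stopifnot(length(lv) == 2)
  r <- 2
  num <- 0
  den <- 0
  for (s in seq_len(nrow(gt))) {
    g <- split(gt[s, ], as.character(pops))
    n_i <- vapply(g, function(x) sum(!is.na(x)), numeric(1))
    if (any(n_i < 2)) next
    p_i <- vapply(g, function(x) sum(x, na.rm = TRUE), numeric(1)) / (2 * n_i)
    h_i <- vapply(g, function(x) sum(x == 1, na.rm = TRUE), numeric(1)) / n_i
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) return(NA_real_)
  num / den
}

# N50/L50 by explicit cumulative sum.
oracle_nx <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  half <- sum(lens) / 2
  acc <- 0
  for (i in seq_along(lens)) {
    acc <- acc + lens[i]
    if (acc >= half) return(list(n50 = lens[i], l50 = i))
  }
}
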