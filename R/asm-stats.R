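# Assembly QC: contiguity statistics, k-mer genome-size estimation,
# coverage fold, telomere end scanning.

#' Contiguity statistics (N50/L50) for an assembly
#'
#' N50 is the length of the sequence at which the cumulative
#' descending-sorted length first reaches at least half the total; L50 is its
#' rank. Gap bases are counted as literal `N` characters.
#'
#' @param sequences Named character vector of sequences, or a numeric vector
#'   of sequence lengths (gap bases then reported as `NA`).
#' @return List with `total_length`, `n_sequences`, `n50`, `l50`, `gap_bases`,
#'   `max_length`, `mean_length`.
#' @export
nx_stats <- function(sequences) {
  if (length(sequences) == 0) stop("nx_stats requires at least one sequence")
  if (is.character(sequences)) {
    lens <- nchar(sequences)
    gap_bases <- sum(vapply(sequences, function(s) {
      sum(charToRaw(s) %in% as.raw(c(78L, 110L)))   # N / n
    }, numeric(1)))
  } else {
    lens <- as.numeric(sequences)
    gap_bases <- NA_real_
  }
  lens <- sort(lens, decreasing = TRUE)
  total <- sum(lens)
  cum <- cumsum(lens)
  l50 <- which(cum >= total / 2)[1]
  list(total_length = total, n_sequences = length(lens),
       n50 = lens[l50], l50 = l50, gap_bases = gap_bases,
       max_length = lens[1], mean_length = total / length(lens))
}

#' Sequencing coverage fold
#'
#' @param total_bases Total sequenced bases (bp).
#' @param genome_size Genome size (bp); must be positive.
#' @return `total_bases / genome_size` at full precision (round only when
#'   reporting).
#' @export
coverage_fold <- function(total_bases, genome_size) {
  if (!is.numeric(genome_size) || genome_size <= 0) {
    stop("genome_size must be positive")
  }
  total_bases / genome_size
}

#' Estimate genome size from a k-mer multiplicity histogram
#'
#' The histogram is densified over multiplicities 1..max and smoothed with a
#' centred moving average (window 3) for peak/valley detection. The error
#' cutoff is the first local minimum scanning from multiplicity 1 (low-
#' multiplicity k-mers are dominated by sequencing errors); peaks are local
#' maxima above the cutoff. Two peaks indicate a heterozygous spectrum; the
#' genome size uses the highest-multiplicity (homozygous) peak:
#' `size = sum(m * count(m), m > cutoff) / homozygous_peak`.
#'
#' @param hist A `kmer_histogram` (see [kmer_histogram()]).
#' @param error_cutoff `"auto"` (default) or a non-negative integer
#'   multiplicity below/at which k-mers are excluded.
#' @param smooth_window Moving-average window for peak detection (default 3).
#' @param min_peak_frac Minimum height of a reported peak as a fraction of
#'   the tallest smoothed count above the cutoff (default 0.05); suppresses
#'   spurious peaks in the sparse high-multiplicity tail.
#' @return List with `size` (bp), `peaks` (multiplicities, ascending),
#'   `homozygous_peak`, `error_cutoff`, `heterozygous` (TRUE when >1 peak).
#' @export
estimate_genome_size <- function(hist, error_cutoff = "auto",
                                 smooth_window = 3, min_peak_frac = 0.05) {
  stopifnot(inherits(hist, "kmer_histogram") || is.data.frame(hist))
  maxm <- max(hist$multiplicity)
  cnt <- numeric(maxm)
  cnt[hist$multiplicity] <- hist$count
  # centred moving average with edge padding
  half <- (smooth_window - 1) %/% 2
  padded <- c(rep(cnt[1], half), cnt, rep(cnt[maxm], half))
  sm <- as.numeric(stats::filter(padded, rep(1 / smooth_window, smooth_window),
                                 sides = 2))[(half + 1):(half + maxm)]

  if (identical(error_cutoff, "auto")) {
    cutoff <- 0
    if (maxm >= 2) {
      i <- 1
      while (i < maxm && sm[i + 1] <= sm[i]) i <- i + 1
      if (i > 1 && i < maxm) cutoff <- i
    }
  } else {
    cutoff <- as.numeric(error_cutoff)
  }

  peaks <- find_peaks(sm, cnt, above = cutoff)
  if (length(peaks) > 0 && cutoff < maxm) {
    tallest <- max(sm[(cutoff + 1):maxm])
    peaks <- peaks[sm[peaks] >= min_peak_frac * tallest]
  }
  if (length(peaks) == 0) stop("no usable peak above the error cutoff")
  hom <- max(peaks)
  usable <- hist$multiplicity > cutoff
  size <- sum(hist$multiplicity[usable] * hist$count[usable]) / hom
  list(size = size, peaks = sort(peaks), homozygous_peak = hom,
       error_cutoff = cutoff, heterozygous = length(peaks) > 1)
}

# Local maxima of the smoothed counts `sm` at multiplicities > `above`.
# Plateaus count once; the reported multiplicity is the raw-count argmax
# within the plateau run.
find_peaks <- function(sm, raw, above = 0) {
  n <- length(sm)
  r <- rle(sm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  peaks <- integer(0)
  for (j in seq_along(r$values)) {
    prev <- if (j == 1) -Inf else r$values[j - 1]
    nxt <- if (j == length(r$values)) -Inf else r$values[j + 1]
    if (r$values[j] > prev && r$values[j] > nxt && r$values[j] > 0) {
      run <- starts[j]:ends[j]
      run <- run[run > above]
      if (length(run) > 0) {
        peaks <- c(peaks, run[which.max(raw[run])])
      }
    }
  }
  peaks
}

#' Scan assembly ends for telomere repeat arrays
#'
#' Counts non-overlapping occurrences of the motif and of its reverse
#' complement within the terminal window of each sequence end; the better of
#' the two orientations is reported per side. A hit requires at least
#' `min_copies` copies. The default motif is the canonical plant telomere
#' repeat.
#'
#' @param sequences Named character vector of sequences.
#' @param motif Telomere repeat motif (default `"TTTAGGG"`).
#' @param window Terminal window size in bp (default 3000); windows larger
#'   than the sequence are truncated to the whole sequence.
#' @param min_copies Minimum motif copies for a hit (default 10).
#' @param all_ends Return every end (including non-hits) instead of hits only.
#' @return data.frame with `seq_id`, `side` (head/tail), `motif` (the winning
#'   orientation), `copy_count`, `density` (fraction of the window covered),
#'   `hit`.
#' @export
telomere_scan <- function(sequences, motif = "TTTAGGG", window = 3000,
                          min_copies = 10, all_ends = FALSE) {
  stopifnot(nchar(motif) > 0, window >= nchar(motif))
  rc <- revcomp(motif)
  rows <- list()
  for (id in names(sequences)) {
    s <- sequences[[id]]
    L <- nchar(s)
    w <- min(window, L)
    for (side in c("head", "tail")) {
      seg <- if (side == "head") substr(s, 1, w) else substr(s, L - w + 1, L)
      nf <- count_motif(seg, motif)
      nr <- count_motif(seg, rc)
      if (nf >= nr) {
        cc <- nf; mot <- motif
      } else {
        cc <- nr; mot <- rc
      }
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = id, side = side, motif = mot, copy_count = cc,
        density = cc * nchar(motif) / w, hit = cc >= min_copies,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (all_ends) out else out[out$hit, , drop = FALSE]
}

# Non-overlapping occurrences of a fixed motif in one string.
count_motif <- function(s, motif) {
  m <- gregexpr(motif, s, fixed = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}
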