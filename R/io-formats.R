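# Readers/writers for the standard formats the pipeline touches.
# All internal coordinates are 0-based half-open (BED convention); the AGP
# writer converts to 1-based inclusive at the boundary.

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, any case).
#' @return Character vector of reverse complements, names preserved.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Read a FASTA file
#'
#' Sequence ids are the first whitespace-delimited token of each header.
#' Sequences are uppercased; record order is preserved.
#'
#' @param path Path to a FASTA file (gzip transparently supported).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  if (any(Biostrings::width(x) == 0)) {
    empty <- ids[Biostrings::width(x) == 0]
    stop("empty sequence(s) in ", path, ": ", paste(empty, collapse = ", "))
  }
  seqs <- toupper(as.character(x))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(length(seqs) == 0 || !is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Mean read quality on the error-probability scale
#'
#' The mean quality of a read is the Phred-scaled mean of its per-base error
#' probabilities, `-10 log10(mean(10^(-q/10)))` -- the convention of common
#' long-read filters -- not the arithmetic mean of the Phred values.
#'
#' @param qual Character vector of Phred+33 quality strings, or a list of
#'   integer Phred vectors.
#' @return Numeric vector of mean quality values.
#' @export
mean_qv <- function(qual) {
  one <- function(q) {
    if (is.character(q)) q <- utf8ToInt(q) - 33L
    if (length(q) == 0) return(NA_real_)
    -10 * log10(mean(10^(-q / 10)))
  }
  vapply(qual, one, numeric(1), USE.NAMES = FALSE)
}

#' Read a FASTQ file
#'
#' @param path Path to a 4-line-record FASTQ file, Phred+33 (gzip supported).
#' @return A data.frame with columns `id`, `sequence` (uppercase), `quality`
#'   (Phred+33 string), `length`, and `mean_qv` (error-probability scale).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  if (length(x) == 0) {
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), length = integer(),
                      mean_qv = numeric(), stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(x))
  quals <- as.character(S4Vectors::mcols(x)$qualities)
  seqs <- toupper(as.character(x))
  bad <- which(nchar(quals) != nchar(seqs))
  if (length(bad) > 0) {
    stop("sequence/quality length mismatch for record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  data.frame(id = ids, sequence = seqs, quality = quals,
             length = nchar(seqs), mean_qv = mean_qv(quals),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with columns `id`, `sequence`, `quality` (as
#'   returned by [read_fastq()]).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    lines <- rbind(paste0("@", reads$id), reads$sequence, "+", reads$quality)
    writeLines(as.vector(lines), con)
  }
  invisible(path)
}

#' Read a PAF alignment file
#'
#' Parses the 12 mandatory PAF columns; optional SAM-style tags are ignored.
#'
#' @param path Path to a PAF file.
#' @return data.frame with columns `qname`, `qlen`, `qstart`, `qend`,
#'   `strand`, `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`, `mapq`.
#'   Coordinates are 0-based half-open as in the format itself.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_paf())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    stop("PAF line ", which(nf < 12)[1], " has fewer than 12 columns")
  }
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  paf <- data.frame(
    qname = m[, 1], qlen = as.numeric(m[, 2]),
    qstart = as.numeric(m[, 3]), qend = as.numeric(m[, 4]),
    strand = m[, 5],
    tname = m[, 6], tlen = as.numeric(m[, 7]),
    tstart = as.numeric(m[, 8]), tend = as.numeric(m[, 9]),
    nmatch = as.numeric(m[, 10]), alen = as.numeric(m[, 11]),
    mapq = as.numeric(m[, 12]), stringsAsFactors = FALSE
  )
  bad_strand <- which(!paf$strand %in% c("+", "-"))
  if (length(bad_strand) > 0) {
    stop("PAF line ", bad_strand[1], ": illegal strand '",
         paf$strand[bad_strand[1]], "' (only +/- allowed)")
  }
  bad <- which(!(paf$qstart >= 0 & paf$qstart < paf$qend & paf$qend <= paf$qlen &
                 paf$tstart >= 0 & paf$tstart < paf$tend & paf$tend <= paf$tlen))
  if (length(bad) > 0) {
    stop("PAF line ", bad[1], ": invalid interval (requires 0 <= start < end <= length)")
  }
  bad <- which(paf$nmatch > paf$alen)
  if (length(bad) > 0) {
    stop("PAF line ", bad[1], ": residue matches exceed alignment block length")
  }
  paf
}

empty_paf <- function() {
  data.frame(qname = character(), qlen = numeric(), qstart = numeric(),
             qend = numeric(), strand = character(), tname = character(),
             tlen = numeric(), tstart = numeric(), tend = numeric(),
             nmatch = numeric(), alen = numeric(), mapq = numeric(),
             stringsAsFactors = FALSE)
}

#' Write alignments to PAF
#'
#' @param paf data.frame in the layout returned by [read_paf()].
#' @param path Output path.
#' @export
write_paf <- function(paf, path) {
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   paf$qname, as.integer(paf$qlen), as.integer(paf$qstart),
                   as.integer(paf$qend), paf$strand, paf$tname,
                   as.integer(paf$tlen), as.integer(paf$tstart),
                   as.integer(paf$tend), as.integer(paf$nmatch),
                   as.integer(paf$alen), as.integer(paf$mapq))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file (3-6 columns)
#'
#' @param path Path to a BED file.
#' @return data.frame with columns `seq_id`, `start`, `end` and, when present,
#'   `label`, `score`, `strand`. Coordinates 0-based half-open.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          data.table = FALSE)
  if (nrow(dt) == 0) {
    return(data.frame(seq_id = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  cols <- c("seq_id", "start", "end", "label", "score", "strand")
  names(dt) <- cols[seq_len(min(ncol(dt), 6))]
  dt$start <- as.numeric(dt$start)
  dt$end <- as.numeric(dt$end)
  if (any(!(dt$start >= 0 & dt$start < dt$end))) {
    stop("invalid BED interval (requires 0 <= start < end)")
  }
  dt
}

#' Write intervals to BED
#'
#' @param intervals data.frame with `seq_id`, `start`, `end` and optional
#'   `label`, `score`, `strand` columns.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("seq_id", "start", "end", "label", "score", "strand"),
                    names(intervals))
  x <- intervals[, cols, drop = FALSE]
  x$start <- format(x$start, scientific = FALSE, trim = TRUE)
  x$end <- format(x$end, scientific = FALSE, trim = TRUE)
  lines <- do.call(paste, c(unname(as.list(x)), sep = "\t"))
  writeLines(if (nrow(intervals) > 0) lines else character(0), path)
  invisible(path)
}

#' Convert RepeatMasker .out annotations to BED intervals
#'
#' Consumes the fixed column layout of RepeatMasker `.out` files (three header
#' lines, whitespace-separated fields, 1-based inclusive query coordinates)
#' and returns 0-based half-open intervals. RepeatMasker itself is never run.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return data.frame of intervals with `label` = repeat name and `strand`.
#' @export
rm_out_to_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3, length(lines)))]
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (length(lines) == 0) {
    return(data.frame(seq_id = character(), start = numeric(), end = numeric(),
                      label = character(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\\s+")
  get <- function(i) vapply(fields, `[[`, character(1), i)
  data.frame(
    seq_id = get(5),
    start = as.numeric(get(6)) - 1,
    end = as.numeric(get(7)),
    label = get(10),
    strand = ifelse(get(9) == "C", "-", "+"),
    stringsAsFactors = FALSE
  )
}

#' Read a two-column k-mer multiplicity histogram
#'
#' @param path Text file with lines "multiplicity<TAB>count" (the layout
#'   written by common k-mer counters).
#' @param k The k-mer length the histogram was computed with (metadata only).
#' @return Object of class `kmer_histogram`: data.frame (`multiplicity`,
#'   `count`) sorted by multiplicity, with attribute `k`.
#' @export
read_kmer_histogram <- function(path, k = NA_integer_) {
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
  kmer_histogram(dt[[1]], dt[[2]], k = k)
}

#' Construct a k-mer histogram object
#'
#' @param multiplicity Integer vector of multiplicities (>= 1).
#' @param count Number of distinct k-mers observed at each multiplicity.
#' @param k k-mer length (metadata).
#' @return data.frame of class `kmer_histogram`, sorted by multiplicity.
#' @export
kmer_histogram <- function(multiplicity, count, k = NA_integer_) {
  stopifnot(length(multiplicity) == length(count), all(multiplicity >= 1),
            all(count >= 0), !anyDuplicated(multiplicity))
  o <- order(multiplicity)
  h <- data.frame(multiplicity = as.numeric(multiplicity)[o],
                  count = as.numeric(count)[o])
  attr(h, "k") <- k
  class(h) <- c("kmer_histogram", "data.frame")
  h
}

#' Write scaffold layouts to AGP v2.1
#'
#' Object and component coordinates are converted from the package-internal
#' 0-based half-open convention to the 1-based inclusive coordinates AGP
#' requires. Gap rows are type "scaffold" with linkage "yes".
#'
#' @param layouts data.frame with columns `scaffold_id`, `component`,
#'   `orientation` (+/-), `gap_after` (bp of N after the component; 0 for the
#'   last component of a scaffold).
#' @param component_lengths Named numeric vector of component lengths.
#' @param path Output path.
#' @param evidence Linkage evidence keyword for gap rows (default
#'   "paired-ends").
#' @export
write_agp <- function(layouts, component_lengths, path, evidence = "paired-ends") {
  lines <- "##agp-version\t2.1"
  if (nrow(layouts) > 0) {
    miss <- setdiff(layouts$component, names(component_lengths))
    if (length(miss) > 0) {
      stop("unknown component id(s) in layout: ", paste(miss, collapse = ", "))
    }
    for (sid in unique(layouts$scaffold_id)) {
      parts <- layouts[layouts$scaffold_id == sid, , drop = FALSE]
      pos <- 0   # 0-based cursor on the object
      pn <- 0L
      for (i in seq_len(nrow(parts))) {
        len <- component_lengths[[parts$component[i]]]
        pn <- pn + 1L
        lines <- c(lines, sprintf("%s\t%d\t%d\t%d\tW\t%s\t%d\t%d\t%s",
                                  sid, pos + 1, pos + len, pn,
                                  parts$component[i], 1L, len,
                                  parts$orientation[i]))
        pos <- pos + len
        gap <- parts$gap_after[i]
        if (i < nrow(parts) && gap < 1) {
          stop("internal gap in scaffold ", sid, " must be >= 1 bp")
        }
        if (gap > 0) {
          pn <- pn + 1L
          lines <- c(lines, sprintf("%s\t%d\t%d\t%d\tN\t%d\tscaffold\tyes\t%s",
                                    sid, pos + 1, pos + gap, pn, gap, evidence))
          pos <- pos + gap
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# Union (merge) of possibly-overlapping intervals per seq_id.
# Returns a data.frame(seq_id, start, end), 0-based half-open, sorted.
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals[, c("seq_id", "start", "end")])
  parts <- lapply(split(intervals, intervals$seq_id), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
    data.frame(seq_id = d$seq_id[1], start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$seq_id, out$start), , drop = FALSE]
}

# Total bases of `intervals` (assumed merged) falling inside [wstart, wend)
# on one seq_id.
interval_coverage <- function(intervals, seq_id, wstart, wend) {
  d <- intervals[intervals$seq_id == seq_id, , drop = FALSE]
  if (nrow(d) == 0) return(0)
  s <- pmax(d$start, wstart)
  e <- pmin(d$end, wend)
  sum(pmax(e - s, 0))
}
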