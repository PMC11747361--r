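# GAP-Seq adaptive-sampling target design at contig ends, long-read QC
# filtering, and gap-spanning read classification.

#' Target-design parameters
#'
#' Defaults are the published GAP-Seq settings: 5,000-bp targets at contig
#' ends; in repeat-aware mode an end qualifies only when strictly less than
#' 50% of the terminal 100-kb window is covered by repeat annotations.
#'
#' @param target_len Target length at each contig end (bp).
#' @param repeat_window Terminal window over which repeat coverage is
#'   evaluated (bp).
#' @param max_repeat_fraction Repeat-coverage threshold (strict upper bound).
#' @param mode `"plain"` or `"repeat_aware"`.
#' @return List of class `target_params`.
#' @export
target_params <- function(target_len = 5000, repeat_window = 100000,
                          max_repeat_fraction = 0.5,
                          mode = c("plain", "repeat_aware")) {
  mode <- match.arg(mode)
  stopifnot(target_len > 0, target_len <= repeat_window,
            max_repeat_fraction >= 0, max_repeat_fraction <= 1)
  structure(list(target_len = target_len, repeat_window = repeat_window,
                 max_repeat_fraction = max_repeat_fraction, mode = mode),
            class = "target_params")
}

#' Design adaptive-sampling target regions at contig ends
#'
#' Plain mode emits the outermost `target_len` bp of both ends of every
#' contig; when a contig is at most twice the target length the two targets
#' merge into the whole contig. Repeat-aware mode uses the same geometry but
#' emits an end only when the merged repeat coverage of its terminal
#' `repeat_window` is strictly below `max_repeat_fraction` (repeat arrays at
#' contig ends defeat adaptive-sampling enrichment). Repeat intervals are
#' unioned before the fraction is computed, so overlapping annotations never
#' double-count.
#'
#' @param contigs Named character vector of contig sequences, or named
#'   numeric vector of contig lengths.
#' @param repeats Optional data.frame of repeat intervals (`seq_id`, `start`,
#'   `end`; 0-based half-open). Required for repeat-aware mode.
#' @param params A [target_params()] object.
#' @param include_suppressed Also return ends suppressed by the repeat rule
#'   (column `emitted` distinguishes them).
#' @return data.frame with `seq_id`, `start`, `end`, `side`
#'   (head/tail/both), `repeat_fraction`, `emitted`.
#' @export
design_targets <- function(contigs, repeats = NULL, params = target_params(),
                           include_suppressed = FALSE) {
  lens <- if (is.character(contigs)) nchar(contigs) else as.numeric(contigs)
  names(lens) <- names(contigs)
  if (!is.null(repeats) && nrow(repeats) > 0) {
    unknown <- setdiff(unique(repeats$seq_id), names(lens))
    if (length(unknown) > 0) {
      stop("repeat annotation references unknown contig id(s): ",
           paste(unknown, collapse = ", "))
    }
    repeats <- merge_intervals(repeats)
  }
  t <- params$target_len
  w <- params$repeat_window
  rows <- list()
  for (id in sort(names(lens))) {
    L <- lens[[id]]
    frac <- c(head = NA_real_, tail = NA_real_)
    if (!is.null(repeats)) {
      ww <- min(w, L)
      frac["head"] <- interval_coverage(repeats, id, 0, ww) / ww
      frac["tail"] <- interval_coverage(repeats, id, L - ww, L) / ww
    }
    if (params$mode == "repeat_aware") {
      if (is.null(repeats)) stop("repeat-aware mode requires repeat intervals")
      ok <- frac < params$max_repeat_fraction   # strict: exactly 50% suppresses
    } else {
      ok <- c(head = TRUE, tail = TRUE)
    }
    head_iv <- c(0, min(t, L))
    tail_iv <- c(max(L - t, 0), L)
    if (ok[["head"]] && ok[["tail"]] && tail_iv[1] < head_iv[2]) {
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = id, start = 0, end = L, side = "both",
        repeat_fraction = if (all(is.na(frac))) NA_real_ else max(frac),
        emitted = TRUE, stringsAsFactors = FALSE)
    } else {
      for (side in c("head", "tail")) {
        iv <- if (side == "head") head_iv else tail_iv
        emitted <- ok[[side]]
        if (emitted || include_suppressed) {
          rows[[length(rows) + 1]] <- data.frame(
            seq_id = id, start = iv[1], end = iv[2], side = side,
            repeat_fraction = frac[[side]], emitted = emitted,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(seq_id = character(), start = numeric(), end = numeric(),
               side = character(), repeat_fraction = numeric(),
               emitted = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!include_suppressed) out <- out[out$emitted, , drop = FALSE]
  out
}

#' Read-filter parameters
#'
#' Defaults are the published thresholds: mean quality >= 10 and length
#' >= 20 kb.
#'
#' @param min_qv Minimum mean read quality (Phred scale, error-probability
#'   mean convention; see [mean_qv()]).
#' @param min_len Minimum read length (bp).
#' @return List of class `read_filter_params`.
#' @export
read_filter_params <- function(min_qv = 10, min_len = 20000) {
  stopifnot(min_qv >= 0, min_len >= 0)
  structure(list(min_qv = min_qv, min_len = min_len),
            class = "read_filter_params")
}

#' Filter long reads by length and mean quality
#'
#' A read is kept iff `mean_qv >= min_qv` and `length >= min_len`. In the
#' report a read failing both criteria is counted once, under length.
#'
#' @param reads data.frame as returned by [read_fastq()].
#' @param params A [read_filter_params()] object.
#' @return List with `kept` (data.frame of surviving reads) and `report`
#'   (`total`, `kept`, `rejected_by_len`, `rejected_by_qv`).
#' @export
filter_reads <- function(reads, params = read_filter_params()) {
  len_ok <- reads$length >= params$min_len
  qv_ok <- reads$mean_qv >= params$min_qv
  keep <- len_ok & qv_ok
  list(kept = reads[keep, , drop = FALSE],
       report = list(total = nrow(reads),
                     kept = sum(keep),
                     rejected_by_len = sum(!len_ok),
                     rejected_by_qv = sum(len_ok & !qv_ok)))
}

#' Classify reads against target regions
#'
#' Each read's best alignment (most residue matches) decides its status: a
#' read overlapping a target region is on-target; it is `gap_spanning` when
#' the alignment reaches within `eps` bp of the contig terminus on the
#' target's outward side and unaligned read bases continue past that end
#' (those bases are the `overhang` that can bridge into the gap). On-target
#' reads stretching only toward the contig interior are `proximal`; reads
#' with no target-overlapping alignment are `off_target`.
#'
#' @param reads data.frame with at least `id` (and `length` if available) --
#'   typically [read_fastq()] output.
#' @param targets Target regions from [design_targets()].
#' @param alignments PAF records of reads (query) aligned to contigs
#'   (target), as from [read_paf()].
#' @param eps End-proximity tolerance in bp (default 100; alignments rarely
#'   reach the exact terminus).
#' @param contigs Optional character vector of known contig ids; when given,
#'   alignments to other ids raise an error.
#' @return data.frame with `read_id`, `status`, `contig`, `side`, `overhang`.
#' @export
classify_reads <- function(reads, targets, alignments, eps = 100,
                           contigs = NULL) {
  unknown <- setdiff(unique(alignments$qname), reads$id)
  if (length(unknown) > 0) {
    stop("alignment references unknown read id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (!is.null(contigs)) {
    unknown_t <- setdiff(unique(alignments$tname), contigs)
    if (length(unknown_t) > 0) {
      stop("alignment references unknown contig id(s): ",
           paste(utils::head(unknown_t, 5), collapse = ", "))
    }
  }

  out <- data.frame(read_id = reads$id, status = "off_target",
                    contig = NA_character_, side = NA_character_,
                    overhang = NA_real_, stringsAsFactors = FALSE)
  if (nrow(alignments) == 0) return(out)

  aln <- alignments[order(alignments$qname, -alignments$nmatch,
                          alignments$tname, alignments$tstart), , drop = FALSE]
  best <- aln[!duplicated(aln$qname), , drop = FALSE]

  for (i in seq_len(nrow(best))) {
    a <- best[i, ]
    row <- match(a$qname, out$read_id)
    tg <- targets[targets$seq_id == a$tname &
                  targets$start < a$tend & targets$end > a$tstart, , drop = FALSE]
    if (nrow(tg) == 0) next
    ovl <- pmin(tg$end, a$tend) - pmax(tg$start, a$tstart)
    tg <- tg[which.max(ovl), ]
    sides <- if (tg$side == "both") c("head", "tail") else tg$side
    status <- "proximal"
    hit_side <- sides[1]
    overhang <- NA_real_
    for (side in sides) {
      if (side == "head") {
        reaches <- a$tstart <= eps
        over <- if (a$strand == "+") a$qstart else a$qlen - a$qend
      } else {
        reaches <- a$tlen - a$tend <= eps
        over <- if (a$strand == "+") a$qlen - a$qend else a$qstart
      }
      if (reaches && over > 0) {
        status <- "gap_spanning"
        hit_side <- side
        overhang <- over
        break
      }
    }
    out$status[row] <- status
    out$contig[row] <- a$tname
    out$side[row] <- hit_side
    out$overhang[row] <- overhang
  }
  out
}
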