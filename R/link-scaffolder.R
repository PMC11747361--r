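# k-mer-pair link scaffolding: contigs are joined when long reads carry two
# k-mers a fixed distance apart whose unique genomic homes lie on the ends of
# two different contigs. Repeats are the stated failure mode of end-targeted
# enrichment, so only k-mers occurring exactly once across the whole contig
# set may contribute links.

#' Link-scaffolding parameters
#'
#' Defaults are the published conservative set: k = 51, at least 15 links per
#' join, 20,000 bp between the k-mers of a pair, 2% allowable error on that
#' distance, and a maximum 0.1 support ratio between the two best partners of
#' a contig end.
#'
#' @param k k-mer length (odd, >= 11).
#' @param min_links Minimum supporting pairs per join.
#' @param pair_distance Distance `d` between k-mer start positions on a read
#'   (bp).
#' @param distance_error Allowable deviation of an implied gap from the edge
#'   median, as a fraction of `pair_distance`.
#' @param max_link_ratio Maximum second-best/best support ratio at an end.
#' @param step Offset step between successive pair extractions along a read.
#' @return List of class `link_params`.
#' @export
link_params <- function(k = 51, min_links = 15, pair_distance = 20000,
                        distance_error = 0.02, max_link_ratio = 0.1,
                        step = 2) {
  stopifnot(k >= 11, k %% 2 == 1, pair_distance > k,
            distance_error > 0, distance_error < 1,
            max_link_ratio > 0, max_link_ratio < 1,
            min_links >= 1, step >= 1)
  structure(list(k = k, min_links = min_links, pair_distance = pair_distance,
                 distance_error = distance_error,
                 max_link_ratio = max_link_ratio, step = step),
            class = "link_params")
}

# Canonical k-mers of one sequence: forward k-mer, its aligned reverse
# complement (taken from the revcomped sequence, no per-k-mer work), and the
# lexicographic minimum of the two.
seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) {
    return(data.frame(pos0 = numeric(0), kmer = character(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  i <- seq_len(L - k + 1)              # 1-based forward starts
  fwd <- substring(seq, i, i + k - 1)
  rc_seq <- revcomp(seq)
  rc <- substring(rc_seq, L - i - k + 2, L - i + 1)
  fwd_is_canon <- fwd <= rc
  data.frame(pos0 = i - 1,
             kmer = ifelse(fwd_is_canon, fwd, rc),
             strand = ifelse(fwd_is_canon, "+", "-"),
             stringsAsFactors = FALSE)
}

#' Index k-mers that occur exactly once across a contig set
#'
#' k-mers are stored in canonical form (lexicographic minimum of the k-mer
#' and its reverse complement). Multi-copy k-mers go to a blacklist and never
#' contribute links; k-mers containing N are skipped.
#'
#' @param contigs Named character vector of contig sequences.
#' @param k Odd k-mer length.
#' @return List with `kmers` (data.table: `kmer`, `contig`, `pos0`, `strand`
#'   -- strand "+" when the forward-strand k-mer is the canonical form),
#'   `blacklist` (character vector), `k`, and `contig_lengths`.
#' @export
index_unique_kmers <- function(contigs, k) {
  stopifnot(k %% 2 == 1, !is.null(names(contigs)))
  per <- lapply(names(contigs), function(id) {
    km <- seq_kmers(contigs[[id]], k)
    if (nrow(km) == 0) return(NULL)
    km <- km[!grepl("N", km$kmer, fixed = TRUE), , drop = FALSE]
    if (nrow(km) == 0) return(NULL)
    km$contig <- id
    km
  })
  dt <- data.table::rbindlist(per)
  if (nrow(dt) == 0) {
    return(list(kmers = dt, blacklist = character(0), k = k,
                contig_lengths = nchar(contigs)))
  }
  dup_first <- duplicated(dt$kmer)
  dup_last <- duplicated(dt$kmer, fromLast = TRUE)
  multi <- dup_first | dup_last
  list(kmers = dt[!multi],
       blacklist = unique(dt$kmer[dup_first]),
       k = k,
       contig_lengths = nchar(contigs))
}

#' Extract k-mer pairs from a read
#'
#' Pairs are taken at offsets `0, step, 2*step, ...` while
#' `offset + pair_distance + k <= read length`; k-mers containing N are
#' skipped. k-mers are reported in canonical form together with the strand of
#' the as-read k-mer relative to the canonical form.
#'
#' @param read A single read sequence (character scalar).
#' @param params A [link_params()] object.
#' @param read_id Identifier recorded with each pair.
#' @return data.frame with `read_id`, `offset` (0-based), `kmer_a`,
#'   `strand_a`, `kmer_b`, `strand_b`, `separation`.
#' @export
extract_pairs <- function(read, params = link_params(), read_id = "read") {
  k <- params$k
  d <- params$pair_distance
  L <- nchar(read)
  empty <- data.frame(read_id = character(0), offset = numeric(0),
                      kmer_a = character(0), strand_a = character(0),
                      kmer_b = character(0), strand_b = character(0),
                      separation = numeric(0), stringsAsFactors = FALSE)
  if (L < d + k) return(empty)
  off <- seq(0, L - d - k, by = params$step)
  rc_seq <- revcomp(read)
  kmer_at <- function(o) {                # o: 0-based offsets
    i <- o + 1
    fwd <- substring(read, i, i + k - 1)
    rc <- substring(rc_seq, L - i - k + 2, L - i + 1)
    canon <- fwd <= rc
    list(kmer = ifelse(canon, fwd, rc), strand = ifelse(canon, "+", "-"),
         has_n = grepl("N", fwd, fixed = TRUE))
  }
  a <- kmer_at(off)
  b <- kmer_at(off + d)
  keep <- !(a$has_n | b$has_n)
  if (!any(keep)) return(empty)
  data.frame(read_id = read_id, offset = off[keep],
             kmer_a = a$kmer[keep], strand_a = a$strand[keep],
             kmer_b = b$kmer[keep], strand_b = b$strand[keep],
             separation = d, stringsAsFactors = FALSE)
}

# Vectorised pair extraction over a read table ([read_fastq()] layout).
extract_pairs_all <- function(reads, params = link_params()) {
  per <- lapply(seq_len(nrow(reads)), function(i) {
    extract_pairs(reads$sequence[i], params, read_id = reads$id[i])
  })
  as.data.frame(data.table::rbindlist(per))
}

#' Build the contig-end link graph from k-mer pairs
#'
#' For every pair whose two k-mers land on different contigs, the (end, end)
#' adjacency, relative orientation, and implied gap are inferred from the hit
#' strands and positions: `gap = d - dist_a - dist_b`, where each `dist` is
#' the distance from the k-mer to its contig's outward end in the direction
#' the read travels. Pairs whose implied gap deviates from the edge's median
#' gap by more than `distance_error * d` are discarded; surviving pairs
#' aggregate into edges with support counts and gap estimates.
#'
#' @param pairs Pair table from [extract_pairs()] / internal extraction.
#' @param index Unique-k-mer index from [index_unique_kmers()].
#' @param params A [link_params()] object (same `k` as the index).
#' @return data.frame of edges: `contig1`, `side1`, `contig2`, `side2`
#'   (ends ordered lexicographically), `support`, `gap_median`, and a
#'   list-column `gaps`.
#' @export
build_link_graph <- function(pairs, index, params = link_params()) {
  stopifnot(params$k == index$k)
  d <- params$pair_distance
  k <- params$k
  lens <- index$contig_lengths
  empty <- data.frame(contig1 = character(0), side1 = character(0),
                      contig2 = character(0), side2 = character(0),
                      support = integer(0), gap_median = numeric(0),
                      stringsAsFactors = FALSE)
  empty$gaps <- list()
  if (nrow(pairs) == 0 || nrow(index$kmers) == 0) return(empty)

  ia <- match(pairs$kmer_a, index$kmers$kmer)
  ib <- match(pairs$kmer_b, index$kmers$kmer)
  keep <- !is.na(ia) & !is.na(ib)
  if (!any(keep)) return(empty)
  ia <- ia[keep]; ib <- ib[keep]
  pa <- pairs[keep, , drop = FALSE]

  ca <- index$kmers$contig[ia]
  cb <- index$kmers$contig[ib]
  diffc <- ca != cb
  if (!any(diffc)) return(empty)
  ia <- ia[diffc]; ib <- ib[diffc]; pa <- pa[diffc, , drop = FALSE]
  ca <- ca[diffc]; cb <- cb[diffc]

  pos_a <- index$kmers$pos0[ia]
  pos_b <- index$kmers$pos0[ib]
  sa <- ifelse(pa$strand_a == index$kmers$strand[ia], 1L, -1L)
  sb <- ifelse(pa$strand_b == index$kmers$strand[ib], 1L, -1L)
  len_a <- as.numeric(lens[ca])
  len_b <- as.numeric(lens[cb])

  # upstream k-mer: the read exits its contig through the end it travels to
  side_a <- ifelse(sa == 1L, "tail", "head")
  dist_a <- ifelse(sa == 1L, len_a - pos_a, pos_a + k)
  # downstream k-mer: the read entered its contig through this end
  side_b <- ifelse(sb == 1L, "head", "tail")
  dist_b <- ifelse(sb == 1L, pos_b, len_b - pos_b - k)
  gap <- d - dist_a - dist_b

  key_a <- paste(ca, side_a, sep = "\r")
  key_b <- paste(cb, side_b, sep = "\r")
  swap <- key_a > key_b
  e <- data.table::data.table(
    contig1 = ifelse(swap, cb, ca), side1 = ifelse(swap, side_b, side_a),
    contig2 = ifelse(swap, ca, cb), side2 = ifelse(swap, side_a, side_b),
    gap = gap)
  contig1 <- side1 <- contig2 <- side2 <- NULL  # NSE guards
  agg <- e[, {
    med <- stats::median(gap)
    ok <- abs(gap - med) <= params$distance_error * d
    g <- sort(gap[ok])
    list(support = length(g),
         gap_median = if (length(g) > 0) stats::median(g) else NA_real_,
         gaps = list(g))
  }, by = list(contig1, side1, contig2, side2)]
  agg <- agg[agg$support > 0]
  data.table::setorder(agg, contig1, side1, contig2, side2)
  as.data.frame(agg)
}

#' Lay out contigs into scaffolds from the link graph
#'
#' At every contig end the incident edges are ranked by support. The best
#' edge is usable iff its support reaches `min_links` and the second-best
#' support divided by the best is at most `max_link_ratio` (a lone edge has
#' ratio 0); a join is made only when the edge is usable from both of its
#' ends. Joined contigs are walked into linear layouts; cycles are broken at
#' their lowest-support edge. Internal gaps are
#' `max(round(median(gap estimates)), 1)` -- negative implied gaps
#' (overlapping contigs) floor to a 1-N gap. Scaffolds are named
#' `scaffold_0001, ...` in descending total-length order.
#'
#' @param edges Edge table from [build_link_graph()].
#' @param contigs Named character vector of contig sequences, or named
#'   numeric lengths.
#' @param params A [link_params()] object.
#' @return List with `layouts` (data.frame: `scaffold_id`, `part`,
#'   `component`, `orientation`, `gap_after`) and `rejected` (edges not used,
#'   with a `reason` column).
#' @export
layout_scaffolds <- function(edges, contigs, params = link_params()) {
  lens <- if (is.character(contigs)) nchar(contigs) else as.numeric(contigs)
  names(lens) <- names(contigs)
  ids <- sort(names(lens))

  if (nrow(edges) > 0) {
    unknown <- setdiff(unique(c(edges$contig1, edges$contig2)), ids)
    if (length(unknown) > 0) {
      stop("edge references unknown contig id(s): ",
           paste(unknown, collapse = ", "))
    }
  }

  sel <- select_joins(edges, params)
  bc <- break_cycles(sel$joins)
  rejected <- rbind(sel$rejected, bc$dropped)
  rownames(rejected) <- NULL

  layouts <- walk_layouts(bc$joins, ids, lens)
  list(layouts = layouts, rejected = rejected)
}

# Rank incident edges per end and keep edges usable from both ends.
# Ranking: support descending, ties by the lexicographic key of the partner
# end (deterministic under any input permutation).
select_joins <- function(edges, params) {
  n <- nrow(edges)
  reasons <- character(n)
  usable1 <- logical(n)
  usable2 <- logical(n)
  note <- function(i, reason) {
    if (reasons[i] == "") reasons[i] <<- reason
  }
  if (n > 0) {
    key1 <- paste(edges$contig1, edges$side1, sep = "\r")
    key2 <- paste(edges$contig2, edges$side2, sep = "\r")
    longs <- data.frame(end = c(key1, key2),
                        edge = rep(seq_len(n), 2),
                        other = c(key2, key1),
                        support = rep(edges$support, 2),
                        slot = rep(1:2, each = n),
                        stringsAsFactors = FALSE)
    for (endk in unique(longs$end)) {
      sub <- longs[longs$end == endk, , drop = FALSE]
      sub <- sub[order(-sub$support, sub$other), , drop = FALSE]
      best <- sub$edge[1]
      ratio <- if (nrow(sub) > 1) sub$support[2] / sub$support[1] else 0
      if (sub$support[1] < params$min_links) {
        note(best, "low_support")
      } else if (ratio > params$max_link_ratio) {
        note(best, "link_ratio")
      } else if (sub$slot[1] == 1L) {
        usable1[best] <- TRUE
      } else {
        usable2[best] <- TRUE
      }
      if (nrow(sub) > 1) {
        for (j in sub$edge[-1]) note(j, "outcompeted")
      }
    }
  }
  both <- usable1 & usable2
  for (i in which(!both)) note(i, "one_sided")
  rejected <- edges[!both, , drop = FALSE]
  rejected$reason <- reasons[!both]
  list(joins = edges[both, , drop = FALSE], rejected = rejected)
}

# Components under the one-join-per-end constraint are paths or simple
# cycles; break each cycle at its minimum-support edge (ties lexicographic).
break_cycles <- function(joins) {
  dropped <- joins[0, , drop = FALSE]
  dropped$reason <- character(0)
  repeat {
    if (nrow(joins) == 0) return(list(joins = joins, dropped = dropped))
    g <- igraph::graph_from_data_frame(
      data.frame(from = joins$contig1, to = joins$contig2), directed = FALSE)
    comp <- igraph::components(g)
    drop <- integer(0)
    for (ci in seq_len(comp$no)) {
      nodes <- names(comp$membership)[comp$membership == ci]
      eidx <- which(joins$contig1 %in% nodes)
      if (length(eidx) >= length(nodes)) {    # cycle
        o <- eidx[order(joins$support[eidx], joins$contig1[eidx],
                        joins$side1[eidx])]
        drop <- c(drop, o[1])
      }
    }
    if (length(drop) == 0) return(list(joins = joins, dropped = dropped))
    dd <- joins[drop, , drop = FALSE]
    dd$reason <- "cycle"
    dropped <- rbind(dropped, dd)
    joins <- joins[-drop, , drop = FALSE]
  }
}

# Walk path components into ordered, oriented layouts. A contig traversed
# head-to-tail has orientation "+". Unjoined contigs become single-part
# layouts. Naming: scaffold_0001, ... by descending total length.
walk_layouts <- function(joins, ids, lens) {
  jmap <- new.env(parent = emptyenv())
  if (nrow(joins) > 0) {
    for (i in seq_len(nrow(joins))) {
      g <- joins$gaps[[i]]
      gap <- max(round(stats::median(g)), 1)
      k1 <- paste(joins$contig1[i], joins$side1[i], sep = "\r")
      k2 <- paste(joins$contig2[i], joins$side2[i], sep = "\r")
      jmap[[k1]] <- list(contig = joins$contig2[i], side = joins$side2[i],
                         gap = gap)
      jmap[[k2]] <- list(contig = joins$contig1[i], side = joins$side1[i],
                         gap = gap)
    }
  }
  has_join <- function(contig, side) {
    !is.null(jmap[[paste(contig, side, sep = "\r")]])
  }
  free_ends <- list()
  for (id in ids) {
    for (side in c("head", "tail")) {
      if (!has_join(id, side)) {
        free_ends[[length(free_ends) + 1]] <- c(id, side)
      }
    }
  }
  visited <- new.env(parent = emptyenv())
  chains <- list()
  for (fe in free_ends) {
    id <- fe[1]
    if (!is.null(visited[[id]])) next
    enter <- fe[2]
    cur <- id
    parts <- list()
    repeat {
      visited[[cur]] <- TRUE
      exit <- if (enter == "head") "tail" else "head"
      orientation <- if (exit == "tail") "+" else "-"
      nxt <- jmap[[paste(cur, exit, sep = "\r")]]
      parts[[length(parts) + 1]] <- data.frame(
        component = cur, orientation = orientation,
        gap_after = if (is.null(nxt)) 0 else nxt$gap,
        stringsAsFactors = FALSE)
      if (is.null(nxt)) break
      cur <- nxt$contig
      enter <- nxt$side
    }
    chains[[length(chains) + 1]] <- do.call(rbind, parts)
  }
  total_len <- vapply(chains, function(ch) {
    sum(lens[ch$component]) + sum(ch$gap_after)
  }, numeric(1))
  first_id <- vapply(chains, function(ch) ch$component[1], character(1))
  o <- order(-total_len, first_id)
  out <- list()
  for (r in seq_along(o)) {
    ch <- chains[[o[r]]]
    ch$scaffold_id <- sprintf("scaffold_%04d", r)
    ch$part <- seq_len(nrow(ch))
    out[[r]] <- ch[, c("scaffold_id", "part", "component", "orientation",
                       "gap_after")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build scaffold sequences from a layout
#'
#' Components are reverse-complemented per their orientation and joined with
#' runs of N of the recorded gap length. Non-N base content is conserved
#' exactly.
#'
#' @param layouts Layout data.frame (see [layout_scaffolds()]).
#' @param components Named character vector of component sequences.
#' @return Named character vector of scaffold sequences.
#' @export
scaffold_sequences <- function(layouts, components) {
  miss <- setdiff(layouts$component, names(components))
  if (length(miss) > 0) {
    stop("unknown component id(s): ", paste(miss, collapse = ", "))
  }
  out <- character(0)
  for (sid in unique(layouts$scaffold_id)) {
    parts <- layouts[layouts$scaffold_id == sid, , drop = FALSE]
    parts <- parts[order(parts$part), , drop = FALSE]
    pieces <- character(0)
    for (i in seq_len(nrow(parts))) {
      s <- components[[parts$component[i]]]
      if (parts$orientation[i] == "-") s <- revcomp(s)
      pieces <- c(pieces, s)
      if (parts$gap_after[i] > 0) {
        pieces <- c(pieces, strrep("N", parts$gap_after[i]))
      }
    }
    out[[sid]] <- paste(pieces, collapse = "")
  }
  out
}

#' One-call link scaffolding pipeline
#'
#' Indexes unique k-mers, extracts k-mer pairs from the reads, builds the
#' link graph, lays out scaffolds, and constructs scaffold sequences.
#'
#' @param contigs Named character vector of contig sequences.
#' @param reads Read table ([read_fastq()] layout).
#' @param params A [link_params()] object.
#' @return List with `layouts`, `rejected`, `edges`, `sequences`.
#' @export
link_scaffold <- function(contigs, reads, params = link_params()) {
  index <- index_unique_kmers(contigs, params$k)
  pairs <- extract_pairs_all(reads, params)
  edges <- build_link_graph(pairs, index, params)
  lay <- layout_scaffolds(edges, contigs, params)
  seqs <- scaffold_sequences(lay$layouts, contigs)
  list(layouts = lay$layouts, rejected = lay$rejected, edges = edges,
       sequences = seqs)
}
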