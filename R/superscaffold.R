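# Cross-assembly bridging (a scaffold of one assembly spanning two scaffolds
# of the other) and reference-guided pseudomolecule construction.

#' Bridging parameters
#'
#' The 100-N join gap is the published rule; anchor and end-window thresholds
#' are configurable defaults chosen to exclude spurious repeat-driven
#' anchors.
#'
#' @param min_anchor Minimum aligned bases per anchoring block side (bp).
#' @param end_window Anchors must fall within this distance of a scaffold
#'   end (bp).
#' @param join_gap N bases inserted at each join.
#' @return List of class `bridge_params`.
#' @export
bridge_params <- function(min_anchor = 20000, end_window = 500000,
                          join_gap = 100) {
  stopifnot(min_anchor >= 1, join_gap >= 1, end_window >= 1)
  structure(list(min_anchor = min_anchor, end_window = end_window,
                 join_gap = join_gap), class = "bridge_params")
}

#' Detect bridges: B-scaffolds spanning two A-scaffold ends
#'
#' For each query (B) sequence, alignment blocks are chained per A-scaffold
#' and strand (collinear blocks only). A bridge is emitted when exactly two
#' A-scaffolds carry anchors of at least `min_anchor` aligned bases, the
#' anchors occupy disjoint, ordered query intervals, and the geometry is
#' consistent: walking along the bridge, it exits through an end of the first
#' A-scaffold and enters through an end of the second, both ends within
#' `end_window` of the respective scaffold terminus.
#'
#' @param paf PAF records with B sequences as query and A-scaffolds as
#'   target ([read_paf()] layout).
#' @param params A [bridge_params()] object.
#' @return data.frame of bridges: `bridge_id` (the B sequence), `a1`,
#'   `side1`, `orient1`, `a2`, `side2`, `orient2`, `support_bases`.
#' @export
detect_bridges <- function(paf, params = bridge_params()) {
  empty <- data.frame(bridge_id = character(0), a1 = character(0),
                      side1 = character(0), orient1 = character(0),
                      a2 = character(0), side2 = character(0),
                      orient2 = character(0), support_bases = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(paf) == 0) return(empty)
  anchors <- chain_anchors(paf)
  anchors <- anchors[anchors$abases >= params$min_anchor, , drop = FALSE]
  out <- list()
  for (q in sort(unique(anchors$qname))) {
    an <- anchors[anchors$qname == q, , drop = FALSE]
    if (length(unique(an$tname)) != 2 || nrow(an) != 2) next
    an <- an[order(an$qlo), , drop = FALSE]
    if (an$qhi[1] > an$qlo[2]) next          # overlapping query intervals
    left <- an[1, ]; right <- an[2, ]
    # left anchor: bridge continues rightwards past it
    if (left$strand == "+") {
      ok1 <- left$tlen - left$thi <= params$end_window
      side1 <- "tail"; orient1 <- "+"
    } else {
      ok1 <- left$tlo <= params$end_window
      side1 <- "head"; orient1 <- "-"
    }
    # right anchor: bridge arrives from the left
    if (right$strand == "+") {
      ok2 <- right$tlo <= params$end_window
      side2 <- "head"; orient2 <- "+"
    } else {
      ok2 <- right$tlen - right$thi <= params$end_window
      side2 <- "tail"; orient2 <- "-"
    }
    if (!(ok1 && ok2)) next
    out[[length(out) + 1]] <- data.frame(
      bridge_id = q, a1 = left$tname, side1 = side1, orient1 = orient1,
      a2 = right$tname, side2 = side2, orient2 = orient2,
      support_bases = left$abases + right$abases, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Chain alignment blocks per (query, target, strand) into anchors. Blocks
# must be collinear (query order matches target order under the strand);
# non-collinear groups are dropped conservatively.
chain_anchors <- function(paf) {
  key <- paste(paf$qname, paf$tname, paf$strand, sep = "\r")
  rows <- lapply(split(seq_len(nrow(paf)), key), function(idx) {
    d <- paf[idx, , drop = FALSE]
    d <- d[order(d$qstart), , drop = FALSE]
    if (nrow(d) > 1) {
      tdiff <- diff(d$tstart)
      coll <- if (d$strand[1] == "+") all(tdiff > 0) else all(tdiff < 0)
      if (!coll) return(NULL)
    }
    data.frame(qname = d$qname[1], tname = d$tname[1], strand = d$strand[1],
               tlen = d$tlen[1],
               qlo = min(d$qstart), qhi = max(d$qend),
               tlo = min(d$tstart), thi = max(d$tend),
               abases = sum(d$tend - d$tstart), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(qname = character(0), tname = character(0),
                      strand = character(0), tlen = numeric(0),
                      qlo = numeric(0), qhi = numeric(0), tlo = numeric(0),
                      thi = numeric(0), abases = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Apply bridges to build super-scaffolds
#'
#' Conflicting bridges -- two bridges claiming the same A-scaffold end with
#' different partners -- are all dropped (conservative; no tie-break is
#' attempted). Duplicate bridges over the same end pair collapse to the
#' best-supported one. Cycles are broken by discarding the lowest-support
#' bridge. Surviving bridges are applied transitively; every join inserts
#' exactly `join_gap` N characters and components are reverse-complemented
#' as their orientation requires. Unbridged scaffolds pass through unchanged
#' under their original names; joined super-scaffolds are named
#' `superscaffold_0001, ...` by descending length.
#'
#' @param a_sequences Named character vector of A-scaffold sequences.
#' @param bridges Bridge table from [detect_bridges()].
#' @param params A [bridge_params()] object.
#' @return List with `sequences` (named character vector), `layouts`
#'   (AGP-ready data.frame), and `dropped` (conflicting/cyclic bridges).
#' @export
apply_bridges <- function(a_sequences, bridges, params = bridge_params()) {
  stopifnot(!is.null(names(a_sequences)))
  if (nrow(bridges) > 0) {
    unknown <- setdiff(unique(c(bridges$a1, bridges$a2)), names(a_sequences))
    if (length(unknown) > 0) {
      stop("bridge references unknown scaffold id(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  dropped <- bridges[0, , drop = FALSE]

  # collapse duplicates over the same (end, end) pair: keep max support
  if (nrow(bridges) > 0) {
    k1 <- paste(bridges$a1, bridges$side1, sep = "\r")
    k2 <- paste(bridges$a2, bridges$side2, sep = "\r")
    pair <- ifelse(k1 <= k2, paste(k1, k2, sep = "\n"),
                   paste(k2, k1, sep = "\n"))
    o <- order(pair, -bridges$support_bases, bridges$bridge_id)
    bridges <- bridges[o, , drop = FALSE]
    bridges <- bridges[!duplicated(pair[o]), , drop = FALSE]
  }

  # conflict rule: any end claimed by more than one (deduplicated) bridge
  # invalidates every bridge touching that end
  if (nrow(bridges) > 0) {
    ends <- c(paste(bridges$a1, bridges$side1, sep = "\r"),
              paste(bridges$a2, bridges$side2, sep = "\r"))
    contested <- unique(ends[duplicated(ends)])
    touches <- paste(bridges$a1, bridges$side1, sep = "\r") %in% contested |
               paste(bridges$a2, bridges$side2, sep = "\r") %in% contested
    dropped <- rbind(dropped, bridges[touches, , drop = FALSE])
    bridges <- bridges[!touches, , drop = FALSE]
  }

  # cycles: drop the bridge with the smallest support and retry
  repeat {
    if (nrow(bridges) == 0) break
    g <- igraph::graph_from_data_frame(
      data.frame(from = bridges$a1, to = bridges$a2), directed = FALSE)
    comp <- igraph::components(g)
    cyc <- integer(0)
    for (ci in seq_len(comp$no)) {
      nodes <- names(comp$membership)[comp$membership == ci]
      eidx <- which(bridges$a1 %in% nodes)
      if (length(eidx) >= length(nodes)) {
        o <- eidx[order(bridges$support_bases[eidx], bridges$bridge_id[eidx])]
        cyc <- c(cyc, o[1])
      }
    }
    if (length(cyc) == 0) break
    dropped <- rbind(dropped, bridges[cyc, , drop = FALSE])
    bridges <- bridges[-cyc, , drop = FALSE]
  }

  joins <- data.frame(contig1 = bridges$a1, side1 = bridges$side1,
                      contig2 = bridges$a2, side2 = bridges$side2,
                      support = bridges$support_bases,
                      stringsAsFactors = FALSE)
  joins$gaps <- as.list(rep(params$join_gap, nrow(joins)))
  lens <- nchar(a_sequences)
  layouts <- walk_layouts(joins, sort(names(a_sequences)), lens)

  # joined chains get superscaffold names; singletons keep their own id
  n_parts <- table(layouts$scaffold_id)
  relabel <- character(0)
  counter <- 0
  for (sid in unique(layouts$scaffold_id)) {
    if (n_parts[[sid]] == 1) {
      relabel[sid] <- layouts$component[layouts$scaffold_id == sid][1]
    } else {
      counter <- counter + 1
      relabel[sid] <- sprintf("superscaffold_%04d", counter)
    }
  }
  layouts$scaffold_id <- relabel[layouts$scaffold_id]
  sequences <- scaffold_sequences(layouts, a_sequences)
  rownames(dropped) <- NULL
  list(sequences = sequences, layouts = layouts, dropped = dropped)
}

#' Anchor super-scaffolds to reference chromosomes
#'
#' Each super-scaffold is assigned to the chromosome receiving the largest
#' share of its aligned bases, provided that share is at least
#' `min_cov_frac`; its orientation is the strand carrying the majority of
#' aligned bases. Within a chromosome, super-scaffolds are ordered by the
#' weighted median reference position of their aligned bases and
#' concatenated with `join_gap`-N gaps into a pseudomolecule named after the
#' chromosome. Sequences failing the share threshold are reported unplaced.
#'
#' @param paf PAF records of super-scaffolds (query) aligned to reference
#'   chromosomes (target).
#' @param sequences Named character vector of super-scaffold sequences.
#' @param min_cov_frac Minimum fraction of aligned bases on the assigned
#'   chromosome (default 0.3).
#' @param join_gap N bases between consecutive super-scaffolds (default 100).
#' @return List with `assignments` (data.frame: `seq_id`, `chromosome`,
#'   `orientation`, `order_key`, `share`, `placed`), `layouts`, `sequences`
#'   (pseudomolecules), `unplaced` (character vector).
#' @export
anchor_to_reference <- function(paf, sequences, min_cov_frac = 0.3,
                                join_gap = 100) {
  stopifnot(!is.null(names(sequences)))
  rows <- list()
  for (q in sort(names(sequences))) {
    d <- paf[paf$qname == q, , drop = FALSE]
    if (nrow(d) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = q, chromosome = NA_character_, orientation = NA_character_,
        order_key = NA_real_, share = NA_real_, placed = FALSE,
        stringsAsFactors = FALSE)
      next
    }
    ab <- tapply(d$tend - d$tstart, d$tname, sum)
    total <- sum(ab)
    best <- names(ab)[order(-ab, names(ab))][1]
    share <- ab[[best]] / total
    db <- d[d$tname == best, , drop = FALSE]
    w <- db$tend - db$tstart
    plus <- sum(w[db$strand == "+"])
    orientation <- if (plus >= sum(w) / 2) "+" else "-"
    ok <- weighted_median((db$tstart + db$tend) / 2, w)
    rows[[length(rows) + 1]] <- data.frame(
      seq_id = q, chromosome = if (share >= min_cov_frac) best else NA_character_,
      orientation = orientation, order_key = ok, share = share,
      placed = share >= min_cov_frac, stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, rows)
  rownames(assignments) <- NULL

  placed <- assignments[assignments$placed, , drop = FALSE]
  layouts <- list()
  for (chrom in sort(unique(placed$chromosome))) {
    p <- placed[placed$chromosome == chrom, , drop = FALSE]
    p <- p[order(p$order_key, p$seq_id), , drop = FALSE]
    layouts[[length(layouts) + 1]] <- data.frame(
      scaffold_id = chrom, part = seq_len(nrow(p)), component = p$seq_id,
      orientation = p$orientation,
      gap_after = c(rep(join_gap, nrow(p) - 1), 0),
      stringsAsFactors = FALSE)
  }
  layouts <- if (length(layouts) > 0) do.call(rbind, layouts) else
    data.frame(scaffold_id = character(0), part = integer(0),
               component = character(0), orientation = character(0),
               gap_after = numeric(0), stringsAsFactors = FALSE)
  rownames(layouts) <- NULL
  pseudo <- scaffold_sequences(layouts, sequences)
  list(assignments = assignments, layouts = layouts, sequences = pseudo,
       unplaced = assignments$seq_id[!assignments$placed])
}

# Weighted median: smallest x whose cumulative weight reaches half the total.
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1]]
}
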