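# Shared fixtures built in code.

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Extract the (end, end) joins implied by a layout table:
# exiting a "+" component crosses its tail; entering a "+" component crosses
# its head.
layout_joins <- function(layouts) {
  keys <- character(0)
  for (sid in unique(layouts$scaffold_id)) {
    p <- layouts[layouts$scaffold_id == sid, , drop = FALSE]
    p <- p[order(p$part), , drop = FALSE]
    if (nrow(p) < 2) next
    for (i in seq_len(nrow(p) - 1)) {
      s1 <- if (p$orientation[i] == "+") "tail" else "head"
      s2 <- if (p$orientation[i + 1] == "+") "head" else "tail"
      keys <- c(keys, paste(p$component[i], s1, p$component[i + 1], s2))
    }
  }
  keys
}

# Both directions of the true adjacency keys of a fragmentation.
truth_join_keys <- function(frag) {
  adj <- frag$adjacencies
  c(paste(adj$contig1, adj$side1, adj$contig2, adj$side2),
    paste(adj$contig2, adj$side2, adj$contig1, adj$side1))
}

count_acgt <- function(seqs) {
  sum(vapply(seqs, function(s) {
    sum(charToRaw(s) %in% charToRaw("ACGT"))
  }, numeric(1)))
}

# Deterministic second fragmentation whose contigs span consecutive
# midpoints of a first fragmentation's contigs: every A-gap is bridged with
# roughly half-contig anchors on both sides.
midpoint_fragmentation <- function(frag_a, prefix = "B") {
  contigs <- character(0)
  map_rows <- list()
  for (cn in unique(frag_a$map$chrom)) {
    am <- frag_a$map[frag_a$map$chrom == cn, , drop = FALSE]
    mids <- floor((am$gstart + am$gend) / 2)
    bounds <- c(0, mids, nchar(frag_a$truth$genome[[cn]]))
    for (j in seq_len(length(bounds) - 1)) {
      id <- sprintf("%s_%s%02d", cn, prefix, j)
      gs <- bounds[j]
      ge <- bounds[j + 1]
      contigs[[id]] <- substr(frag_a$truth$genome[[cn]], gs + 1, ge)
      map_rows[[length(map_rows) + 1]] <- data.frame(
        contig = id, chrom = cn, gstart = gs, gend = ge, flipped = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(contigs = contigs, map = do.call(rbind, map_rows),
                 adjacencies = NULL, truth = frag_a$truth),
            class = "sim_fragmentation")
}
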