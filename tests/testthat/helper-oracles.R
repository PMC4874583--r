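# Independent oracles the implementation is checked against: brute-force
# all-pairs edge enumeration, breadth-first-search components over an
# explicit edge list, the adjacent-gap single-linkage rule, and small
# random-instance generators.  These deliberately share no code with the
# package internals.

# All same-chromosome pairs (i, j), i < j in row order, with |dpos| below the
# threshold: O(n^2) enumeration via the full distance matrix.
oracle_edges <- function(sites, threshold, inclusive = FALSE) {
  from <- integer(0); to <- integer(0)
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    if (length(idx) < 2) next
    d <- abs(outer(sites$pos[idx], sites$pos[idx], "-"))
    hit <- which(upper.tri(d) & (if (inclusive) d <= threshold else d < threshold),
                 arr.ind = TRUE)
    from <- c(from, idx[hit[, 1]])
    to <- c(to, idx[hit[, 2]])
  }
  list(from = from, to = to)
}

# Breadth-first search components over an explicit edge list; returns a
# component id per node.
oracle_bfs <- function(n, from, to) {
  adj <- split(c(to, from), factor(c(from, to), levels = seq_len(n)))
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[is.na(comp[nb])]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  comp
}

# Adjacent-gap single-linkage rule applied directly to the sorted positions:
# a new cluster starts where the gap between consecutive positions reaches
# the threshold (or the chromosome changes).
oracle_gap_rule <- function(sites, threshold, inclusive = FALSE) {
  comp <- integer(nrow(sites))
  cid <- 0L
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    p <- sites$pos[idx]
    gap <- c(Inf, diff(p))
    brk <- if (inclusive) gap > threshold else gap >= threshold
    comp[idx] <- cid + cumsum(brk)
    cid <- cid + sum(brk)
  }
  comp
}

# Canonical signature of a partition given as a membership vector over
# row_ids: comparable across algorithms and orderings.
partition_signature <- function(row_ids, comp) {
  unname(sort(vapply(split(row_ids, comp),
                     function(x) paste(sort(x), collapse = ","), character(1)),
              method = "radix"))
}

cis_set_signature <- function(cis_set) {
  unname(sort(vapply(cis_set,
                     function(c) paste(sort(c$members$row_id), collapse = ","),
                     character(1)), method = "radix"))
}

# Random IS dataset: duplicate positions allowed on purpose.
random_sites <- function(n, n_chrom = 3, max_pos = 1e5, labels = c("A", "B", "C")) {
  sort_sites(data.frame(
    chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    pos = sample.int(max_pos, n, replace = TRUE),
    label = sample(labels, n, replace = TRUE)))
}

make_sites <- function(pos, chrom = "chr1", label = "t") {
  sort_sites(data.frame(chrom = chrom, pos = pos, label = label))
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
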