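# shared fixtures and independent oracles, all built in code

# layout from a 0/1 label vector (LSG vs other), unit-ish coordinates
make_layout <- function(labels, chrom = "chrI") {
  n <- length(labels)
  chromosome_layout(data.frame(
    gene_id = sprintf("%s_g%03d", chrom, seq_len(n)),
    chrom = chrom,
    start = seq_len(n) * 1000,
    end = seq_len(n) * 1000 + 500,
    strand = "+",
    class = ifelse(labels == 1, "LSG", "other"),
    stringsAsFactors = FALSE))
}

# brute-force max-gap cluster oracle: enumerate every contiguous sublist of
# labeled positions, keep valid (all gaps <= max_gap) maximal ones of
# size >= 2.  Independent of the greedy scan in find_clusters().
oracle_clusters <- function(labels, max_gap) {
  pos <- which(labels == 1L)
  k <- length(pos)
  out <- list()
  if (k < 2) return(out)
  valid <- function(i, j) all(diff(pos[i:j]) <= max_gap + 1L)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!valid(i, j)) next
      left_ext <- i > 1 && valid(i - 1L, j)
      right_ext <- j < k && valid(i, j + 1L)
      if (!left_ext && !right_ext) out[[length(out) + 1L]] <- pos[i:j]
    }
  }
  out
}

# counts matrix with per-sample totals forced to `total` by a filler gene,
# so CPM of the focal genes equals their raw counts * 1e6 / total
make_counts <- function(gene_counts, conditions, reps = 2, total = 1e6) {
  n <- nrow(gene_counts)
  k <- length(conditions)
  samples <- data.frame(
    sample = sprintf("%s_R%d", rep(conditions, each = reps),
                     rep(seq_len(reps), k)),
    condition = rep(conditions, each = reps),
    replicate = rep(seq_len(reps), k))
  counts <- matrix(0L, n + 1, k * reps,
                   dimnames = list(c(rownames(gene_counts), "filler"),
                                   samples$sample))
  for (j in seq_len(k * reps)) {
    cond <- match(samples$condition[j], conditions)
    counts[seq_len(n), j] <- gene_counts[, cond]
    counts[n + 1, j] <- total - sum(gene_counts[, cond])
  }
  list(counts = counts, samples = samples)
}
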