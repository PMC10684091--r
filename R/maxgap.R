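#' Detect max-gap clusters of labeled genes
#'
#' A max-gap cluster is a maximal run of labeled genes in chromosomal order
#' in which consecutive labeled genes are separated by at most `max_gap`
#' unlabeled genes.  Gaps are counted in genes, not base pairs.  Runs of a
#' single labeled gene are never clusters (minimum size 2).  Clusters are
#' disjoint and cover every labeled gene that belongs to a size >= 2 run;
#' maximality makes the decomposition unique, so the greedy left-to-right
#' scan is exact.
#'
#' @param layout a [chromosome_layout()] (may span several chromosomes).
#' @param max_gap maximum number of intervening unlabeled genes (>= 0).
#' @return list of `gene_cluster` objects, each a list with `chromosome`,
#'   `member_indices` (per-chromosome gene ordinals), `members` (gene ids),
#'   `size`, `max_gap`, `gap_sequence`, `span` (physical start/end), and
#'   `p_value` (NA until [cluster_pvalue()]).
#' @seealso [cluster_pvalue()], [summarize_clusters()]
#' @export
find_clusters <- function(layout, max_gap) {
  stopifnot(inherits(layout, "chromosome_layout"), max_gap >= 0)
  max_gap <- as.integer(max_gap)
  out <- list()
  for (ch in unique(layout$chrom)) {
    g <- layout[layout$chrom == ch, , drop = FALSE]
    pos <- which(g$label == 1L)
    if (length(pos) < 2L) next
    d <- diff(pos)
    grp <- cumsum(c(1L, as.integer(d > max_gap + 1L)))
    for (k in split(seq_along(pos), grp)) {
      if (length(k) < 2L) next
      idx <- pos[k]
      out[[length(out) + 1L]] <- structure(list(
        chromosome = ch,
        member_indices = idx,
        members = g$gene_id[idx],
        size = length(idx),
        max_gap = max_gap,
        gap_sequence = diff(idx) - 1L,
        span = c(start = g$start[idx[1L]], end = g$end[idx[length(idx)]]),
        p_value = NA_real_
      ), class = "gene_cluster")
    }
  }
  out
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(sprintf("<gene_cluster> %s: %d genes (ordinals %d-%d), max_gap=%d, p=%s\n",
              x$chromosome, x$size, min(x$member_indices),
              max(x$member_indices), x$max_gap,
              format(x$p_value, digits = 3)))
  invisible(x)
}

# largest run of 1s under the max-gap rule; 0 when no label present
max_run_size <- function(labels, max_gap) {
  pos <- which(labels == 1L)
  if (length(pos) == 0L) return(0L)
  if (length(pos) == 1L) return(1L)
  d <- diff(pos)
  grp <- cumsum(c(1L, as.integer(d > max_gap + 1L)))
  max(tabulate(grp))
}

#' Permutation p-value of a max-gap cluster
#'
#' The null model permutes the chromosome's label vector uniformly
#' (chromosome-stratified, preserving the per-chromosome label count).  The
#' p-value is `(1 + b) / (1 + n_perm)` where `b` counts permutations whose
#' label vector contains at least one max-gap run of size >= the observed
#' cluster size at the same `max_gap`.
#'
#' @param cluster a `gene_cluster` from [find_clusters()].
#' @param layout the layout the cluster was derived from.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return p-value in (0, 1].
#' @export
cluster_pvalue <- function(cluster, layout, n_perm = 2000L, seed = 1L) {
  stopifnot(inherits(cluster, "gene_cluster"),
            inherits(layout, "chromosome_layout"))
  if (n_perm < 100L) stop("n_perm must be >= 100")
  labels <- layout$label[layout$chrom == cluster$chromosome]
  if (length(labels) == 0L) stop("cluster chromosome absent from layout")
  if (max(cluster$member_indices) > length(labels) ||
      any(labels[cluster$member_indices] != 1L)) {
    stop("cluster is inconsistent with the layout it claims to come from")
  }
  null_max <- null_max_run_sizes(labels, cluster$max_gap, n_perm, seed)
  unname((1 + sum(null_max >= cluster$size)) / (1 + n_perm))
}

# shared permutation machinery: null distribution of the largest run size
null_max_run_sizes <- function(labels, max_gap, n_perm, seed) {
  set.seed(seed)
  n <- length(labels)
  vapply(seq_len(n_perm), function(i) {
    max_run_size(sample(labels, n), max_gap)
  }, integer(1))
}

#' Permutation p-values for a set of clusters
#'
#' Vectorized companion of [cluster_pvalue()]: clusters on the same
#' chromosome share one set of permutations, and Benjamini-Hochberg
#' adjusted p-values are attached genome-wide.
#'
#' @inheritParams cluster_pvalue
#' @param clusters list of `gene_cluster` objects (one `max_gap`).
#' @return the clusters, each with `p_value` and `p_adjusted` filled in.
#' @export
cluster_pvalues <- function(clusters, layout, n_perm = 2000L, seed = 1L) {
  stopifnot(inherits(layout, "chromosome_layout"))
  if (length(clusters) == 0L) return(clusters)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  chroms <- vapply(clusters, `[[`, character(1), "chromosome")
  gaps <- vapply(clusters, `[[`, integer(1), "max_gap")
  if (length(unique(gaps)) != 1L) stop("clusters mix max_gap values")
  p <- numeric(length(clusters))
  for (ch in unique(chroms)) {
    labels <- layout$label[layout$chrom == ch]
    null_max <- null_max_run_sizes(labels, gaps[1L], n_perm,
                                   seed + match(ch, unique(layout$chrom)))
    for (i in which(chroms == ch)) {
      p[i] <- (1 + sum(null_max >= clusters[[i]]$size)) / (1 + n_perm)
    }
  }
  padj <- bh_adjust(p)
  for (i in seq_along(clusters)) {
    clusters[[i]]$p_value <- p[i]
    clusters[[i]]$p_adjusted <- padj[i]
  }
  clusters
}

#' Tabulate clusters by size
#'
#' Produces the per-size summary used to report clustering of a gene class:
#' for each cluster size, the number of clusters, the number of genes they
#' contain (size x clusters), and the percentage of the class total, plus a
#' totals row.
#'
#' @param clusters list of `gene_cluster` objects.
#' @param class_total number of genes in the focal class (denominator of
#'   the percentage column); must be >= the number of clustered genes.
#' @return data.frame `cluster_size`, `n_clusters`, `n_genes`,
#'   `pct_class_genes`, with a final `"total"` row.
#' @export
summarize_clusters <- function(clusters, class_total) {
  sizes <- vapply(clusters, `[[`, integer(1), "size")
  if (class_total < sum(sizes)) {
    stop("class_total (", class_total, ") is smaller than the number of ",
         "clustered genes (", sum(sizes), ")")
  }
  if (length(sizes) == 0L || class_total == 0L) {
    return(data.frame(cluster_size = "total", n_clusters = 0L, n_genes = 0L,
                      pct_class_genes = 0, stringsAsFactors = FALSE))
  }
  tab <- table(sizes)
  size_num <- as.integer(names(tab))
  n_clusters <- as.integer(tab)
  n_genes <- size_num * n_clusters
  out <- data.frame(
    cluster_size = as.character(size_num),
    n_clusters = n_clusters,
    n_genes = n_genes,
    pct_class_genes = 100 * n_genes / class_total,
    stringsAsFactors = FALSE)
  out <- out[order(size_num), , drop = FALSE]
  out <- rbind(out, data.frame(
    cluster_size = "total", n_clusters = sum(n_clusters),
    n_genes = sum(n_genes),
    pct_class_genes = 100 * sum(n_genes) / class_total,
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Coerce clusters to a data.frame
#'
#' @param clusters list of `gene_cluster` objects.
#' @return data.frame, one row per cluster.
#' @export
clusters_as_data_frame <- function(clusters) {
  if (length(clusters) == 0L) {
    return(data.frame(cluster_id = integer(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), size = integer(0),
                      max_gap = integer(0), members = character(0),
                      p_value = numeric(0), p_adjusted = numeric(0)))
  }
  data.frame(
    cluster_id = seq_along(clusters),
    chrom = vapply(clusters, `[[`, character(1), "chromosome"),
    start = vapply(clusters, function(x) unname(x$span["start"]), numeric(1)),
    end = vapply(clusters, function(x) unname(x$span["end"]), numeric(1)),
    size = vapply(clusters, `[[`, integer(1), "size"),
    max_gap = vapply(clusters, `[[`, integer(1), "max_gap"),
    members = vapply(clusters, function(x) paste(x$members, collapse = ","),
                     character(1)),
    p_value = vapply(clusters, `[[`, numeric(1), "p_value"),
    p_adjusted = vapply(clusters, function(x) x$p_adjusted %||% NA_real_,
                        numeric(1)),
    stringsAsFactors = FALSE)
}
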