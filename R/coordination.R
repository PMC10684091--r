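#' Co-expression coordination within one gene cluster
#'
#' Computes pairwise correlation (Pearson by default) between the
#' condition-ordered relative-expression profiles of the cluster members,
#' over the conditions where both genes are measurable (level > 0;
#' unmeasurable conditions are dropped pairwise, never imputed).  Pairs
#' need at least `min_shared` shared measurable conditions; genes with
#' constant profiles give undefined correlations and are excluded from the
#' maximum rather than treated as 0.  The cluster is *coordinated* iff the
#' largest off-diagonal coefficient exceeds `r_threshold`.
#'
#' @param cluster a `gene_cluster` from [find_clusters()], or a character
#'   vector of member gene ids.
#' @param rel a [relative_expression()] result, or a genes x conditions
#'   matrix of relative levels (0 = unmeasurable).
#' @param include_neighbors number of flanking genes on each side of the
#'   cluster to include (requires a `gene_cluster` plus `layout`).
#' @param layout layout used to resolve neighbors.
#' @param method correlation method (`"pearson"` or `"spearman"`).
#' @param min_shared minimum shared measurable conditions per pair.
#' @param r_threshold coordination threshold on the max off-diagonal
#'   coefficient (default 0.5).
#' @return object of class `coordination_result`: list with `cluster_id`,
#'   `members`, `cor_matrix`, `n_pairs` (usable pairs), `max_offdiag_r`,
#'   `coordinated`, `reason` (`"ok"` or `"<2 usable genes"`).
#' @export
cluster_correlations <- function(cluster, rel, include_neighbors = 0L,
                                 layout = NULL, method = "pearson",
                                 min_shared = 3L, r_threshold = 0.5) {
  if (inherits(cluster, "gene_cluster")) {
    members <- cluster$members
    cluster_id <- paste0(cluster$chromosome, ":",
                         min(cluster$member_indices), "-",
                         max(cluster$member_indices))
    if (include_neighbors > 0L) {
      if (is.null(layout)) stop("neighbor inclusion needs the layout")
      g <- layout[layout$chrom == cluster$chromosome, , drop = FALSE]
      lo <- max(1L, min(cluster$member_indices) - include_neighbors)
      hi <- min(nrow(g), max(cluster$member_indices) + include_neighbors)
      members <- unique(c(g$gene_id[lo:hi]))
    }
  } else {
    members <- as.character(cluster)
    cluster_id <- NA_character_
  }
  lev <- if (inherits(rel, "rel_expr")) rel$level else as.matrix(rel)
  members <- intersect(members, rownames(lev))
  k <- length(members)
  empty <- function(reason) {
    structure(list(cluster_id = cluster_id, members = members,
                   cor_matrix = matrix(NA_real_, k, k,
                                       dimnames = list(members, members)),
                   n_pairs = 0L, max_offdiag_r = NA_real_,
                   coordinated = FALSE, reason = reason),
              class = "coordination_result")
  }
  if (k < 2L) return(empty("<2 usable genes"))
  prof <- lev[members, , drop = FALSE]
  cm <- matrix(NA_real_, k, k, dimnames = list(members, members))
  diag(cm) <- 1
  n_pairs <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      use <- prof[i, ] > 0 & prof[j, ] > 0
      if (sum(use) < min_shared) next
      x <- prof[i, use]
      y <- prof[j, use]
      if (sd(x) == 0 || sd(y) == 0) next
      r <- cor(x, y, method = method)
      cm[i, j] <- cm[j, i] <- r
      n_pairs <- n_pairs + 1L
    }
  }
  off <- cm[upper.tri(cm)]
  if (all(is.na(off))) {
    out <- empty("<2 usable genes")
    out$cor_matrix <- cm
    return(out)
  }
  max_r <- max(off, na.rm = TRUE)
  structure(list(cluster_id = cluster_id, members = members,
                 cor_matrix = cm, n_pairs = n_pairs,
                 max_offdiag_r = max_r,
                 coordinated = max_r > r_threshold, reason = "ok"),
            class = "coordination_result")
}

#' @export
print.coordination_result <- function(x, ...) {
  cat(sprintf("<coordination_result> %s: %d members, %d usable pairs, max r = %s, %s\n",
              x$cluster_id, length(x$members), x$n_pairs,
              format(x$max_offdiag_r, digits = 3),
              if (x$coordinated) "coordinated" else
                paste0("not coordinated (", x$reason, ")")))
  invisible(x)
}

#' Screen a set of clusters for coordinated expression
#'
#' @param clusters list of `gene_cluster` objects.
#' @param rel a [relative_expression()] result (or levels matrix).
#' @param ... passed to [cluster_correlations()].
#' @return list of `coordination_result`, sorted by `max_offdiag_r`
#'   descending (undefined maxima last).
#' @export
screen_clusters <- function(clusters, rel, ...) {
  res <- lapply(clusters, cluster_correlations, rel = rel, ...)
  if (length(res) == 0L) return(res)
  key <- vapply(res, `[[`, numeric(1), "max_offdiag_r")
  res[order(key, decreasing = TRUE, na.last = TRUE)]
}
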