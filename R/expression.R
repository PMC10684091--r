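#' Relative expression normalized to the lowest condition
#'
#' Converts a replicated count matrix into per-gene, per-condition relative
#' expression levels in the style of Bayesian relative-expression reports:
#' the lowest measurable condition of a gene is set to 1, conditions with
#' unmeasurable expression are reported as 0, and 95% credible intervals
#' accompany each level.
#'
#' Counts are library-size normalized (counts per million).  A gene is
#' *detectable* in a condition iff its CPM reaches `detect_threshold` in at
#' least half of the replicates.  The per-condition transcription rate is
#' modeled as Gamma-Poisson: pooling replicates, the rate posterior under a
#' Jeffreys-style prior is `Gamma(K + pseudocount, N)` with `K` the summed
#' counts and `N` the summed library size (in millions).  Ratios of
#' independent Gamma posteriors are scaled F distributed, giving closed-form
#' interval quantiles and contrast p-values.
#'
#' @param counts genes x samples matrix of non-negative integers (or the
#'   list returned by [simulate_counts()]).
#' @param samples sample sheet data.frame with columns `sample`,
#'   `condition`, `replicate`; every sample must map to one condition and
#'   every condition needs >= 2 replicates.
#' @param pseudocount Gamma shape added to the summed counts (default 0.5,
#'   the Jeffreys prior).
#' @param detect_threshold CPM that must be reached in at least half of the
#'   replicates for a condition to count as measurable.
#' @param lib_sizes optional named per-sample library sizes; defaults to
#'   the column sums of `counts`.  Supplying external sizes makes relative
#'   levels exactly invariant to rescaling a single gene's counts.
#' @return object of class `rel_expr`: list with genes x conditions
#'   matrices `level`, `lower95`, `upper95`, `detectable`, `cpm_mean`,
#'   posterior parameters `shape` and `rate_denom`, the per-gene reference
#'   condition index `reference` (NA when nothing is detectable), and
#'   `conditions`, `genes`.
#' @export
relative_expression <- function(counts, samples = NULL, pseudocount = 0.5,
                                detect_threshold = 1, lib_sizes = NULL) {
  if (is.list(counts) && !is.matrix(counts) && all(c("counts", "samples") %in%
                                                   names(counts))) {
    samples <- counts$samples
    counts <- counts$counts
  }
  stopifnot(is.matrix(counts), !is.null(samples))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(samples$sample %in% colnames(counts))) {
    stop("sample sheet lists samples absent from the count matrix")
  }
  if (anyDuplicated(samples$sample)) {
    stop("a sample maps to more than one condition")
  }
  counts <- counts[, samples$sample, drop = FALSE]
  conds <- unique(samples$condition)
  reps_per <- table(samples$condition)
  if (any(reps_per < 2)) {
    stop("every condition needs >= 2 replicates for interval estimation")
  }
  libsize <- if (is.null(lib_sizes)) colSums(counts) else {
    if (!all(colnames(counts) %in% names(lib_sizes))) {
      stop("lib_sizes must name every sample")
    }
    lib_sizes[colnames(counts)]
  }
  cpm <- sweep(counts, 2, pmax(libsize, 1) / 1e6, "/")

  n <- nrow(counts)
  k <- length(conds)
  genes <- rownames(counts) %||% sprintf("gene%d", seq_len(n))

  detectable <- matrix(FALSE, n, k, dimnames = list(genes, conds))
  cpm_mean <- matrix(0, n, k, dimnames = list(genes, conds))
  shape <- matrix(0, n, k, dimnames = list(genes, conds))
  rate_denom <- matrix(0, n, k, dimnames = list(genes, conds))
  for (j in seq_len(k)) {
    sel <- samples$sample[samples$condition == conds[j]]
    sub_cpm <- cpm[, sel, drop = FALSE]
    detectable[, j] <- rowSums(sub_cpm >= detect_threshold) >=
      length(sel) / 2
    cpm_mean[, j] <- rowMeans(sub_cpm)
    shape[, j] <- rowSums(counts[, sel, drop = FALSE]) + pseudocount
    rate_denom[, j] <- sum(libsize[match(sel, samples$sample)]) / 1e6
  }

  level <- matrix(0, n, k, dimnames = list(genes, conds))
  lower <- matrix(0, n, k, dimnames = list(genes, conds))
  upper <- matrix(0, n, k, dimnames = list(genes, conds))
  reference <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    det <- which(detectable[i, ])
    if (length(det) == 0L) next
    ref <- det[which.min(cpm_mean[i, det])]
    reference[i] <- ref
    a_r <- shape[i, ref]
    b_r <- rate_denom[i, ref]
    for (j in det) {
      level[i, j] <- cpm_mean[i, j] / cpm_mean[i, ref]
      a_c <- shape[i, j]
      b_c <- rate_denom[i, j]
      # lambda_c / lambda_ref ~ (b_r a_c)/(b_c a_r) * F(2 a_c, 2 a_r)
      scale <- (b_r * a_c) / (b_c * a_r)
      lower[i, j] <- scale * qf(0.025, 2 * a_c, 2 * a_r)
      upper[i, j] <- scale * qf(0.975, 2 * a_c, 2 * a_r)
    }
  }
  structure(list(level = level, lower95 = lower, upper95 = upper,
                 detectable = detectable, cpm_mean = cpm_mean,
                 shape = shape, rate_denom = rate_denom,
                 reference = reference, conditions = conds, genes = genes),
            class = "rel_expr")
}

#' @export
print.rel_expr <- function(x, ...) {
  cat(sprintf("<rel_expr> %d genes x %d conditions (%s)\n",
              length(x$genes), length(x$conditions),
              paste(x$conditions, collapse = ", ")))
  invisible(x)
}

# two-sided posterior contrast p-value between two Gamma posteriors,
# vectorized over genes
.gamma_contrast_p <- function(a1, b1, a2, b2) {
  # P(lambda1 <= lambda2) with lambda1/lambda2 scaled-F distributed
  p_le <- pf((b1 * a2) / (b2 * a1), 2 * a1, 2 * a2)
  pmin(1, 2 * pmin(p_le, 1 - p_le))
}

#' Call dynamically expressed genes
#'
#' A gene is *dynamic* iff (a) it is detectable in at least two conditions,
#' (b) the max/min ratio of its relative levels across detectable
#' conditions reaches `fold`, and (c) the max-versus-min posterior contrast
#' is significant at `alpha` after Benjamini-Hochberg adjustment across all
#' tested genes.
#'
#' @param rel a [relative_expression()] result.
#' @param fold minimum fold change (default 5).
#' @param alpha significance level on BH-adjusted contrast p-values.
#' @return character vector of dynamic gene ids; the full per-gene table
#'   (`gene_id`, `fold`, `p`, `p_adjusted`, `dynamic`, `excluded`) is
#'   attached as attribute `"detail"`.
#' @export
call_dynamic <- function(rel, fold = 5, alpha = 0.05) {
  stopifnot(inherits(rel, "rel_expr"))
  if (length(rel$conditions) < 2) stop("need >= 2 conditions")
  n <- length(rel$genes)
  fold_obs <- rep(NA_real_, n)
  p <- rep(NA_real_, n)
  excluded <- rep(FALSE, n)
  for (i in seq_len(n)) {
    det <- which(rel$detectable[i, ])
    if (length(det) < 2L) {
      excluded[i] <- TRUE
      next
    }
    jmax <- det[which.max(rel$level[i, det])]
    jmin <- det[which.min(rel$level[i, det])]
    fold_obs[i] <- rel$level[i, jmax] / rel$level[i, jmin]
    p[i] <- .gamma_contrast_p(rel$shape[i, jmax], rel$rate_denom[i, jmax],
                              rel$shape[i, jmin], rel$rate_denom[i, jmin])
  }
  padj <- rep(NA_real_, n)
  tested <- !excluded
  padj[tested] <- bh_adjust(p[tested])
  dynamic <- tested & fold_obs >= fold & padj <= alpha
  dynamic[is.na(dynamic)] <- FALSE
  detail <- data.frame(gene_id = rel$genes, fold = fold_obs, p = p,
                       p_adjusted = padj, dynamic = dynamic,
                       excluded = excluded, stringsAsFactors = FALSE)
  structure(rel$genes[dynamic], detail = detail)
}

#' Expression status across sampled points
#'
#' A gene is expressed overall iff it is detectable in at least
#' `min_points` of the sampled conditions; genes detected at exactly one
#' point are flagged (`single_point_only`), matching the convention of
#' reporting them parenthetically.
#'
#' @param rel a [relative_expression()] result.
#' @param min_points detections required to count as expressed (default 2).
#' @return data.frame `gene_id`, `n_points_detected`, `expressed_overall`,
#'   `single_point_only`.
#' @export
status_across_stages <- function(rel, min_points = 2) {
  stopifnot(inherits(rel, "rel_expr"))
  if (length(rel$conditions) < 2) stop("need >= 2 sampled points")
  npts <- rowSums(rel$detectable)
  data.frame(gene_id = rel$genes,
             n_points_detected = as.integer(npts),
             expressed_overall = npts >= min_points,
             single_point_only = npts == 1L,
             stringsAsFactors = FALSE)
}

#' Pair categories used by classify_pair
#' @export
pair_categories <- function() {
  c("only_in_mutant", "higher_in_mutant", "no_difference",
    "not_measurable_in_either", "higher_in_wildtype", "only_in_wildtype")
}

#' Six-way mutant-versus-wildtype expression categories
#'
#' Classifies each gene by detectability first and, when the gene is
#' measurable in both strains, by the BH-adjusted posterior contrast:
#' `only_in_mutant`, `higher_in_mutant`, `no_difference`,
#' `not_measurable_in_either`, `higher_in_wildtype`, `only_in_wildtype`.
#' The six categories are exhaustive and mutually exclusive.
#'
#' @param rel_mutant,rel_wildtype [relative_expression()] results sharing
#'   the gene universe (each may hold several conditions).
#' @param alpha significance level on BH-adjusted contrasts.
#' @param mutant_condition,wildtype_condition condition to compare (default
#'   the single condition of each table, otherwise required).
#' @return data.frame `gene_id`, `category` (factor over the six levels),
#'   `p`, `p_adjusted`.
#' @export
classify_pair <- function(rel_mutant, rel_wildtype, alpha = 0.05,
                          mutant_condition = NULL, wildtype_condition = NULL) {
  stopifnot(inherits(rel_mutant, "rel_expr"), inherits(rel_wildtype, "rel_expr"))
  if (!identical(rel_mutant$genes, rel_wildtype$genes)) {
    stop("mutant and wildtype tables must share the gene universe")
  }
  pick <- function(rel, cond, who) {
    if (is.null(cond)) {
      if (length(rel$conditions) != 1L) {
        stop("several conditions in the ", who, " table; name one")
      }
      cond <- rel$conditions[1L]
    }
    match(cond, rel$conditions)
  }
  jm <- pick(rel_mutant, mutant_condition, "mutant")
  jw <- pick(rel_wildtype, wildtype_condition, "wildtype")

  det_m <- rel_mutant$detectable[, jm]
  det_w <- rel_wildtype$detectable[, jw]
  n <- length(rel_mutant$genes)
  p <- rep(NA_real_, n)
  both <- det_m & det_w
  if (any(both)) {
    p[both] <- .gamma_contrast_p(
      rel_mutant$shape[both, jm], rel_mutant$rate_denom[both, jm],
      rel_wildtype$shape[both, jw], rel_wildtype$rate_denom[both, jw])
  }
  padj <- rep(NA_real_, n)
  padj[both] <- bh_adjust(p[both])

  mean_m <- rel_mutant$cpm_mean[, jm]
  mean_w <- rel_wildtype$cpm_mean[, jw]
  category <- rep("no_difference", n)
  category[!det_m & !det_w] <- "not_measurable_in_either"
  category[det_m & !det_w] <- "only_in_mutant"
  category[!det_m & det_w] <- "only_in_wildtype"
  sig <- both & !is.na(padj) & padj <= alpha
  category[sig & mean_m > mean_w] <- "higher_in_mutant"
  category[sig & mean_m < mean_w] <- "higher_in_wildtype"
  data.frame(gene_id = rel_mutant$genes,
             category = factor(category, levels = pair_categories()),
             p = p, p_adjusted = padj, stringsAsFactors = FALSE)
}
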