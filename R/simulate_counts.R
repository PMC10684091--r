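#' Configuration for the replicated count-matrix generator
#'
#' Defaults emulate the structure of the developmental RNA-seq series the
#' analysis consumes: eight timepoints (as in a sexual-development
#' timecourse), three biological replicates per timepoint, negative-binomial
#' counts with moderate overdispersion, and a subset of gene x condition
#' blocks fully silenced (all replicates zero), so "not expressed at all"
#' states are realizable.
#'
#' @param n_timepoints number of conditions/timepoints.
#' @param n_replicates replicates per condition (must be >= 2; the assumed
#'   design uses three biological replicates).
#' @param library_size expected total counts per sample.
#' @param dispersion negative-binomial overdispersion (size = 1/dispersion);
#'   must be > 0.
#' @param coordinated_cluster_ids planted-cluster ids (from
#'   [simulate_genome()] truth) whose member genes share one latent
#'   log-profile.
#' @param silent_gene_fraction marginal probability that a gene x condition
#'   block is fully silenced (all replicates zero).  Silencing is
#'   correlated within a gene via a Beta-distributed propensity, so a
#'   subset of genes is silent across all conditions; 1 yields an all-zero
#'   matrix.
#' @param fold_change_range `(min, max)` multiplicative range of the
#'   max/min latent fold change across the timecourse per gene.
#' @param coordination_noise sd of the independent log-scale noise added to
#'   the shared profile of coordinated cluster members.
#' @param seed integer seed.
#' @return list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_timepoints = 8,
                                  n_replicates = 3,
                                  library_size = 5e6,
                                  dispersion = 0.1,
                                  coordinated_cluster_ids = integer(0),
                                  silent_gene_fraction = 0.15,
                                  fold_change_range = c(1, 8),
                                  coordination_noise = 0.1,
                                  seed = 1L) {
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (dispersion <= 0) stop("dispersion must be > 0")
  stopifnot(n_timepoints >= 1, library_size > 0,
            silent_gene_fraction >= 0, silent_gene_fraction <= 1,
            length(fold_change_range) == 2,
            fold_change_range[1] >= 1,
            fold_change_range[2] >= fold_change_range[1],
            coordination_noise >= 0)
  structure(list(
    n_timepoints = as.integer(n_timepoints),
    n_replicates = as.integer(n_replicates),
    library_size = library_size,
    dispersion = dispersion,
    coordinated_cluster_ids = coordinated_cluster_ids,
    silent_gene_fraction = silent_gene_fraction,
    fold_change_range = fold_change_range,
    coordination_noise = coordination_noise,
    seed = as.integer(seed)
  ), class = "expression_sim_config")
}

#' Simulate a replicated count matrix over a gene layout
#'
#' Each gene gets a latent log-profile over timepoints (baseline plus a
#' smooth random walk rescaled so its max/min fold lies in
#' `fold_change_range`).  Genes belonging to a coordinated planted cluster
#' share the cluster's profile plus independent N(0, `coordination_noise`)
#' log-noise.  Gene x condition blocks are silenced (all replicates zero)
#' with probability `silent_gene_fraction`.  Expected counts are normalized
#' per condition so a sample's expected total equals `library_size` times a
#' mild per-sample size factor; counts are negative-binomial.
#'
#' @param layout a [chromosome_layout()], typically from [simulate_genome()]
#'   (its `planted_cluster` column resolves `coordinated_cluster_ids`).
#' @param config an [expression_sim_config()].
#' @return list with `counts` (genes x samples integer matrix), `samples`
#'   (sample sheet: `sample`, `condition`, `replicate`), and `truth`
#'   (list: `log_profile` genes x conditions, `silenced` logical matrix,
#'   `size_factors`).
#' @export
simulate_counts <- function(layout, config) {
  stopifnot(inherits(layout, "chromosome_layout"),
            inherits(config, "expression_sim_config"))
  ids <- config$coordinated_cluster_ids
  if (length(ids)) {
    if (!("planted_cluster" %in% names(layout))) {
      stop("layout carries no planted_cluster column; cannot resolve ",
           "coordinated_cluster_ids")
    }
    missing_ids <- setdiff(ids, unique(layout$planted_cluster))
    if (length(missing_ids)) {
      stop("coordinated_cluster_ids absent from layout: ",
           paste(missing_ids, collapse = ", "))
    }
  }
  set.seed(config$seed)
  n <- nrow(layout)
  k <- config$n_timepoints
  r <- config$n_replicates
  conditions <- sprintf("T%d", seq_len(k))
  samples <- data.frame(
    sample = sprintf("%s_R%d", rep(conditions, each = r),
                     rep(seq_len(r), times = k)),
    condition = rep(conditions, each = r),
    replicate = rep(seq_len(r), times = k),
    stringsAsFactors = FALSE)

  smooth_profile <- function() {
    z <- cumsum(rnorm(k))
    span <- diff(range(z))
    amp <- exp(runif(1, log(config$fold_change_range[1]),
                     log(config$fold_change_range[2])))
    if (span < 1e-12 || k == 1) rep(0, k) else (z - mean(z)) / span * log(amp)
  }

  baseline <- rnorm(n, mean = log(100), sd = 1.2)
  log_profile <- matrix(0, n, k, dimnames = list(layout$gene_id, conditions))
  cluster_profiles <- list()
  member_of <- if ("planted_cluster" %in% names(layout)) {
    layout$planted_cluster
  } else rep(NA_integer_, n)
  for (i in seq_len(n)) {
    cid <- member_of[i]
    if (!is.na(cid) && cid %in% ids) {
      key <- as.character(cid)
      if (is.null(cluster_profiles[[key]])) {
        cluster_profiles[[key]] <- smooth_profile()
      }
      dev <- cluster_profiles[[key]] +
        rnorm(k, sd = config$coordination_noise)
    } else {
      dev <- smooth_profile()
    }
    log_profile[i, ] <- baseline[i] + dev
  }

  # silencing is drawn per gene x condition block but correlated within a
  # gene through a Beta-distributed propensity: the marginal silent-cell
  # fraction equals silent_gene_fraction, while the propensity's
  # overdispersion (nu = 0.5) concentrates silencing in a subset of genes
  # so that fully silent genes ("not expressed at all") actually occur
  f <- config$silent_gene_fraction
  q <- if (f <= 0) rep(0, n) else if (f >= 1) rep(1, n) else
    rbeta(n, f * 0.5, (1 - f) * 0.5)
  silenced <- matrix(runif(n * k) < rep(q, k), n, k,
                     dimnames = list(layout$gene_id, conditions))
  w <- exp(log_profile)
  w[silenced] <- 0

  size_factors <- exp(rnorm(k * r, sd = 0.05))
  names(size_factors) <- samples$sample
  counts <- matrix(0L, n, k * r,
                   dimnames = list(layout$gene_id, samples$sample))
  for (j in seq_len(k * r)) {
    cond <- match(samples$condition[j], conditions)
    tot <- sum(w[, cond])
    mu <- if (tot > 0) config$library_size * size_factors[j] * w[, cond] / tot
          else rep(0, n)
    cnt <- integer(n)
    pos <- mu > 0
    cnt[pos] <- rnbinom(sum(pos), mu = mu[pos], size = 1 / config$dispersion)
    counts[, j] <- cnt
  }

  list(counts = counts, samples = samples,
       truth = list(log_profile = log_profile, silenced = silenced,
                    size_factors = size_factors))
}
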