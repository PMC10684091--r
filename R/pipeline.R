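#' Configure a full synthetic-to-report pipeline run
#'
#' Thresholds default to the canonical parameter set of the analysis:
#' max-gap values 5, 1 and 0; a 5-fold dynamic-expression threshold at
#' alpha 0.05; coordination at r > 0.5; clusters reported below adjusted
#' p < 0.01.
#'
#' @param genome a [genome_sim_config()] (its seed is re-derived from
#'   `seed`).
#' @param expression an [expression_sim_config()] (idem).
#' @param max_gap integer vector of max-gap values to scan.
#' @param report_max_gap the max-gap whose clusters feed profile-free
#'   downstream stages (coordination, BED report).
#' @param criterion information criterion for the clustering profile.
#' @param profile_max_segments segment bound of the DP profile.
#' @param fold,alpha dynamic-expression thresholds.
#' @param cluster_p cluster report threshold on BH-adjusted p-values.
#' @param n_perm permutations per chromosome.
#' @param seed master seed; all stage seeds derive from it.
#' @param outdir output directory.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(genome = genome_sim_config(),
                            expression = expression_sim_config(),
                            max_gap = c(5L, 1L, 0L),
                            report_max_gap = 1L,
                            criterion = "BIC",
                            profile_max_segments = 30L,
                            fold = 5, alpha = 0.05,
                            cluster_p = 0.01,
                            n_perm = 1000L,
                            seed = 42L,
                            outdir = tempfile("lsgclust_run_")) {
  stopifnot(inherits(genome, "genome_sim_config"),
            inherits(expression, "expression_sim_config"),
            report_max_gap %in% max_gap)
  structure(list(genome = genome, expression = expression,
                 max_gap = as.integer(max_gap),
                 report_max_gap = as.integer(report_max_gap),
                 criterion = criterion,
                 profile_max_segments = as.integer(profile_max_segments),
                 fold = fold, alpha = alpha, cluster_p = cluster_p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

#' Load a pipeline configuration from JSON
#'
#' Unknown fields are rejected; nested `genome` and `expression` blocks
#' are handed to their config constructors.
#'
#' @param path JSON file.
#' @param outdir optional override of the configured output directory.
#' @return a `run_config`.
#' @export
read_pipeline_config <- function(path, outdir = NULL) {
  raw <- read_json(path, simplifyVector = TRUE)
  known <- c("genome", "expression", "max_gap", "report_max_gap",
             "criterion", "profile_max_segments", "fold", "alpha",
             "cluster_p", "n_perm", "seed", "outdir")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  args <- raw
  if (!is.null(raw$genome)) {
    g <- raw$genome
    if (!is.null(g$cluster_size_distribution)) {
      g$cluster_size_distribution <- unlist(g$cluster_size_distribution)
    }
    args$genome <- do.call(genome_sim_config, g)
  }
  if (!is.null(raw$expression)) {
    args$expression <- do.call(expression_sim_config, raw$expression)
  }
  if (!is.null(outdir)) args$outdir <- outdir
  do.call(pipeline_config, args)
}

.stage_log <- function(report, stage, t0, ...) {
  dt <- round(as.numeric(Sys.time()) - t0, 2)
  info <- list(...)
  message(sprintf("[%s] done in %ss%s", stage, dt,
                  if (length(info))
                    paste0(" (", paste(names(info), unlist(info), sep = "=",
                                       collapse = ", "), ")")
                  else ""))
  report$log[[stage]] <- c(list(seconds = dt), info)
  report
}

#' Run the full pipeline on synthetic inputs
#'
#' Executes simulate -> classify -> cluster -> profile -> express ->
#' enrich -> coordinate in dependency order, writing every artifact under
#' `config$outdir` and returning (and writing) a report that mirrors the
#' analysis' headline tables: per-size cluster summaries, class-by-state
#' enrichment, six-way pair-category counts, and coordination rankings.
#' A manifest with md5 checksums of every output file makes determinism
#' checkable.
#'
#' @param config a [pipeline_config()] (or path to a JSON config).
#' @return invisibly, the report list (also written to `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  report <- list(seed = config$seed, log = list())

  # stage seeds: fixed offsets from the master seed (kept < 2^31)
  sd <- function(off) (config$seed + off) %% .Machine$integer.max

  t0 <- as.numeric(Sys.time())
  config$genome$seed <- sd(1)
  sim <- simulate_genome(config$genome)
  layout <- sim$layout
  write_genome_gff3(layout, out("genes.gff3"))
  write_label_table(layout, out("labels.tsv"))
  truth <- sim$truth
  report <- .stage_log(report, "simulate_genome", t0,
                       genes = nrow(layout), planted = nrow(truth))

  t0 <- as.numeric(Sys.time())
  hits <- simulate_hits(layout, seed = sd(2))
  write_hit_table(hits, out("hits.tsv"))
  assignments <- classify_lineage(hits)
  fwrite(as.data.table(assignments[, c("gene_id", "stratum", "is_lsg",
                                       "self_only")]),
         out("assignments.tsv"), sep = "\t")
  census <- stratum_census(assignments)
  write_json(setNames(as.list(census$n_genes), census$stratum),
             out("census.json"), auto_unbox = TRUE)
  report$census <- setNames(census$n_genes, census$stratum)
  report <- .stage_log(report, "classify", t0, hits = nrow(hits))

  t0 <- as.numeric(Sys.time())
  class_total <- sum(layout$label)
  cluster_sets <- list()
  for (g in config$max_gap) {
    cl <- find_clusters(layout, g)
    cl <- cluster_pvalues(cl, layout, n_perm = config$n_perm, seed = sd(3))
    cluster_sets[[as.character(g)]] <- cl
    fwrite(as.data.table(summarize_clusters(cl, class_total)),
           out(sprintf("cluster_summary_maxgap%d.tsv", g)), sep = "\t")
  }
  clusters <- cluster_sets[[as.character(config$report_max_gap)]]
  keep <- vapply(clusters, function(x) isTRUE(x$p_adjusted < config$cluster_p),
                 logical(1))
  write_cluster_bed(clusters, out("clusters.bed"))
  write_cluster_bed(clusters[keep], out("clusters_significant.bed"))
  report$cluster_summary <- lapply(cluster_sets, summarize_clusters,
                                   class_total = class_total)
  report <- .stage_log(report, "cluster", t0,
                       clusters = length(clusters),
                       significant = sum(keep))

  t0 <- as.numeric(Sys.time())
  prof <- list()
  for (ch in unique(layout$chrom)) {
    pr <- dp_model_average(label_vector(layout, ch),
                           criterion = config$criterion,
                           max_segments = config$profile_max_segments)
    pr$chrom <- ch
    pr$gene_id <- layout$gene_id[layout$chrom == ch]
    prof[[ch]] <- as.data.frame(pr)
  }
  prof <- do.call(rbind, prof)
  fwrite(as.data.table(prof[, c("chrom", "gene_id", "position", "rate",
                                "lower95", "upper95")]),
         out("profile.tsv"), sep = "\t")
  report <- .stage_log(report, "profile", t0)

  t0 <- as.numeric(Sys.time())
  config$expression$seed <- sd(4)
  if (length(config$expression$coordinated_cluster_ids) == 0 &&
      nrow(truth) > 0) {
    # by default, let a handful of planted clusters be truly coordinated
    set.seed(sd(5))
    config$expression$coordinated_cluster_ids <-
      sort(resample(truth$cluster_id, min(5L, nrow(truth))))
  }
  cnt <- simulate_counts(layout, config$expression)
  write_count_matrix(cnt$counts, cnt$samples, out("counts.tsv"),
                     out("samples.tsv"))
  rel <- relative_expression(cnt$counts, cnt$samples)
  write_relative_expression(rel, out("relative_expression.tsv"))
  dynamic <- call_dynamic(rel, fold = config$fold, alpha = config$alpha)
  status <- status_across_stages(rel)
  fwrite(as.data.table(status), out("status.tsv"), sep = "\t")
  report <- .stage_log(report, "express", t0,
                       dynamic = length(dynamic),
                       expressed = sum(status$expressed_overall))

  # mutant-vs-wildtype pair categories: an independent simulation of the
  # same genome stands in for the mutant strain (different silencing draw)
  t0 <- as.numeric(Sys.time())
  mutant_cfg <- config$expression
  mutant_cfg$seed <- sd(6)
  mutant_cnt <- simulate_counts(layout, mutant_cfg)
  rel_mutant <- relative_expression(mutant_cnt$counts, mutant_cnt$samples)
  first_cond <- rel$conditions[1L]
  pairs <- classify_pair(rel_mutant, rel, alpha = config$alpha,
                         mutant_condition = first_cond,
                         wildtype_condition = first_cond)
  fwrite(as.data.table(pairs), out("pair_categories.tsv"), sep = "\t")
  report$pair_category_counts <- as.list(table(pairs$category))
  report <- .stage_log(report, "pair", t0,
                       categories = length(unique(pairs$category)))

  t0 <- as.numeric(Sys.time())
  labels <- setNames(layout$class, layout$gene_id)
  states <- setNames(ifelse(status$expressed_overall, "expressed",
                            "not_expressed"), status$gene_id)
  if (length(unique(states)) > 1 && any(labels %in% c("LSG", "HET_LSG")) &&
      !all(labels %in% c("LSG", "HET_LSG"))) {
    enr <- class_state_tables(labels, states)
    enr_df <- data.frame(
      state = names(enr),
      chi2 = vapply(enr, `[[`, numeric(1), "chi2"),
      df = vapply(enr, `[[`, numeric(1), "df"),
      p = vapply(enr, `[[`, numeric(1), "p"),
      p_adjusted = vapply(enr, `[[`, numeric(1), "p_adjusted"))
  } else {
    enr_df <- data.frame(state = character(0), chi2 = numeric(0),
                         df = numeric(0), p = numeric(0),
                         p_adjusted = numeric(0))
  }
  fwrite(as.data.table(enr_df), out("enrichment.tsv"), sep = "\t")
  report$enrichment <- enr_df
  report <- .stage_log(report, "enrich", t0)

  t0 <- as.numeric(Sys.time())
  coord <- screen_clusters(clusters, rel)
  coord_df <- data.frame(
    cluster_id = vapply(coord, `[[`, character(1), "cluster_id"),
    n_members = vapply(coord, function(x) length(x$members), integer(1)),
    n_pairs = vapply(coord, `[[`, integer(1), "n_pairs"),
    max_r = vapply(coord, `[[`, numeric(1), "max_offdiag_r"),
    coordinated = vapply(coord, `[[`, logical(1), "coordinated"),
    reason = vapply(coord, `[[`, character(1), "reason"))
  fwrite(as.data.table(coord_df), out("coordination.tsv"), sep = "\t")
  report$coordination <- coord_df
  report <- .stage_log(report, "coordinate", t0,
                       coordinated = sum(coord_df$coordinated))

  files <- sort(list.files(config$outdir, full.names = TRUE))
  files <- files[basename(files) != "report.json"]
  report$manifest <- data.frame(file = basename(files),
                                md5 = unname(md5sum(files)),
                                stringsAsFactors = FALSE)
  write_json(report, out("report.json"), auto_unbox = TRUE, digits = NA,
             force = TRUE, pretty = TRUE)
  invisible(report)
}
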