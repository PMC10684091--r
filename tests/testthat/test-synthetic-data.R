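test_that("simulate_genome honors degenerate and forced configurations", {
  # no LSGs at all
  cfg <- genome_sim_config(n_chromosomes = 2, genes_per_chromosome = 100,
                           lsg_fraction = 0, background_lsg_rate = 0,
                           het_count = 0, seed = 3)
  sim <- simulate_genome(cfg)
  expect_equal(sum(sim$layout$label), 0)
  expect_equal(nrow(sim$truth), 0)

  # exactly one planted size-5 cluster, no background
  cfg <- genome_sim_config(n_chromosomes = 1, genes_per_chromosome = 200,
                           lsg_fraction = 5 / 200, background_lsg_rate = 0,
                           het_count = 0,
                           cluster_size_distribution = c(`5` = 1), seed = 9)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$truth), 1)
  expect_equal(sim$truth$size, 5)
  idx <- which(sim$layout$class == "LSG")
  expect_length(idx, 5)
  expect_equal(diff(idx), rep(1L, 4))   # contiguous

  # sizing error when a cluster cannot fit
  cfg <- genome_sim_config(n_chromosomes = 1, genes_per_chromosome = 10,
                           lsg_fraction = 0.9, background_lsg_rate = 0,
                           cluster_size_distribution = c(`23` = 1), seed = 1)
  expect_error(simulate_genome(cfg), "capacity")
})

test_that("genome layouts are ordered, non-overlapping, deterministic", {
  cfg <- genome_sim_config(n_chromosomes = 3, genes_per_chromosome = 150,
                           seed = 11)
  sim1 <- simulate_genome(cfg)
  sim2 <- simulate_genome(cfg)
  expect_identical(sim1, sim2)
  for (ch in unique(sim1$layout$chrom)) {
    g <- sim1$layout[sim1$layout$chrom == ch, ]
    expect_true(all(diff(g$start) > 0))
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
})

test_that("telomere bias places LSGs closer to chromosome ends", {
  cfg <- genome_sim_config(n_chromosomes = 1, genes_per_chromosome = 500,
                           telomere_bias = 0.9, seed = 1)
  sim <- simulate_genome(cfg)
  n <- nrow(sim$layout)
  ord <- seq_len(n)
  # normalized distance to the nearest chromosome end in gene-ordinal space
  dist_end <- pmin(ord - 1, n - ord) / n
  lsg <- sim$layout$label == 1
  wt <- suppressWarnings(
    stats::wilcox.test(dist_end[lsg], dist_end[!lsg], alternative = "less"))
  expect_lt(wt$p.value, 0.05)
  expect_lt(mean(dist_end[lsg]), mean(dist_end[!lsg]))
})

test_that("marginal LSG fraction converges to lsg_fraction", {
  f <- 670 / 10592
  cfg <- genome_sim_config(n_chromosomes = 1, genes_per_chromosome = 2000,
                           lsg_fraction = f, seed = 21)
  sim <- simulate_genome(cfg)
  tol <- 3 * sqrt(f * (1 - f) / 2000)
  expect_lt(abs(mean(sim$layout$label) - f), tol)
})

test_that("planted clusters are exactly recoverable at max_gap 0", {
  cfg <- genome_sim_config(n_chromosomes = 2, genes_per_chromosome = 400,
                           background_lsg_rate = 0, seed = 5)
  sim <- simulate_genome(cfg)
  found <- find_clusters(sim$layout, 0)
  fm <- sort(vapply(found, function(x) paste(sort(x$members), collapse = ","),
                    character(1)))
  tm <- sort(vapply(sim$truth$members,
                    function(m) paste(sort(m), collapse = ","), character(1)))
  expect_identical(fm, tm)
})

test_that("simulate_hits structure matches class labels", {
  lay <- make_layout(c(1, 0))
  hits <- simulate_hits(lay, seed = 4)
  lsg_hits <- hits[hits$query_gene == lay$gene_id[1], ]
  other_hits <- hits[hits$query_gene == lay$gene_id[2], ]
  expect_true(all(lsg_hits$mrca_rank == "Neurospora"))
  expect_true(any(other_hits$mrca_rank != "Neurospora" &
                    other_hits$e_value <= 0.05))
  expect_true(all(hits$e_value <= 0.05))
  expect_error(simulate_hits(lay, outgroup_taxa = character(0)),
               "nonempty")
  # determinism
  expect_identical(simulate_hits(lay, seed = 4), hits)
})

test_that("simulate_counts respects silencing, coordination and scale", {
  cfg0 <- genome_sim_config(n_chromosomes = 1, genes_per_chromosome = 120,
                            background_lsg_rate = 0, seed = 2)
  sim <- simulate_genome(cfg0)
  cid <- sim$truth$cluster_id[which.max(sim$truth$size)]

  # all silent -> all-zero matrix
  ecfg <- expression_sim_config(silent_gene_fraction = 1, seed = 3)
  cnt <- simulate_counts(sim$layout, ecfg)
  expect_true(all(cnt$counts == 0))

  # shared latent profile: noise -> 0 gives pairwise r = 1
  ecfg <- expression_sim_config(coordinated_cluster_ids = cid,
                                coordination_noise = 0,
                                silent_gene_fraction = 0, seed = 3)
  cnt <- simulate_counts(sim$layout, ecfg)
  members <- sim$truth$members[[match(cid, sim$truth$cluster_id)]]
  prof <- cnt$truth$log_profile[members, ]
  cc <- cor(t(prof))
  expect_true(all(abs(cc[upper.tri(cc)] - 1) < 1e-9))

  # mean sample count tracks library_size / n_genes
  ecfg <- expression_sim_config(seed = 7)
  cnt <- simulate_counts(sim$layout, ecfg)
  expect_lt(abs(mean(colSums(cnt$counts)) / ecfg$library_size - 1), 0.05)
  expect_true(all(cnt$counts >= 0))
  expect_true(all(cnt$counts == floor(cnt$counts)))

  # config validation
  expect_error(expression_sim_config(dispersion = 0), "dispersion")
  expect_error(expression_sim_config(n_replicates = 1), "replicates")
  expect_error(
    simulate_counts(sim$layout,
                    expression_sim_config(coordinated_cluster_ids = 999L)),
    "absent")
})
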