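hit_row <- function(gene, taxon, rank, e, rb = FALSE) {
  data.frame(query_gene = gene, subject_taxon = taxon, mrca_rank = rank,
             e_value = e, reciprocal_best = rb, stringsAsFactors = FALSE)
}

test_that("filter_hits applies the cutoff with stable order", {
  empty <- data.frame(query_gene = character(0), subject_taxon = character(0),
                      mrca_rank = character(0), e_value = numeric(0),
                      reciprocal_best = logical(0))
  expect_equal(nrow(filter_hits(empty, 0.05)), 0)
  one <- hit_row("g1", "tax", "Neurospora", 0.06)
  expect_equal(nrow(filter_hits(one, 0.05)), 0)      # boundary exclusion
  expect_equal(nrow(filter_hits(one, 0.06)), 1)      # boundary inclusion
  mixed <- rbind(hit_row("g1", "a", "Neurospora", 1e-12),
                 hit_row("g1", "b", "Eukaryota", 1e-5),
                 hit_row("g2", "c", "Dikarya", 1e-30),
                 hit_row("g2", "d", "Ascomycota", 0.04))
  strict <- filter_hits(mixed, 1e-10)
  expect_equal(strict$subject_taxon, c("a", "c"))
  expect_error(filter_hits(mixed, 0), "e_cutoff")
})

test_that("classify_lineage applies the deepest-retained-rank rule", {
  tab <- rbind(
    hit_row("lsg1", "Neurospora_discreta", "Neurospora", 1e-20, TRUE),
    hit_row("lsg1", "Neurospora_tetrasperma", "Neurospora", 0.04, FALSE),
    hit_row("deep1", "Neurospora_discreta", "Neurospora", 1e-40, TRUE),
    hit_row("deep1", "Arabidopsis_thaliana", "Eukaryota", 1e-30, FALSE))
  asg <- classify_lineage(tab)
  a <- asg[match(c("lsg1", "deep1"), asg$gene_id), ]
  expect_equal(a$is_lsg, c(TRUE, FALSE))
  expect_equal(a$stratum, c("Neurospora", "Eukaryota"))
  # orthologs only at the strict cutoff with the reciprocal flag
  expect_equal(asg$in_genus_orthologs[[match("lsg1", asg$gene_id)]],
               "Neurospora_discreta")

  # a gene with no hit at all is flagged self-only and counted as LSG
  asg2 <- classify_lineage(tab, genes = c("lonely", "lsg1", "deep1"))
  lone <- asg2[asg2$gene_id == "lonely", ]
  expect_true(lone$is_lsg)
  expect_true(lone$self_only)
  expect_equal(lone$stratum, "unclassified-self-only")

  # a marginal deep hit beyond the cutoff does not remove LSG status
  tab3 <- rbind(hit_row("g", "Neurospora_discreta", "Neurospora", 1e-20, TRUE),
                hit_row("g", "Ustilago_maydis", "Dikarya", 0.2))
  expect_true(classify_lineage(tab3)$is_lsg)
  expect_false(classify_lineage(tab3, broad_cutoff = 0.5)$is_lsg)
})

test_that("lowering the cutoff only moves genes toward exclusive strata", {
  ladder <- default_rank_ladder()
  set.seed(8)
  for (rep in 1:20) {
    n_hits <- sample(1:6, 1)
    tab <- hit_row(rep("g", n_hits),
                   sprintf("t%d", seq_len(n_hits)),
                   sample(ladder, n_hits, replace = TRUE),
                   10^runif(n_hits, -30, 0))
    cutoffs <- sort(10^runif(4, -20, -1), decreasing = TRUE)
    depths <- vapply(cutoffs, function(ct) {
      a <- classify_lineage(tab, broad_cutoff = ct, genes = "g")
      match(a$stratum, c(ladder, "unclassified-self-only"))
    }, numeric(1))
    # decreasing cutoff => stratum index never moves toward inclusivity,
    # treating self-only (index 7) as more exclusive than any rank
    d <- ifelse(depths == 7, 0, depths)
    expect_true(all(diff(d) <= 0))
  }
})

test_that("stratum_census conserves genes and splits by stratum", {
  tab <- do.call(rbind, lapply(seq_along(default_rank_ladder()), function(i) {
    hit_row(sprintf("g%d", i), sprintf("t%d", i), default_rank_ladder()[i],
            1e-20)
  }))
  asg <- classify_lineage(tab)
  census <- stratum_census(asg)
  expect_equal(sum(census$n_genes), nrow(asg))
  got <- census$n_genes[match(default_rank_ladder(), census$stratum)]
  expect_equal(got, rep(1L, 6))

  # all-LSG census
  tab2 <- hit_row(paste0("g", 1:3), "Neurospora_discreta", "Neurospora", 1e-9)
  census2 <- stratum_census(classify_lineage(tab2))
  expect_equal(census2$n_genes[census2$stratum == "Neurospora"], 3L)
  expect_equal(sum(census2$n_genes), 3L)
})

test_that("classification round-trips simulated hit tables exactly", {
  cfg <- genome_sim_config(n_chromosomes = 2, genes_per_chromosome = 150,
                           seed = 13)
  sim <- simulate_genome(cfg)
  hits <- simulate_hits(sim$layout, seed = 14)
  truth <- attr(hits, "truth")
  asg <- classify_lineage(hits)
  m <- match(truth$gene_id, asg$gene_id)
  expect_false(anyNA(m))
  expect_equal(asg$is_lsg[m], truth$is_lsg)
  expect_equal(asg$stratum[m], truth$stratum)
})
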