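test_that("relative levels rescale to the lowest measurable condition", {
  cm <- make_counts(rbind(g1 = c(5, 10, 50)), c("A", "B", "C"))
  rel <- relative_expression(cm$counts, cm$samples)
  expect_equal(unname(rel$level["g1", ]), c(1, 2, 10))
  expect_true(all(rel$detectable["g1", ]))
  expect_equal(unname(rel$reference[1]), 1L)
  # envelope brackets the point estimate
  expect_true(all(rel$lower95["g1", ] <= rel$level["g1", ] &
                    rel$level["g1", ] <= rel$upper95["g1", ]))

  # all-zero gene: every condition unmeasurable, level 0, interval [0, 0]
  cm0 <- make_counts(rbind(g1 = c(5, 10, 50), dead = c(0, 0, 0)),
                     c("A", "B", "C"))
  rel0 <- relative_expression(cm0$counts, cm0$samples)
  expect_equal(unname(rel0$level["dead", ]), c(0, 0, 0))
  expect_equal(unname(rel0$lower95["dead", ]), c(0, 0, 0))
  expect_equal(unname(rel0$upper95["dead", ]), c(0, 0, 0))
  expect_true(is.na(rel0$reference[2]))

  # a condition below the detection threshold reports 0, not a tiny level
  cmt <- make_counts(rbind(g1 = c(0, 10, 50)), c("A", "B", "C"))
  relt <- relative_expression(cmt$counts, cmt$samples)
  expect_equal(unname(relt$level["g1", ]), c(0, 1, 5))
})

test_that("relative levels are invariant to rescaling a gene's counts", {
  cm <- make_counts(rbind(g1 = c(7, 21, 70), g2 = c(40, 20, 10)),
                    c("A", "B", "C"))
  libs <- setNames(colSums(cm$counts), colnames(cm$counts))
  rel1 <- relative_expression(cm$counts, cm$samples, lib_sizes = libs)
  scaled <- cm$counts
  scaled["g1", ] <- scaled["g1", ] * 3L
  rel2 <- relative_expression(scaled, cm$samples, lib_sizes = libs)
  expect_equal(rel2$level["g1", ], rel1$level["g1", ])
  expect_equal(rel2$level["g2", ], rel1$level["g2", ])
})

test_that("credible intervals cover a true 8-fold change", {
  set.seed(18)
  n_sim <- 200
  covered <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    low <- rpois(3, 40)
    high <- rpois(3, 320)
    counts <- matrix(c(low, high), nrow = 1,
                     dimnames = list("g", sprintf("S%d", 1:6)))
    counts <- rbind(counts, filler = 1e6 - colSums(counts))
    samples <- data.frame(sample = sprintf("S%d", 1:6),
                          condition = rep(c("lo", "hi"), each = 3),
                          replicate = rep(1:3, 2))
    rel <- relative_expression(counts, samples,
                               lib_sizes = setNames(rep(1e6, 6),
                                                    sprintf("S%d", 1:6)))
    covered[s] <- rel$lower95["g", "hi"] <= 8 && 8 <= rel$upper95["g", "hi"]
  }
  expect_gte(mean(covered), 0.9)
})

test_that("call_dynamic combines the fold rule with adjusted significance", {
  cm <- make_counts(rbind(flat = c(100, 200, 300),
                          jump = c(100, 100, 600),
                          dead = c(0, 0, 0)),
                    c("A", "B", "C"), reps = 3)
  rel <- relative_expression(cm$counts, cm$samples)
  dyn <- call_dynamic(rel, fold = 5, alpha = 0.05)
  expect_false("flat" %in% dyn)     # 3-fold < 5
  expect_true("jump" %in% dyn)      # 6-fold, disjoint intervals
  detail <- attr(dyn, "detail")
  expect_true(detail$excluded[detail$gene_id == "dead"])
  expect_error(call_dynamic(
    relative_expression(make_counts(rbind(g = 5), "A", reps = 3)$counts,
                        make_counts(rbind(g = 5), "A", reps = 3)$samples)),
    "conditions")
})

test_that("null simulation keeps the dynamic-call rate below alpha", {
  set.seed(23)
  n <- 1000
  counts <- matrix(rpois(n * 12, 50), n, 12,
                   dimnames = list(sprintf("g%d", 1:n), sprintf("S%d", 1:12)))
  samples <- data.frame(sample = sprintf("S%d", 1:12),
                        condition = rep(sprintf("T%d", 1:4), each = 3),
                        replicate = rep(1:3, 4))
  rel <- relative_expression(counts, samples)
  dyn <- call_dynamic(rel, fold = 5, alpha = 0.05)
  expect_lte(length(dyn) / n, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("status_across_stages applies the two-point rule", {
  cm <- make_counts(rbind(never = c(0, 0, 0, 0),
                          once = c(0, 0, 80, 0),
                          twice = c(50, 0, 80, 0),
                          always = c(10, 20, 30, 40)),
                    sprintf("T%d", 1:4))
  rel <- relative_expression(cm$counts, cm$samples)
  st <- status_across_stages(rel)
  rownames(st) <- st$gene_id
  expect_equal(st[c("never", "once", "twice", "always"), "expressed_overall"],
               c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(st[c("never", "once", "twice", "always"), "single_point_only"],
               c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(st["always", "n_points_detected"], 4L)
})

test_that("classify_pair partitions the universe into six categories", {
  mk <- function(x) {
    cm <- make_counts(x, "C", reps = 3)
    relative_expression(cm$counts, cm$samples)
  }
  genes <- rbind(m_only = 200, both_hi_m = 900, same = 100,
                 neither = 0, both_hi_w = 100, w_only = 0, filler2 = 17)
  mut <- mk(genes)
  wt <- mk(rbind(m_only = 0, both_hi_m = 100, same = 100,
                 neither = 0, both_hi_w = 900, w_only = 200, filler2 = 17))
  pc <- classify_pair(mut, wt, alpha = 0.05)
  got <- setNames(as.character(pc$category), pc$gene_id)
  expect_equal(unname(got["m_only"]), "only_in_mutant")
  expect_equal(unname(got["w_only"]), "only_in_wildtype")
  expect_equal(unname(got["neither"]), "not_measurable_in_either")
  expect_equal(unname(got["both_hi_m"]), "higher_in_mutant")
  expect_equal(unname(got["both_hi_w"]), "higher_in_wildtype")
  expect_equal(unname(got["same"]), "no_difference")
  # exhaustive partition
  expect_equal(sum(table(pc$category)), length(mut$genes))
})

test_that("classify_pair is calibrated under the null", {
  set.seed(29)
  n <- 400
  mk <- function() {
    counts <- matrix(rpois(n * 3, 80), n, 3,
                     dimnames = list(sprintf("g%d", 1:n), sprintf("S%d", 1:3)))
    samples <- data.frame(sample = sprintf("S%d", 1:3), condition = "C",
                          replicate = 1:3)
    relative_expression(counts, samples)
  }
  pc <- classify_pair(mk(), mk(), alpha = 0.05)
  expect_gte(mean(pc$category == "no_difference"), 0.95)
})
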