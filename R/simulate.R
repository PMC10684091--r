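#' Configuration for the synthetic genome generator
#'
#' Defaults emulate the *N. crassa* setting the analysis was designed around:
#' seven chromosomes, roughly 10,500 protein-coding genes, an LSG fraction of
#' 670/10592, 68 HET-domain genes, and a planted-cluster size distribution
#' taken from the observed tally of LSG cluster sizes (57 clusters of 2, 28
#' of 3, 8 of 4, 14 of 5, 5 of 6, 3 of 7, 2 of 8, 3 of 9, and one each of
#' 11, 16 and 23 genes).
#'
#' @param n_chromosomes number of chromosomes.
#' @param genes_per_chromosome genes per chromosome.
#' @param lsg_fraction target marginal fraction of LSG-labeled genes.
#' @param het_count number of HET-domain genes to place.
#' @param cluster_size_distribution named numeric vector mapping cluster size
#'   (>= 2) to probability; must sum to 1.
#' @param telomere_bias fraction of planted clusters anchored in the outer
#'   10% of the gene order of a chromosome (mirrored at both ends); the
#'   remainder are placed uniformly over the middle 80%.
#' @param background_lsg_rate per-gene rate of unplanted (singleton) LSGs.
#' @param seed integer seed.
#' @return a list of class `genome_sim_config`.
#' @export
genome_sim_config <- function(n_chromosomes = 7,
                              genes_per_chromosome = 1500,
                              lsg_fraction = 670 / 10592,
                              het_count = 68,
                              cluster_size_distribution = default_cluster_sizes(),
                              telomere_bias = 0.9,
                              background_lsg_rate = 0.02,
                              seed = 1L) {
  stopifnot(n_chromosomes >= 1, genes_per_chromosome >= 1,
            lsg_fraction >= 0, lsg_fraction <= 1,
            het_count >= 0, telomere_bias >= 0, telomere_bias <= 1,
            background_lsg_rate >= 0, background_lsg_rate <= 1)
  sizes <- as.integer(names(cluster_size_distribution))
  if (any(is.na(sizes)) || any(sizes < 2)) {
    stop("cluster_size_distribution must be named by integer sizes >= 2")
  }
  if (abs(sum(cluster_size_distribution) - 1) > 1e-9) {
    stop("cluster_size_distribution probabilities must sum to 1")
  }
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    lsg_fraction = lsg_fraction,
    het_count = as.integer(het_count),
    cluster_size_distribution = cluster_size_distribution,
    telomere_bias = telomere_bias,
    background_lsg_rate = background_lsg_rate,
    seed = as.integer(seed)
  ), class = "genome_sim_config")
}

#' @rdname genome_sim_config
#' @export
default_cluster_sizes <- function() {
  counts <- c(`2` = 57, `3` = 28, `4` = 8, `5` = 14, `6` = 5, `7` = 3,
              `8` = 2, `9` = 3, `11` = 1, `16` = 1, `23` = 1)
  counts / sum(counts)
}

#' Simulate a genome layout with planted LSG clusters
#'
#' Generates an ordered, non-overlapping gene layout per chromosome.  LSGs
#' arise two ways: *planted* clusters (contiguous runs of LSGs whose sizes
#' are drawn from `cluster_size_distribution`, anchored telomerically with
#' probability `telomere_bias`) and *background* singleton LSGs drawn
#' per-gene at `background_lsg_rate`.  The number of planted LSGs is chosen
#' so that planted + expected background approximates
#' `lsg_fraction * total genes`.  HET-domain genes are placed preferentially
#' adjacent to planted clusters (emulating LSG/HET co-clustering); a small
#' number land on LSGs themselves and become class `"HET_LSG"`.
#'
#' Planted clusters are separated by at least 3 non-LSG genes, so with
#' `background_lsg_rate = 0` they are exactly recoverable by
#' [find_clusters()] at `max_gap = 0`.
#'
#' @param config a [genome_sim_config()].
#' @return list with elements `layout` (a [chromosome_layout()] carrying a
#'   `planted_cluster` column) and `truth` (data.frame of planted clusters:
#'   `cluster_id`, `chrom`, `first_index`, `size`, `members`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "genome_sim_config"))
  set.seed(config$seed)
  n_chr <- config$n_chromosomes
  gpc <- config$genes_per_chromosome
  total <- n_chr * gpc
  chroms <- sprintf("chr%s", as.roman(seq_len(n_chr)))

  # planted gene budget
  target_lsg <- round(config$lsg_fraction * total)
  planted_target <- max(0L, target_lsg - round(config$background_lsg_rate * total))
  sizes <- integer(0)
  size_support <- as.integer(names(config$cluster_size_distribution))
  while (sum(sizes) < planted_target) {
    s <- resample(size_support, 1L, prob = config$cluster_size_distribution)
    if (sum(sizes) + s > planted_target + max(size_support)) break
    sizes <- c(sizes, s)
  }
  if (length(sizes) && max(sizes) + 6L > gpc) {
    stop("cluster demand exceeds chromosome capacity: largest planted cluster ",
         "of ", max(sizes), " genes does not fit in ", gpc, " genes")
  }

  classes <- rep("other", total)
  planted_id <- rep(NA_integer_, total)
  # per-chromosome occupancy (planted cluster genes plus a 3-gene buffer)
  occupied <- matrix(FALSE, nrow = n_chr, ncol = gpc)
  truth <- vector("list", length(sizes))
  if (length(sizes)) {
    # place large clusters first so they still fit late in the process
    sizes <- sort(sizes, decreasing = TRUE)
    for (i in seq_along(sizes)) {
      s <- sizes[i]
      placed <- FALSE
      for (attempt in seq_len(200L)) {
        ch <- sample.int(n_chr, 1L)
        if (runif(1) < config$telomere_bias) {
          u <- 0.1 * rbeta(1L, 0.5, 3)          # dense near the very end
          frac <- if (runif(1) < 0.5) u else 1 - u
        } else {
          frac <- runif(1L, 0.1, 0.9)
        }
        first <- 1L + as.integer(round(frac * (gpc - s)))
        idx <- first:(first + s - 1L)
        buf <- max(1L, first - 3L):min(gpc, first + s + 2L)
        if (!any(occupied[ch, buf])) {
          occupied[ch, buf] <- TRUE
          gidx <- (ch - 1L) * gpc + idx
          classes[gidx] <- "LSG"
          planted_id[gidx] <- i
          truth[[i]] <- data.frame(cluster_id = i, chrom = chroms[ch],
                                   first_index = first, size = s)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("cluster demand exceeds chromosome capacity: could not place a ",
             s, "-gene cluster after 200 attempts")
      }
    }
  }

  # background singleton LSGs on unplanted genes
  if (config$background_lsg_rate > 0) {
    free <- which(classes == "other")
    hit <- free[runif(length(free)) < config$background_lsg_rate]
    classes[hit] <- "LSG"
  }

  # HET genes: most adjacent to planted clusters, a few on LSGs (HET_LSG)
  if (config$het_count > 0) {
    n_on_lsg <- min(3L, config$het_count, sum(classes == "LSG"))
    lsg_idx <- which(classes == "LSG")
    if (n_on_lsg > 0) {
      onto <- resample(lsg_idx, n_on_lsg)
      classes[onto] <- "HET_LSG"
    }
    n_rest <- config$het_count - n_on_lsg
    if (n_rest > 0) {
      # candidate positions flanking planted clusters (within 2 genes)
      flank <- integer(0)
      for (tr in truth) {
        if (is.null(tr)) next
        ch <- match(tr$chrom, chroms)
        lo <- tr$first_index - 2L
        hi <- tr$first_index + tr$size + 1L
        cand <- c(lo:(tr$first_index - 1L), (tr$first_index + tr$size):hi)
        cand <- cand[cand >= 1L & cand <= gpc]
        flank <- c(flank, (ch - 1L) * gpc + cand)
      }
      flank <- unique(flank[classes[flank] == "other"])
      n_flank <- min(length(flank), round(0.6 * n_rest))
      het_idx <- if (n_flank > 0) resample(flank, n_flank) else integer(0)
      free <- setdiff(which(classes == "other"), het_idx)
      extra <- n_rest - n_flank
      if (extra > 0) het_idx <- c(het_idx, resample(free, extra))
      classes[het_idx] <- "HET"
    }
  }

  # physical coordinates: gene lengths ~ Gamma, intergenic gaps ~ Exp,
  # mimicking compact fungal gene density (~1 gene / 2.5 kb)
  layout <- vector("list", n_chr)
  for (ch in seq_len(n_chr)) {
    len <- 200L + as.integer(round(rgamma(gpc, shape = 3, scale = 500)))
    gap <- 50L + as.integer(round(rexp(gpc, rate = 1 / 600)))
    start <- cumsum(as.numeric(gap)) + c(0, cumsum(as.numeric(len)))[seq_len(gpc)]
    gidx <- (ch - 1L) * gpc + seq_len(gpc)
    layout[[ch]] <- data.frame(
      gene_id = sprintf("NCS%05d", gidx),
      chrom = chroms[ch],
      start = start,
      end = start + len,
      strand = sample(c("+", "-"), gpc, replace = TRUE),
      class = classes[gidx],
      planted_cluster = planted_id[gidx],
      stringsAsFactors = FALSE
    )
  }
  layout <- do.call(rbind, layout)
  layout <- chromosome_layout(layout)

  truth <- truth[!vapply(truth, is.null, logical(1))]
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(cluster_id = integer(0), chrom = character(0),
               first_index = integer(0), size = integer(0))
  if (nrow(truth)) {
    truth$members <- lapply(seq_len(nrow(truth)), function(i) {
      layout$gene_id[layout$chrom == truth$chrom[i]][
        truth$first_index[i]:(truth$first_index[i] + truth$size[i] - 1L)]
    })
    truth <- truth[order(truth$cluster_id), ]
    rownames(truth) <- NULL
  }
  list(layout = layout, truth = truth)
}

#' Default outgroup taxa for hit simulation
#'
#' A named vector mapping subject taxa to the taxonomic rank of their most
#' recent common ancestor with the focal species, mirroring the rank ladder
#' of [default_rank_ladder()].
#' @export
default_outgroup_taxa <- function() {
  c(Sordaria_macrospora = "Sordariomycetes",
    Podospora_anserina = "Sordariomycetes",
    Aspergillus_nidulans = "Pezizomycotina",
    Saccharomyces_cerevisiae = "Ascomycota",
    Ustilago_maydis = "Dikarya",
    Arabidopsis_thaliana = "Eukaryota",
    Drosophila_melanogaster = "Eukaryota")
}

#' Simulate a homology hit table from a labeled layout
#'
#' LSG-class genes (including `HET_LSG`) receive hits only from in-genus
#' taxa at E <= 0.05, with at least one reciprocal-best in-genus ortholog at
#' E <= 1e-10.  Every non-LSG gene receives at least one out-of-genus hit at
#' E <= 0.05 whose rank is the gene's (simulated) true phylostratum, plus
#' optional shallower hits; the drawn strata are returned as ground truth.
#'
#' @param layout a [chromosome_layout()].
#' @param outgroup_taxa named character vector, taxon -> rank of the MRCA
#'   with the focal species; ranks must come from `rank_ladder` (minus the
#'   genus rank).
#' @param seed integer seed.
#' @param genus_taxa in-genus subject taxa.
#' @param rank_ladder rank ladder, most exclusive first.
#' @return data.frame of class `hit_table` with columns `query_gene`,
#'   `subject_taxon`, `mrca_rank`, `e_value`, `reciprocal_best`, and an
#'   attribute `truth` (data.frame gene_id, stratum, is_lsg).
#' @export
simulate_hits <- function(layout, outgroup_taxa = default_outgroup_taxa(),
                          seed = 1L,
                          genus_taxa = c("Neurospora_tetrasperma",
                                         "Neurospora_discreta"),
                          rank_ladder = default_rank_ladder()) {
  stopifnot(inherits(layout, "chromosome_layout"))
  if (length(outgroup_taxa) == 0) stop("outgroup_taxa must be nonempty")
  bad <- setdiff(unname(outgroup_taxa), rank_ladder[-1])
  if (length(bad)) stop("outgroup ranks not on the ladder: ",
                        paste(bad, collapse = ", "))
  set.seed(seed)
  genus_rank <- rank_ladder[1]
  is_lsg <- layout$class %in% c("LSG", "HET_LSG")
  n <- nrow(layout)

  rows <- vector("list", n)
  strata <- character(n)
  rank_of_taxon <- outgroup_taxa
  for (i in seq_len(n)) {
    gene <- layout$gene_id[i]
    # in-genus hits for everyone (orthologs within the genus)
    n_in <- sample(1:2, 1L)
    in_taxa <- resample(genus_taxa, n_in)
    in_e <- 10^runif(n_in, -50, -11)            # strong in-genus orthology
    in_rb <- rep(TRUE, n_in)
    if (is_lsg[i]) {
      strata[i] <- genus_rank
      rows[[i]] <- data.frame(query_gene = gene, subject_taxon = in_taxa,
                              mrca_rank = genus_rank, e_value = in_e,
                              reciprocal_best = in_rb,
                              stringsAsFactors = FALSE)
    } else {
      # true phylostratum: any non-genus rank present among the outgroups
      avail <- unique(unname(rank_of_taxon))
      stratum <- resample(avail, 1L)
      strata[i] <- stratum
      # one defining hit at the stratum rank ...
      deep_taxa <- names(rank_of_taxon)[rank_of_taxon == stratum]
      t0 <- resample(deep_taxa, 1L)
      # ... plus hits at strictly shallower (more exclusive) outgroup ranks
      depth <- match(stratum, rank_ladder)
      shallow <- names(rank_of_taxon)[
        match(rank_of_taxon, rank_ladder) < depth]
      n_sh <- if (length(shallow)) sample(0:min(2L, length(shallow)), 1L) else 0L
      sh_taxa <- if (n_sh > 0) resample(shallow, n_sh) else character(0)
      out_taxa <- c(t0, sh_taxa)
      out_e <- 10^runif(length(out_taxa), -30, log10(0.05))
      rows[[i]] <- data.frame(
        query_gene = gene,
        subject_taxon = c(in_taxa, out_taxa),
        mrca_rank = c(rep(genus_rank, n_in),
                      unname(rank_of_taxon[out_taxa])),
        e_value = c(in_e, out_e),
        reciprocal_best = c(in_rb, rep(FALSE, length(out_taxa))),
        stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, rows)
  rownames(hits) <- NULL
  attr(hits, "truth") <- data.frame(gene_id = layout$gene_id,
                                    stratum = strata, is_lsg = is_lsg,
                                    stringsAsFactors = FALSE)
  class(hits) <- c("hit_table", "data.frame")
  hits
}
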