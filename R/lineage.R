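#' Default taxonomic rank ladder
#'
#' Most exclusive (the focal genus) first.  The default mirrors the strata
#' customarily used for Sordariomycete phylostratigraphy: genus, class,
#' subphylum, phylum, subkingdom, domain.
#' @export
default_rank_ladder <- function() {
  c("Neurospora", "Sordariomycetes", "Pezizomycotina", "Ascomycota",
    "Dikarya", "Eukaryota")
}

#' Filter a hit table by E-value
#'
#' Retains rows with `e_value <= e_cutoff`, preserving row order.  The
#' conventional broad cutoff for homology detection is 0.05; a strict
#' cutoff of 1e-10 is used for within-genus ortholog confirmation.
#'
#' @param table a hit table (data.frame with columns `query_gene`,
#'   `subject_taxon`, `mrca_rank`, `e_value`, `reciprocal_best`).
#' @param e_cutoff positive E-value cutoff.
#' @return the filtered hit table.
#' @export
filter_hits <- function(table, e_cutoff) {
  stopifnot(is.data.frame(table), e_cutoff > 0)
  if (nrow(table) == 0) return(table)
  if (any(table$e_value < 0)) stop("negative e_value in hit table")
  out <- table[table$e_value <= e_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign phylostrata and lineage-specificity from homology hits
#'
#' A gene's phylostratum is the most inclusive (deepest, i.e. most
#' ancestral) MRCA rank among its hits retained at `broad_cutoff`: a single
#' retained out-of-genus hit is enough to remove lineage-specific status.
#' A gene is an LSG iff every retained hit is in-genus.  Genes with no
#' retained hit (or absent from the table but listed in `genes`) are
#' assigned the stratum `"unclassified-self-only"` and flagged
#' (`self_only = TRUE`); they count as LSGs because no external homology
#' contradicts lineage specificity.
#'
#' In-genus orthologs are the reciprocal-best in-genus subjects retained at
#' the stricter `ortholog_cutoff`.
#'
#' @param table hit table (see [filter_hits()]).
#' @param broad_cutoff E-value cutoff for homology detection.
#' @param ortholog_cutoff E-value cutoff for in-genus ortholog confirmation.
#' @param rank_ladder rank ladder, most exclusive first; the first entry is
#'   the in-genus rank.
#' @param genes optional gene universe; genes without hits are classified
#'   as self-only.
#' @return data.frame of class `phylostratum_assignment`: `gene_id`,
#'   `stratum`, `is_lsg`, `self_only`, `in_genus_orthologs` (list column).
#' @export
classify_lineage <- function(table, broad_cutoff = 0.05,
                             ortholog_cutoff = 1e-10,
                             rank_ladder = default_rank_ladder(),
                             genes = NULL) {
  stopifnot(is.data.frame(table))
  genus_rank <- rank_ladder[1]
  if (nrow(table)) {
    bad <- setdiff(unique(table$mrca_rank), rank_ladder)
    if (length(bad)) stop("hit ranks not on the ladder: ",
                          paste(bad, collapse = ", "))
  }
  retained <- filter_hits(table, broad_cutoff)
  ortho <- filter_hits(table, ortholog_cutoff)
  ortho <- ortho[ortho$mrca_rank == genus_rank & ortho$reciprocal_best, ,
                 drop = FALSE]

  universe <- unique(c(table$query_gene, genes))
  depth <- match(retained$mrca_rank, rank_ladder)
  max_depth <- tapply(depth, retained$query_gene, max)
  ortho_by_gene <- split(ortho$subject_taxon, ortho$query_gene)

  d <- max_depth[universe]
  stratum <- ifelse(is.na(d), "unclassified-self-only", rank_ladder[d])
  out <- data.frame(
    gene_id = universe,
    stratum = unname(stratum),
    is_lsg = unname(is.na(d) | d == 1L),
    self_only = unname(is.na(d)),
    stringsAsFactors = FALSE)
  out$in_genus_orthologs <- lapply(universe, function(g) {
    unique(ortho_by_gene[[g]]) %||% character(0)
  })
  rownames(out) <- NULL
  class(out) <- c("phylostratum_assignment", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() without the scalar-x surprise
resample <- function(x, size, ...) x[sample.int(length(x), size, ...)]

#' Tally genes per phylostratum
#'
#' @param assignments output of [classify_lineage()].
#' @param rank_ladder ladder used to order the census rows.
#' @return data.frame `stratum`, `n_genes`; counts sum to the number of
#'   assigned genes.
#' @export
stratum_census <- function(assignments, rank_ladder = default_rank_ladder()) {
  stopifnot(is.data.frame(assignments), nrow(assignments) > 0)
  levels <- c(rank_ladder, "unclassified-self-only")
  tab <- table(factor(assignments$stratum, levels = levels))
  out <- data.frame(stratum = names(tab), n_genes = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[out$n_genes > 0 | out$stratum %in% rank_ladder, , drop = FALSE]
}
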