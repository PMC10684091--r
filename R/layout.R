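#' Ordered gene layout of one or more chromosomes
#'
#' A `chromosome_layout` is the substrate of all positional analysis in the
#' package: one row per protein-coding gene, ordered by chromosome and start
#' coordinate, carrying a class label and a derived 0/1 label vector marking
#' the focal class set (by default LSGs, including LSGs that also encode a
#' HET domain).
#'
#' Coordinates are held 0-based half-open internally; [write_genome_gff3()]
#' converts to the 1-based inclusive GFF3 convention on output.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `class`.  `class` must be one of `"LSG"`, `"HET"`,
#'   `"HET_LSG"`, `"other"`.  Additional columns are kept.
#' @param focal_classes classes contributing a 1 to the label vector.
#' @return A data.frame of (sub)class `chromosome_layout`, ordered by
#'   `chrom` then `start`, with a `label` column of 0/1.
#' @examples
#' gl <- data.frame(gene_id = paste0("g", 1:4), chrom = "chrI",
#'                  start = c(0, 1000, 2500, 4000),
#'                  end = c(800, 2300, 3600, 5200),
#'                  strand = "+", class = c("LSG", "other", "LSG", "HET"))
#' layout <- chromosome_layout(gl)
#' label_vector(layout, "chrI")
#' @export
chromosome_layout <- function(genes, focal_classes = c("LSG", "HET_LSG")) {
  required <- c("gene_id", "chrom", "start", "end", "strand", "class")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols)) {
    stop("layout is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  bad <- setdiff(unique(genes$class), c("LSG", "HET", "HET_LSG", "other"))
  if (length(bad)) stop("unknown gene classes: ", paste(bad, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id in layout")
  if (any(genes$end <= genes$start)) stop("gene end must exceed start")
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  # non-overlap within chromosome
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)])) {
      stop("overlapping genes on chromosome ", ch)
    }
  }
  genes$label <- as.integer(genes$class %in% focal_classes)
  rownames(genes) <- NULL
  attr(genes, "focal_classes") <- focal_classes
  class(genes) <- c("chromosome_layout", "data.frame")
  genes
}

#' @rdname chromosome_layout
#' @param layout a `chromosome_layout`.
#' @param chrom chromosome identifier; if `NULL` and the layout holds a
#'   single chromosome, that one is used.
#' @export
label_vector <- function(layout, chrom = NULL) {
  stopifnot(inherits(layout, "chromosome_layout"))
  if (is.null(chrom)) {
    chroms <- unique(layout$chrom)
    if (length(chroms) != 1L) {
      stop("layout has several chromosomes; supply `chrom`")
    }
    chrom <- chroms
  }
  layout$label[layout$chrom == chrom]
}

#' Relabel the focal class set of a layout
#'
#' @param layout a `chromosome_layout`.
#' @param focal_classes new focal class set.
#' @return the layout with its `label` column recomputed.
#' @export
set_focal_classes <- function(layout, focal_classes) {
  stopifnot(inherits(layout, "chromosome_layout"))
  layout$label <- as.integer(layout$class %in% focal_classes)
  attr(layout, "focal_classes") <- focal_classes
  layout
}

#' @export
print.chromosome_layout <- function(x, ...) {
  cat(sprintf(
    "<chromosome_layout> %d genes on %d chromosome(s); %d labeled (%s)\n",
    nrow(x), length(unique(x$chrom)), sum(x$label),
    paste(attr(x, "focal_classes"), collapse = "+")
  ))
  NextMethod()
}
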