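#' Read and write the package's file formats
#'
#' Gene layouts travel as GFF3 (one `gene` record per protein-coding gene)
#' plus a TSV label table; clusters as BED; everything else as plain TSV.
#' Internal coordinates are 0-based half-open; the GFF3 writer emits the
#' 1-based inclusive convention and the reader converts back.
#'
#' @param layout a [chromosome_layout()].
#' @param path output file.
#' @name lsg_io
NULL

#' @rdname lsg_io
#' @export
write_genome_gff3 <- function(layout, path) {
  stopifnot(inherits(layout, "chromosome_layout"))
  gr <- GenomicRanges::GRanges(
    seqnames = layout$chrom,
    ranges = IRanges::IRanges(start = layout$start + 1L, end = layout$end),
    strand = layout$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- "lsgclust"
  S4Vectors::mcols(gr)$ID <- layout$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname lsg_io
#' @param labels_path TSV with columns `gene_id`, `class`.
#' @export
write_label_table <- function(layout, labels_path) {
  stopifnot(inherits(layout, "chromosome_layout"))
  fwrite(data.table(gene_id = layout$gene_id, class = layout$class),
         labels_path, sep = "\t")
  invisible(labels_path)
}

#' @rdname lsg_io
#' @param gff_path GFF3 file of gene records.
#' @param focal_classes forwarded to [chromosome_layout()].
#' @export
read_genome_layout <- function(gff_path, labels_path,
                               focal_classes = c("LSG", "HET_LSG")) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  labels <- as.data.frame(fread(labels_path))
  ids <- S4Vectors::mcols(gr)$ID
  cls <- labels$class[match(ids, labels$gene_id)]
  if (anyNA(cls)) stop("label table misses genes present in the GFF3")
  chromosome_layout(data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    class = cls,
    stringsAsFactors = FALSE), focal_classes = focal_classes)
}

#' @rdname lsg_io
#' @param hits a hit table.
#' @export
write_hit_table <- function(hits, path) {
  fwrite(as.data.table(as.data.frame(hits)), path, sep = "\t")
  invisible(path)
}

#' @rdname lsg_io
#' @export
read_hit_table <- function(path) {
  out <- as.data.frame(fread(path))
  required <- c("query_gene", "subject_taxon", "mrca_rank", "e_value",
                "reciprocal_best")
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols)) {
    stop("hit table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  class(out) <- c("hit_table", "data.frame")
  out
}

#' @rdname lsg_io
#' @param counts genes x samples matrix.
#' @param samples sample sheet.
#' @param counts_path,samples_path output TSVs.
#' @export
write_count_matrix <- function(counts, samples, counts_path, samples_path) {
  dt <- data.table(gene_id = rownames(counts))
  dt <- cbind(dt, as.data.table(counts))
  fwrite(dt, counts_path, sep = "\t")
  fwrite(as.data.table(samples), samples_path, sep = "\t")
  invisible(counts_path)
}

#' @rdname lsg_io
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  dt <- fread(counts_path)
  counts <- as.matrix(dt[, -1])
  rownames(counts) <- dt[[1]]
  storage.mode(counts) <- "integer"
  list(counts = counts, samples = as.data.frame(fread(samples_path)))
}

#' @rdname lsg_io
#' @param clusters list of `gene_cluster` objects (p-values filled in).
#' @export
write_cluster_bed <- function(clusters, path) {
  df <- clusters_as_data_frame(clusters)
  if (nrow(df) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- ifelse(is.na(df$p_value), 0,
                  pmin(1000, round(-10 * log10(pmax(df$p_value, 1e-100)))))
  bed <- data.table(chrom = df$chrom,
                    start = as.integer(df$start),
                    end = as.integer(df$end),
                    name = sprintf("cluster_%03d", df$cluster_id),
                    score = as.integer(score),
                    strand = ".")
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname lsg_io
#' @param rel a [relative_expression()] result.
#' @export
write_relative_expression <- function(rel, path) {
  stopifnot(inherits(rel, "rel_expr"))
  long <- data.table(
    gene_id = rep(rel$genes, times = length(rel$conditions)),
    condition = rep(rel$conditions, each = length(rel$genes)),
    level = as.numeric(rel$level),
    lower95 = as.numeric(rel$lower95),
    upper95 = as.numeric(rel$upper95),
    detectable = as.logical(rel$detectable))
  fwrite(long, path, sep = "\t")
  invisible(path)
}
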