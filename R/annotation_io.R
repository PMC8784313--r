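#' Write / read annotation and panel tables
#'
#' The annotation is exchanged as a BED12-like TSV (chrom, start, end,
#' gene_id, score, strand, blockCount, blockSizes, blockStarts; no header,
#' block starts relative to the gene start as in BED), the abundance matrix
#' as a gene x cell-type TSV, and marker panels as a two-column
#' (cell_type, gene_id) TSV.
#'
#' @param ann A `nucsort_annotation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(ann, path) {
  stopifnot(inherits(ann, "nucsort_annotation"))
  ex <- split(ann$exons, ann$exons$gene_id)
  g <- ann$genes
  sizes <- starts <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    e <- ex[[g$gene_id[i]]]
    e <- e[order(e$start), , drop = FALSE]
    sizes[i] <- paste(e$end - e$start, collapse = ",")
    starts[i] <- paste(e$start - g$start[i], collapse = ",")
  }
  bed <- data.frame(g$chrom, g$start, g$end, g$gene_id, 0L, g$strand,
                    g$n_exons, sizes, starts)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 9L) stop("expected a 9-column BED12-like annotation TSV")
  names(bed)[1:9] <- c("chrom", "start", "end", "gene_id", "score", "strand",
                       "n_exons", "block_sizes", "block_starts")
  exons <- do.call(rbind, lapply(seq_len(nrow(bed)), function(i) {
    sz <- as.integer(strsplit(bed$block_sizes[i], ",")[[1]])
    st <- as.integer(strsplit(bed$block_starts[i], ",")[[1]])
    if (length(sz) != bed$n_exons[i] || length(st) != bed$n_exons[i])
      stop(sprintf("gene %s: blockCount does not match block lists", bed$gene_id[i]))
    data.frame(gene_id = bed$gene_id[i], chrom = bed$chrom[i],
               start = bed$start[i] + st, end = bed$start[i] + st + sz,
               exon_index = seq_along(sz), row.names = NULL)
  }))
  genes <- data.frame(gene_id = bed$gene_id, chrom = bed$chrom,
                      strand = bed$strand, start = bed$start, end = bed$end,
                      n_exons = bed$n_exons,
                      exonic_length = vapply(split(exons$end - exons$start, exons$gene_id),
                                             sum, 0L)[bed$gene_id],
                      row.names = NULL)
  structure(list(genes = genes, exons = exons, introns = NULL, junctions = NULL,
                 expr = NULL, markers = NULL, cell_types = NULL,
                 chrom_lengths = vapply(split(genes$end, genes$chrom), max, 0L) + 10000L,
                 intergenic = NULL, seed = NA_integer_),
            class = "nucsort_annotation")
}

#' @rdname write_annotation_bed
#' @export
write_expression_tsv <- function(ann, path) {
  stopifnot(inherits(ann, "nucsort_annotation"), !is.null(ann$expr))
  df <- data.frame(gene_id = rownames(ann$expr), ann$expr,
                   check.names = FALSE, row.names = NULL)
  write_tsv(df, path)
}

#' @param markers Named list of gene-id character vectors (one per panel).
#' @rdname write_annotation_bed
#' @export
write_marker_panels <- function(markers, path) {
  df <- data.frame(
    cell_type = rep(names(markers), lengths(markers)),
    gene_id = unlist(markers, use.names = FALSE))
  write_tsv(df, path)
}

#' @rdname write_annotation_bed
#' @export
read_marker_panels <- function(path) {
  df <- read_tsv(path)
  if (!all(c("cell_type", "gene_id") %in% names(df)))
    stop("panel TSV must have columns cell_type and gene_id")
  split(df$gene_id, df$cell_type)
}

#' Read a two-column reference expression TSV
#'
#' Accepts the generic (gene_id, value) shape of published per-cell-type
#' expression tables (FPKM / RPM / average read count).  Returns a named
#' numeric vector with the unit attached as an attribute.
#'
#' @param path TSV with a header; first column gene ids, second values.
#' @param unit Unit label carried into enrichment computations.
#' @export
read_reference_expression <- function(path, unit = NA_character_) {
  df <- read_tsv(path)
  if (ncol(df) < 2L) stop("reference expression TSV needs >= 2 columns")
  x <- as.numeric(df[[2L]])
  names(x) <- as.character(df[[1L]])
  attr(x, "unit") <- unit
  x
}
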