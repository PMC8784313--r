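#' Junction intervals of alignment records
#'
#' For junction-spanning records, the reference interval skipped by the
#' first N operation (0-based half-open).
#'
#' @param records Alignment data.frame (see [read_sam()]).
#' @return data.frame with chrom, start, end, strand and the source row
#'   index; one row per junction-spanning record.
#' @export
junction_spans <- function(records) {
  js <- is_junction_spanning(records$cigar, records$qname)
  idx <- which(js)
  if (!length(idx))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      row = integer(0)))
  fj <- cigar_first_junction(records$cigar[idx])
  start0 <- records$pos[idx] - 1L + fj$pre_ref
  data.frame(chrom = records$rname[idx],
             start = start0, end = start0 + fj$n_length,
             strand = ifelse(bitwAnd(records$flag[idx], 16L) != 0L, "-", "+"),
             row = idx, row.names = NULL)
}

#' Assign junction-spanning reads to genes
#'
#' A read is assigned to a gene iff its skipped-intron interval lies
#' entirely within exactly one gene's \[start, end) span (containment, not
#' exon-boundary matching -- robust to annotation imprecision).  Junctions
#' contained in more than one gene are ambiguous and left unassigned (never
#' silently double-counted); junctions extending past every gene span are
#' unassigned.  In stranded mode the read strand must match the gene strand.
#'
#' @param records Alignment data.frame; rows that are not junction spanning
#'   get `NA`.
#' @param annotation A `nucsort_annotation` (only gene spans are needed).
#' @param stranded Require read/gene strand agreement (default unstranded).
#' @return Character vector, one gene id or `NA` per record.
#' @export
assign_reads <- function(records, annotation, stranded = FALSE) {
  stopifnot(inherits(annotation, "nucsort_annotation"))
  genes <- annotation$genes
  out <- rep(NA_character_, nrow(records))
  js <- junction_spans(records)
  if (!nrow(js)) return(out)
  for (ch in unique(js$chrom)) {
    qi <- which(js$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    # convert 0-based half-open to 1-based closed for IRanges
    q <- IRanges::IRanges(start = js$start[qi] + 1L, end = js$end[qi])
    s <- IRanges::IRanges(start = genes$start[gi] + 1L, end = genes$end[gi])
    hits <- IRanges::findOverlaps(q, s, type = "within")
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (stranded) {
      ok <- js$strand[qi[qh]] == genes$strand[gi[sh]]
      qh <- qh[ok]; sh <- sh[ok]
    }
    tab <- tabulate(qh, nbins = length(qi))
    uniq <- which(tab == 1L)
    if (length(uniq)) {
      first <- match(uniq, qh)
      out[js$row[qi[uniq]]] <- genes$gene_id[gi[sh[first]]]
    }
  }
  out
}

new_expr_table <- function(values, unit, unassigned = NULL) {
  stopifnot(is.matrix(values))
  structure(values, unit = unit, unassigned = unassigned,
            class = c("expr_table", class(values)))
}

#' @export
print.expr_table <- function(x, ...) {
  cat(sprintf("expr_table [%s]: %d sample(s) x %d genes\n",
              attr(x, "unit"), nrow(x), ncol(x)))
  invisible(x)
}

expr_unit <- function(x) attr(x, "unit")

#' Count junction reads per gene
#'
#' @param records Filtered alignment data.frame (junction-spanning reads).
#'   Non-junction rows are counted as unassigned.
#' @param annotation A `nucsort_annotation`.
#' @param sample_label Row label for the resulting one-row table.
#' @param stranded Passed to [assign_reads()].
#' @return One-row `expr_table` (unit "count") over all annotated genes;
#'   attribute `unassigned` holds the per-sample unassigned read count.
#'   `sum(counts) + unassigned` equals `nrow(records)` exactly.
#' @export
count_table <- function(records, annotation, sample_label = "sample",
                        stranded = FALSE) {
  gid <- assign_reads(records, annotation, stranded = stranded)
  lev <- annotation$genes$gene_id
  counts <- tabulate(match(gid, lev), nbins = length(lev))
  values <- matrix(as.integer(counts), nrow = 1,
                   dimnames = list(sample_label, lev))
  new_expr_table(values, "count",
                 unassigned = setNames(sum(is.na(gid)), sample_label))
}

#' Combine single-sample expression tables
#'
#' @param tables List of `expr_table`s sharing unit and gene set.
#' @export
bind_expr_tables <- function(tables) {
  units <- unique(vapply(tables, expr_unit, ""))
  if (length(units) != 1L) stop("cannot bind tables with different units")
  values <- do.call(rbind, lapply(tables, unclass))
  un <- do.call(c, lapply(tables, attr, "unassigned"))
  new_expr_table(values, units, unassigned = un)
}

#' Convert junction counts to TPM
#'
#' Junction reads originate from spliced molecules, so length normalisation
#' uses the exonic (spliced) gene length: `rate_g = count_g / exonic_kb`,
#' `TPM_g = 1e6 * rate_g / sum(rates)`.  Every nonzero sample row sums to
#' 1e6; all-zero rows stay zero and are flagged in the `zero_samples`
#' attribute.
#'
#' @param counts `expr_table` with unit "count".
#' @param annotation Provides `exonic_length` per gene; zero lengths are an
#'   error.
#' @return `expr_table` with unit "TPM".
#' @export
to_tpm <- function(counts, annotation) {
  stopifnot(inherits(counts, "expr_table"))
  if (expr_unit(counts) != "count") stop("to_tpm expects a count table")
  len <- annotation$genes$exonic_length[match(colnames(counts), annotation$genes$gene_id)]
  if (anyNA(len)) stop("annotation is missing genes present in the count table")
  if (any(len <= 0)) stop("zero exonic length in annotation")
  rate <- sweep(unclass(counts), 2, len / 1000, "/")
  tot <- rowSums(rate)
  zero <- tot == 0
  tot[zero] <- 1
  tpm <- rate / tot * 1e6
  out <- new_expr_table(tpm, "TPM", unassigned = attr(counts, "unassigned"))
  attr(out, "zero_samples") <- rownames(counts)[zero]
  out
}

#' Convert counts to reads-per-million (no length term)
#'
#' @inheritParams to_tpm
#' @export
to_rpm <- function(counts) {
  stopifnot(inherits(counts, "expr_table"))
  if (expr_unit(counts) != "count") stop("to_rpm expects a count table")
  tot <- rowSums(unclass(counts))
  zero <- tot == 0
  tot[zero] <- 1
  out <- new_expr_table(unclass(counts) / tot * 1e6, "RPM",
                        unassigned = attr(counts, "unassigned"))
  attr(out, "zero_samples") <- rownames(counts)[zero]
  out
}

#' Number of detected genes per sample
#'
#' @param counts `expr_table` with unit "count".
#' @param min_count Detection threshold (inclusive).
#' @return Named integer vector, one entry per sample.
#' @export
detected_genes <- function(counts, min_count = 1) {
  stopifnot(inherits(counts, "expr_table"))
  if (expr_unit(counts) != "count") stop("detected_genes expects a count table")
  apply(unclass(counts) >= min_count, 1, sum)
}

#' Extract one sample's expression as a named vector
#'
#' Keeps the table's unit as an attribute, ready for [gene_enrichment()].
#'
#' @param table An `expr_table`.
#' @param sample Row label.
#' @export
expr_row <- function(table, sample) {
  stopifnot(inherits(table, "expr_table"))
  if (!sample %in% rownames(table)) stop(sprintf("no sample '%s' in table", sample))
  x <- unclass(table)[sample, ]
  attr(x, "unit") <- expr_unit(table)
  x
}

#' Write / read an expression table as genes x samples TSV
#'
#' @param table An `expr_table`.
#' @param path TSV path.  Layout: gene_id column followed by one column per
#'   sample.
#' @export
write_expr_table <- function(table, path) {
  df <- data.frame(gene_id = colnames(table), t(unclass(table)),
                   check.names = FALSE, row.names = NULL)
  write_tsv(df, path)
}

#' @rdname write_expr_table
#' @param unit Unit label to attach on read.
#' @export
read_expr_table <- function(path, unit) {
  df <- read_tsv(path)
  values <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(values) <- df[[1]]
  new_expr_table(values, unit)
}
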