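#' Simulate aligned nuclear RNA-seq reads for a nucleus composition
#'
#' Emits a valid plain-text SAM stream reproducing the read-class structure
#' of nuclear RNA preps: a `dna_contamination_fraction` of records are
#' intergenic genomic-DNA reads (junctionless, placed in gaps between
#' genes); of the gene-derived remainder, `intronic_read_fraction` are
#' junctionless reads inside introns and the rest span exactly one exon-exon
#' junction, with a CIGAR N operation whose length equals the skipped
#' intron.  Expected junction-read counts per gene are proportional to the
#' composition-weighted gene abundance.  Unfixed mode scales the total
#' record count by `rna_recovery_factor_unfixed` (RNA leak during sorting).
#'
#' Reads are single-end, fixed length, at most one junction per read;
#' SEQ/QUAL are `"*"`.  Each record carries ground-truth tags
#' `XC:Z:<class>` (junction/intronic/intergenic) and `XG:Z:<gene>`.
#'
#' @param composition Named non-negative numeric vector: nuclei (or weights)
#'   per cell type.  Unknown cell types raise an error naming the type.
#' @param annotation A [make_annotation()] result.
#' @param config A [sim_config()].
#' @param stream Integer sub-stream offset so multiple samples drawn from
#'   the same config/seed are independent but reproducible.
#' @param sample_name Used as the read-name prefix.
#' @return Object of class `sim_reads`: list with `header`, `records`
#'   (data.frame in SAM column order plus `tags`), and `counts` (totals per
#'   read class).
#' @export
simulate_reads <- function(composition, annotation, config, stream = 0L,
                           sample_name = "sample") {
  stopifnot(inherits(annotation, "nucsort_annotation"),
            inherits(config, "sim_config"))
  if (is.null(annotation$expr))
    stop("annotation has no abundance matrix (was it read from BED only?)")
  if (length(composition) == 0L || is.null(names(composition)))
    stop("`composition` must be a named cell-type -> count vector")
  unknown <- setdiff(names(composition), colnames(annotation$expr))
  if (length(unknown))
    stop(sprintf("unknown cell type in composition: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (any(composition < 0) || sum(composition) <= 0)
    stop("composition must be non-negative with positive total")

  n_total <- config$read_depth
  if (config$fixation == "unfixed")
    n_total <- as.integer(round(n_total * config$rna_recovery_factor_unfixed))

  frac <- composition / sum(composition)
  w <- as.numeric(annotation$expr[, names(frac), drop = FALSE] %*% frac)
  genes <- annotation$genes
  rl <- config$read_length

  # per-gene lookup offsets into the intron/junction tables (both are in
  # gene order of `genes`)
  jt <- annotation$junctions
  it <- annotation$introns
  n_j <- genes$n_exons - 1L
  off <- c(0L, cumsum(n_j))[seq_len(nrow(genes))]
  gap <- annotation$intergenic

  hdr <- sam_header_lines(annotation$chrom_lengths)
  empty <- data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      rnext = character(0), pnext = integer(0),
                      tlen = integer(0), seq = character(0),
                      qual = character(0), tags = character(0))
  if (n_total == 0L)
    return(structure(list(header = hdr, records = empty,
                          counts = list(total = 0L, intergenic = 0L,
                                        intronic = 0L, junction = 0L)),
                     class = "sim_reads"))

  withr::with_seed(derive_seed(config$seed, RNG_STREAM[["reads"]] + stream), {
    d <- config$dna_contamination_fraction
    i <- config$intronic_read_fraction
    cls <- sample(c("intergenic", "intronic", "junction"), n_total,
                  replace = TRUE,
                  prob = c(d, (1 - d) * i, (1 - d) * (1 - i)))

    rname <- character(n_total)
    pos0 <- integer(n_total)
    cigar <- character(n_total)
    flag <- integer(n_total)
    gene <- rep("*", n_total)

    ig <- which(cls == "intergenic")
    if (length(ig)) {
      glen <- gap$end - gap$start - rl + 1L
      row <- sample.int(nrow(gap), length(ig), replace = TRUE, prob = glen)
      rname[ig] <- gap$chrom[row]
      pos0[ig] <- gap$start[row] + as.integer(floor(runif(length(ig)) * glen[row]))
      cigar[ig] <- sprintf("%dM", rl)
    }

    gr <- which(cls != "intergenic")
    if (length(gr)) {
      gi <- sample.int(nrow(genes), length(gr), replace = TRUE, prob = w)
      gene[gr] <- genes$gene_id[gi]
      rname[gr] <- genes$chrom[gi]
      flag[gr] <- ifelse(genes$strand[gi] == "-", 16L, 0L)

      intr <- cls[gr] == "intronic"
      if (any(intr)) {
        gii <- gi[intr]
        pick <- off[gii] + as.integer(floor(runif(sum(intr)) * n_j[gii])) + 1L
        span <- it$end[pick] - it$start[pick] - rl + 1L
        # introns are >= 200 bp by construction, always >= read length
        pos0[gr[intr]] <- it$start[pick] +
          as.integer(floor(runif(sum(intr)) * pmax(span, 1L)))
        cigar[gr[intr]] <- sprintf("%dM", rl)
      }

      junc <- !intr
      if (any(junc)) {
        gij <- gi[junc]
        pick <- off[gij] + as.integer(floor(runif(sum(junc)) * n_j[gij])) + 1L
        lo <- pmax(10L, rl - jt$right_exon_length[pick])
        hi <- pmin(rl - 10L, jt$left_exon_length[pick])
        o <- lo + as.integer(floor(runif(sum(junc)) * (hi - lo + 1L)))
        pos0[gr[junc]] <- jt$donor_end[pick] - o
        cigar[gr[junc]] <- sprintf("%dM%dN%dM", o, jt$intron_length[pick], rl - o)
      }
    }

    records <- data.frame(
      qname = sprintf("%s_%07d", sample_name, seq_len(n_total)),
      flag = flag, rname = rname, pos = pos0 + 1L, mapq = 255L,
      cigar = cigar, rnext = "*", pnext = 0L, tlen = 0L,
      seq = "*", qual = "*",
      tags = sprintf("XC:Z:%s\tXG:Z:%s", cls, gene),
      row.names = NULL)
  })

  structure(list(
    header = hdr, records = records,
    counts = list(total = n_total,
                  intergenic = sum(cls == "intergenic"),
                  intronic = sum(cls == "intronic"),
                  junction = sum(cls == "junction"))
  ), class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("sim_reads: %d records (%d junction, %d intronic, %d intergenic)\n",
              x$counts$total, x$counts$junction, x$counts$intronic,
              x$counts$intergenic))
  invisible(x)
}

#' @rdname simulate_reads
#' @param reads A `sim_reads` object.
#' @param path Output SAM path.
#' @export
write_sim_reads <- function(reads, path) {
  stopifnot(inherits(reads, "sim_reads"))
  write_sam(reads$header, reads$records, path)
}
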