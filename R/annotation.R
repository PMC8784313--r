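# Canonical gene symbols grafted onto the first few synthetic markers of each
# type so that qPCR targets and QC rules can be expressed in the field's
# vocabulary (Cldn5/Cdh5 endothelium, PTPRC/AIF1 microglia, Map2/NeuN neurons,
# Ubc/Actb housekeeping).
CANONICAL_MARKERS <- list(
  endothelial     = c("CLDN5", "CDH5", "VWF", "ERG", "PECAM1", "ICAM2"),
  neuron          = c("MAP2", "MEG3", "RBFOX3", "SYT1"),
  microglia       = c("PTPRC", "AIF1", "CSF1R"),
  astrocyte       = c("GFAP", "AQP4", "SLC1A2"),
  oligodendrocyte = c("MBP", "MOG", "PLP1"),
  OPC             = c("PDGFRA", "CSPG4"),
  other           = character()
)
CANONICAL_SHARED <- c("UBC", "ACTB", "GAPDH")

#' Generate a synthetic gene annotation with cell-type marker panels
#'
#' Lays out `n_genes` multi-exon genes (3-6 exons, exons 150-400 bp, introns
#' 200-1000 bp) on two simulated chromosomes with intergenic gaps, assigns
#' each cell type a disjoint panel of marker genes, and builds a gene x
#' cell-type abundance matrix.  A marker gene carries `marker_exclusivity`
#' of its total abundance in its own type, the remainder spread evenly over
#' the other types; non-marker ("shared") genes are expressed equally in all
#' types.  Every gene has total abundance 10 (arbitrary units), so each cell
#' type's total transcriptional output is identical -- this makes per-sample
#' TPM normalisation cancel exactly in sorted-vs-unsorted ratios.
#'
#' Coordinates are 0-based half-open internally; SAM emission converts to
#' 1-based.
#'
#' @param config A [sim_config()].
#' @param cell_types Character vector of cell-type names; each gets a marker
#'   panel.
#' @return An object of class `nucsort_annotation`: a list with elements
#'   `genes` (gene table incl. `exonic_length`), `exons`, `introns`,
#'   `junctions` (donor/acceptor geometry per exon-exon junction), `expr`
#'   (gene x cell-type abundance matrix), `markers` (named list of gene-id
#'   panels), `chrom_lengths`, and `intergenic` (gap intervals used to place
#'   genomic-DNA reads).
#' @export
make_annotation <- function(config, cell_types = nuc_cell_types()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  K <- length(cell_types)
  m <- config$n_marker_genes_per_type
  if (n < K * m)
    stop(sprintf(
      "infeasible configuration: n_genes = %d cannot host %d cell types x %d markers",
      n, K, m), call. = FALSE)

  withr::with_seed(derive_seed(config$seed, RNG_STREAM[["annotation"]]), {
    n_ex <- sample(3:6, n, replace = TRUE)
    chrom <- rep(c("chr1", "chr2"), length.out = n)
    strand <- sample(c("+", "-"), n, replace = TRUE)

    cursor <- c(chr1 = 0L, chr2 = 0L)
    gene_start <- integer(n)
    gene_end <- integer(n)
    exon_list <- vector("list", n)
    for (g in seq_len(n)) {
      ne <- n_ex[g]
      elen <- sample(150:400, ne, replace = TRUE)
      ilen <- sample(200:1000, ne - 1L, replace = TRUE)
      gap <- sample(2000:5000, 1L)
      s <- cursor[[chrom[g]]] + gap
      starts <- s + c(0L, cumsum(elen[-ne] + ilen))
      ends <- starts + elen
      exon_list[[g]] <- cbind(start = starts, end = ends)
      gene_start[g] <- s
      gene_end[g] <- ends[ne]
      cursor[[chrom[g]]] <- ends[ne]
    }

    # marker gene placement is random over the genome
    marker_idx <- sample(n, K * m)
    markers <- split(marker_idx, rep(cell_types, each = m))[cell_types]

    # gene ids: canonical symbols for the first markers of each panel and the
    # first shared genes, synthetic ids elsewhere
    gene_id <- sprintf("G%05d", seq_len(n))
    abbrev <- c(endothelial = "ENDO", neuron = "NEUR", microglia = "MICR",
                astrocyte = "ASTR", oligodendrocyte = "OLIG", OPC = "OPC",
                other = "OTHR")
    for (t in cell_types) {
      idx <- markers[[t]]
      canon <- CANONICAL_MARKERS[[t]]
      if (is.null(canon)) canon <- character()
      nm <- character(length(idx))
      nc <- min(length(canon), length(idx))
      if (nc > 0) nm[seq_len(nc)] <- canon[seq_len(nc)]
      if (length(idx) > nc) {
        ab <- if (t %in% names(abbrev)) abbrev[[t]] else toupper(substr(t, 1, 4))
        nm[(nc + 1L):length(idx)] <- sprintf("%s_M%03d", ab, (nc + 1L):length(idx))
      }
      gene_id[idx] <- nm
    }
    shared_idx <- setdiff(seq_len(n), marker_idx)
    nshared_canon <- min(length(CANONICAL_SHARED), length(shared_idx))
    if (nshared_canon > 0)
      gene_id[shared_idx[seq_len(nshared_canon)]] <- CANONICAL_SHARED[seq_len(nshared_canon)]

    markers <- lapply(markers, function(i) gene_id[i])

    # abundance matrix: total 10 units per gene
    q <- config$marker_exclusivity
    expr <- matrix(10 / K, nrow = n, ncol = K,
                   dimnames = list(gene_id, cell_types))
    for (t in cell_types) {
      i <- match(markers[[t]], gene_id)
      expr[i, ] <- 10 * (1 - q) / (K - 1)
      expr[i, t] <- 10 * q
    }
  })

  exonic_length <- vapply(exon_list, function(e) sum(e[, "end"] - e[, "start"]), 0L)
  exons <- do.call(rbind, lapply(seq_len(n), function(g) {
    e <- exon_list[[g]]
    data.frame(gene_id = gene_id[g], chrom = chrom[g],
               start = e[, "start"], end = e[, "end"],
               exon_index = seq_len(nrow(e)), row.names = NULL)
  }))
  introns <- do.call(rbind, lapply(seq_len(n), function(g) {
    e <- exon_list[[g]]
    ne <- nrow(e)
    data.frame(gene_id = gene_id[g], chrom = chrom[g],
               start = e[-ne, "end"], end = e[-1L, "start"], row.names = NULL)
  }))
  introns$length <- introns$end - introns$start
  junctions <- do.call(rbind, lapply(seq_len(n), function(g) {
    e <- exon_list[[g]]
    ne <- nrow(e)
    data.frame(gene_id = gene_id[g], chrom = chrom[g],
               donor_end = e[-ne, "end"],            # 0-based exclusive end of left exon
               acceptor_start = e[-1L, "start"],     # 0-based start of right exon
               intron_length = e[-1L, "start"] - e[-ne, "end"],
               left_exon_length = e[-ne, "end"] - e[-ne, "start"],
               right_exon_length = e[-1L, "end"] - e[-1L, "start"],
               row.names = NULL)
  }))

  genes <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      start = gene_start, end = gene_end,
                      n_exons = n_ex, exonic_length = as.integer(exonic_length),
                      row.names = NULL)

  chrom_lengths <- vapply(split(genes$end, genes$chrom), max, 0L) + 10000L
  intergenic <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    data.frame(chrom = ch,
               start = c(0L, g$end),
               end = c(g$start, chrom_lengths[[ch]]), row.names = NULL)
  }))
  intergenic <- intergenic[intergenic$end - intergenic$start >= config$read_length, ]

  structure(list(
    genes = genes, exons = exons, introns = introns, junctions = junctions,
    expr = expr, markers = markers, cell_types = cell_types,
    chrom_lengths = chrom_lengths, intergenic = intergenic,
    seed = config$seed
  ), class = "nucsort_annotation")
}

#' @export
print.nucsort_annotation <- function(x, ...) {
  cat(sprintf("nucsort_annotation: %d genes on %d chromosomes, %d cell types\n",
              nrow(x$genes), length(x$chrom_lengths), length(x$cell_types)))
  cat(sprintf("  marker panels: %s\n",
              paste(sprintf("%s (%d)", names(x$markers), lengths(x$markers)),
                    collapse = ", ")))
  invisible(x)
}
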