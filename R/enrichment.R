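#' Per-gene log2 enrichment between two expression vectors
#'
#' The sorted-vs-reference statistic: `log2((x + eps) / (y + eps))` over the
#' gene intersection of the two inputs.  With `pseudocount = 0`, genes with
#' a zero denominator are flagged non-finite and excluded from medians
#' downstream.  When the two inputs carry different units (e.g. TPM from
#' sorted nuclei against FPKM from a published whole-cell table) both are
#' rescaled to sum to 1e6 first, with a loud warning -- the ratio is then
#' scale-free, mirroring the mixed-unit comparisons this analysis permits.
#'
#' @param numerator,denominator Named numeric vectors (see [expr_row()]);
#'   an optional `unit` attribute drives the mixed-unit rescaling.
#' @param pseudocount Non-negative `eps`, in the unit of the inputs.
#' @param comparison_label Free-text label stored on the result.
#' @param rescale `"auto"` rescales only on unit mismatch; `"always"`,
#'   `"never"` force the behaviour.
#' @return data.frame of class `enrichment_table` with columns gene_id,
#'   log2_enrichment, finite.
#' @export
gene_enrichment <- function(numerator, denominator, pseudocount = 0.5,
                            comparison_label = "sorted-vs-reference",
                            rescale = c("auto", "always", "never")) {
  rescale <- match.arg(rescale)
  if (pseudocount < 0) stop("`pseudocount` must be >= 0")
  if (is.null(names(numerator)) || is.null(names(denominator)))
    stop("numerator and denominator must be named by gene id")
  shared <- intersect(names(numerator), names(denominator))
  if (!length(shared)) stop("empty gene intersection between inputs")
  x <- as.numeric(numerator[shared])
  y <- as.numeric(denominator[shared])
  un <- attr(numerator, "unit"); ud <- attr(denominator, "unit")
  mismatch <- !is.null(un) && !is.null(ud) && !is.na(un) && !is.na(ud) && un != ud
  if (rescale == "always" || (rescale == "auto" && mismatch)) {
    if (mismatch)
      warning(sprintf(
        "mixed units (%s vs %s): rescaling both inputs to sum 1e6 before the ratio",
        un, ud))
    if (sum(x) > 0) x <- x / sum(x) * 1e6
    if (sum(y) > 0) y <- y / sum(y) * 1e6
  }
  l2 <- log2((x + pseudocount) / (y + pseudocount))
  out <- data.frame(gene_id = shared, log2_enrichment = l2,
                    finite = is.finite(l2), row.names = NULL)
  structure(out, comparison_label = comparison_label,
            class = c("enrichment_table", "data.frame"))
}

enr_values <- function(enr, genes) {
  v <- enr$log2_enrichment[match(genes, enr$gene_id)]
  v[!is.na(v) & !enr$finite[match(genes, enr$gene_id)]] <- NA
  v
}

#' Panel medians and relative enrichment of the target panel
#'
#' Median log2 enrichment per marker panel, plus the target panel's median
#' enrichment relative to the other panels: the target median minus the
#' median over all non-target panel genes pooled (default), or minus the
#' median of the other panels' medians (`other = "median_of_medians"`).
#' Panels with no finite values after intersection are flagged and excluded
#' from the pooled background.
#'
#' @param enrichment An `enrichment_table`.
#' @param panels Named list of gene-id vectors (disjoint; enforced upstream
#'   by [refine_markers()]).
#' @param target Panel whose relative enrichment is reported.
#' @param other Aggregation of the non-target background.
#' @return Object of class `panel_summary`: list with `per_panel`
#'   (panel, n, median_log2, excluded), `relative_enrichment`, `target`,
#'   `other_aggregation`.
#' @export
panel_summary <- function(enrichment, panels, target = "endothelial",
                          other = c("pooled", "median_of_medians")) {
  other <- match.arg(other)
  stopifnot(inherits(enrichment, "enrichment_table"))
  if (!target %in% names(panels))
    stop(sprintf("target panel '%s' not among panels", target))
  vals <- lapply(panels, function(g) {
    v <- enr_values(enrichment, g)
    v[is.finite(v)]
  })
  n <- vapply(vals, length, 0L)
  med <- vapply(vals, function(v) if (length(v)) median(v) else NA_real_, 0)
  per_panel <- data.frame(panel = names(panels), n = n, median_log2 = med,
                          excluded = n == 0L, row.names = NULL)
  non_target <- setdiff(names(panels)[n > 0L], target)
  rel <- NA_real_
  if (n[[target]] > 0L && length(non_target)) {
    bg <- if (other == "pooled") median(unlist(vals[non_target]))
          else median(med[non_target])
    rel <- med[[target]] - bg
  }
  structure(list(per_panel = per_panel, relative_enrichment = unname(rel),
                 target = target, other_aggregation = other),
            class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  print(x$per_panel)
  cat(sprintf("relative enrichment of '%s' vs other panels (%s): %.3f log2\n",
              x$target, x$other_aggregation, x$relative_enrichment))
  invisible(x)
}

#' Refine marker panels against gold-standard references
#'
#' Marker-stringency refinement: a target-panel gene is retained iff its
#' log2 enrichment is at least `min_log2` (inclusive) in every provided
#' reference enrichment table (e.g. whole-cell and nuclei endothelial-vs-bulk
#' references); genes absent or non-finite in a reference fail the check
#' unless `min_log2` is `-Inf`.  Independently, genes appearing in more than
#' one panel are removed from all panels (a gene may not inflate two
#' panels).  Removals are reported with reasons, never applied silently.
#'
#' @param panels Named list of gene-id vectors.
#' @param reference_enrichments One `enrichment_table` or a list of them.
#' @param min_log2 Inclusive retention threshold for the target panel.
#' @param target Panel subjected to the reference check.
#' @return List with `panels` (refined) and `removed`
#'   (panel, gene_id, reason).
#' @export
refine_markers <- function(panels, reference_enrichments, min_log2 = 1,
                           target = "endothelial") {
  if (inherits(reference_enrichments, "enrichment_table"))
    reference_enrichments <- list(reference_enrichments)
  all_genes <- unlist(panels, use.names = FALSE)
  dup <- unique(all_genes[duplicated(all_genes)])
  removed <- data.frame(panel = character(0), gene_id = character(0),
                        reason = character(0))
  out <- panels
  if (length(dup)) {
    for (p in names(out)) {
      hit <- intersect(out[[p]], dup)
      if (length(hit))
        removed <- rbind(removed, data.frame(panel = p, gene_id = hit,
                                             reason = "cross_panel_duplicate"))
      out[[p]] <- setdiff(out[[p]], dup)
    }
  }
  if (target %in% names(out) && length(out[[target]])) {
    g <- out[[target]]
    pass <- rep(TRUE, length(g))
    for (ref in reference_enrichments) {
      v <- enr_values(ref, g)
      v[is.na(v)] <- -Inf
      pass <- pass & (v >= min_log2)
    }
    if (any(!pass)) {
      removed <- rbind(removed, data.frame(
        panel = target, gene_id = g[!pass],
        reason = sprintf("below_min_log2_%g_in_reference", min_log2)))
      out[[target]] <- g[pass]
    }
    if (!length(out[[target]]))
      warning(sprintf("refinement removed every gene from panel '%s'", target))
  }
  list(panels = out, removed = removed)
}

#' Correlation between two enrichment tables
#'
#' Pairs genes on the intersection (finite values in both) and reports
#' Pearson and Spearman coefficients -- the cross-dataset comparison of
#' sorted-nuclei enrichment against published whole-cell enrichment.
#'
#' @param enrA,enrB `enrichment_table`s.
#' @return List with `pairs` (gene_id, a, b), `pearson`, `spearman`, `n`.
#'   Fewer than 3 shared finite pairs is an error.
#' @export
enrichment_correlation <- function(enrA, enrB) {
  shared <- intersect(enrA$gene_id, enrB$gene_id)
  a <- enr_values(enrA, shared)
  b <- enr_values(enrB, shared)
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L)
    stop(sprintf("need >= 3 shared finite pairs, got %d", sum(ok)))
  pairs <- data.frame(gene_id = shared[ok], a = a[ok], b = b[ok])
  list(pairs = pairs,
       pearson = cor(pairs$a, pairs$b),
       spearman = cor(pairs$a, pairs$b, method = "spearman"),
       n = nrow(pairs))
}

#' QC rules for sorted samples
#'
#' The two published outlier-removal rules: (A) very low Erg+ staining in
#' the flow data, and (B) contamination of a sorted sample with microglial /
#' hematopoietic reads, detected as PTPRC (CD45) TPM above a ceiling.
#'
#' @param erg_fraction_min Minimum acceptable ErgHi fraction of the parent
#'   population.
#' @param contamination_gene Gene id probed by rule B.
#' @param contamination_tpm_max Inclusive TPM ceiling for rule B.
#' @export
qc_rules <- function(erg_fraction_min = 0.005,
                     contamination_gene = "PTPRC",
                     contamination_tpm_max = 500) {
  structure(list(erg_fraction_min = erg_fraction_min,
                 contamination_gene = contamination_gene,
                 contamination_tpm_max = contamination_tpm_max),
            class = "qc_rules")
}

#' Flag outlier samples
#'
#' Applies [qc_rules()] to per-sample gating fractions and a TPM table.
#' Samples are flagged, never dropped -- exclusion is an explicit downstream
#' action.  A missing contamination gene skips rule B with a warning.
#'
#' @param erg_fractions Named numeric vector: ErgHi fraction per sample
#'   (`NA` skips rule A for that sample).
#' @param expression `expr_table` in TPM.
#' @param rules A [qc_rules()].
#' @return data.frame with sample, pass, reasons.
#' @export
sample_qc <- function(erg_fractions, expression, rules = qc_rules()) {
  stopifnot(inherits(expression, "expr_table"))
  if (expr_unit(expression) != "TPM")
    stop("sample_qc expects a TPM table")
  samples <- rownames(expression)
  reasons <- setNames(vector("list", length(samples)), samples)
  for (s in samples) {
    ef <- if (s %in% names(erg_fractions)) erg_fractions[[s]] else NA_real_
    if (!is.na(ef) && ef < rules$erg_fraction_min)
      reasons[[s]] <- c(reasons[[s]],
                        sprintf("A: Erg+ fraction %.4f below %.4f", ef,
                                rules$erg_fraction_min))
  }
  g <- rules$contamination_gene
  if (!g %in% colnames(expression)) {
    warning(sprintf("contamination gene '%s' absent from table: rule B skipped", g))
  } else {
    tpm <- unclass(expression)[, g]
    for (s in samples) {
      if (tpm[[s]] > rules$contamination_tpm_max)
        reasons[[s]] <- c(reasons[[s]],
                          sprintf("B: %s TPM %.1f above ceiling %.1f", g,
                                  tpm[[s]], rules$contamination_tpm_max))
    }
  }
  data.frame(sample = samples,
             pass = vapply(reasons, function(r) length(r) == 0L, TRUE),
             reasons = vapply(reasons, paste, "", collapse = "; "),
             row.names = NULL)
}
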