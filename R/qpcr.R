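#' Simulate a qPCR plate for nucleus compositions
#'
#' For each sample the composition-weighted abundance of a gene is
#' `w_g = sum_t frac_t * expr[g, t]`; the cycle threshold is
#' `CT = ct_reference - log2(w_g) + N(0, qpcr_noise_sd)` per replicate well,
#' so lower abundance gives higher CT and a doubling of abundance lowers CT
#' by exactly one cycle at zero noise.
#'
#' @param compositions Named list: sample label -> named cell-type count (or
#'   weight) vector.
#' @param targets Gene ids to assay.
#' @param housekeeping Housekeeping gene id; zero abundance in any sample is
#'   an error (CT undefined).
#' @param annotation A [make_annotation()] result (provides the abundance
#'   matrix).
#' @param config A [sim_config()]; uses ct_reference, qpcr_noise_sd,
#'   qpcr_replicates, seed.
#' @param stream Sub-stream offset for reproducible independent plates.
#' @return data.frame of wells: sample, gene, replicate, ct.
#' @export
simulate_qpcr <- function(compositions, targets, housekeeping, annotation,
                          config, stream = 0L) {
  stopifnot(inherits(annotation, "nucsort_annotation"),
            inherits(config, "sim_config"))
  if (is.null(names(compositions)) || !is.list(compositions))
    stop("`compositions` must be a named list of composition vectors")
  genes <- unique(c(targets, housekeeping))
  missing <- setdiff(genes, rownames(annotation$expr))
  if (length(missing))
    stop(sprintf("genes absent from annotation: %s",
                 paste(missing, collapse = ", ")))
  w <- sapply(names(compositions), function(s) {
    comp <- compositions[[s]]
    unknown <- setdiff(names(comp), colnames(annotation$expr))
    if (length(unknown))
      stop(sprintf("unknown cell type in composition: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    frac <- comp / sum(comp)
    as.numeric(annotation$expr[genes, names(frac), drop = FALSE] %*% frac)
  })                                      # genes x samples
  w <- matrix(w, nrow = length(genes),
              dimnames = list(genes, names(compositions)))
  if (any(w[housekeeping, ] <= 0))
    stop(sprintf("housekeeping gene %s has zero abundance: CT undefined",
                 housekeeping))
  reps <- config$qpcr_replicates
  grid <- expand.grid(replicate = seq_len(reps), gene = genes,
                      sample = names(compositions), stringsAsFactors = FALSE)
  ct0 <- config$ct_reference - log2(w[cbind(grid$gene, grid$sample)])
  withr::with_seed(derive_seed(config$seed, RNG_STREAM[["qpcr"]] + stream), {
    ct <- ct0 + rnorm(nrow(grid), 0, config$qpcr_noise_sd)
  })
  data.frame(sample = grid$sample, gene = grid$gene,
             replicate = grid$replicate, ct = ct, row.names = NULL)
}

#' Housekeeping-normalised delta-CT per sample and target
#'
#' `delta_ct = mean(ct_target) - mean(ct_housekeeping)` within each sample
#' (replicates aggregated by mean CT, the standard ddCt practice), with
#' replicate SDs reported and propagated.
#'
#' @param wells data.frame with columns sample, gene, ct (replicate rows
#'   permitted).
#' @param housekeeping Housekeeping gene id; missing from any sample is an
#'   error naming the sample.
#' @return data.frame: sample, gene, delta_ct, sd_delta, n_target,
#'   n_housekeeping.
#' @export
delta_ct <- function(wells, housekeeping) {
  need <- c("sample", "gene", "ct")
  if (!all(need %in% names(wells)))
    stop("wells must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(wells$ct))) stop("non-finite CT value in wells")
  out <- list()
  for (s in unique(wells$sample)) {
    ws <- wells[wells$sample == s, ]
    hk <- ws$ct[ws$gene == housekeeping]
    if (!length(hk))
      stop(sprintf("housekeeping gene %s not measured in sample %s",
                   housekeeping, s), call. = FALSE)
    for (g in setdiff(unique(ws$gene), housekeeping)) {
      tg <- ws$ct[ws$gene == g]
      sd_t <- if (length(tg) > 1L) sd(tg) else 0
      sd_h <- if (length(hk) > 1L) sd(hk) else 0
      out[[length(out) + 1L]] <- data.frame(
        sample = s, gene = g,
        delta_ct = mean(tg) - mean(hk),
        sd_delta = sqrt(sd_t^2 / length(tg) + sd_h^2 / length(hk)),
        n_target = length(tg), n_housekeeping = length(hk))
    }
  }
  do.call(rbind, out)
}

#' Fold enrichment from two delta-CTs
#'
#' `fold = efficiency^(delta_ct_unsorted - delta_ct_sorted)`; fold > 1 means
#' the transcript is enriched in the sorted population.  Amplification
#' efficiency defaults to perfect doubling.
#'
#' @param delta_sorted,delta_unsorted Numeric delta-CT values (vectorised).
#' @param efficiency Per-cycle amplification factor.
#' @export
fold_enrichment <- function(delta_sorted, delta_unsorted, efficiency = 2) {
  efficiency^(delta_unsorted - delta_sorted)
}

#' Per-gene fold-enrichment table versus an unsorted reference sample
#'
#' @param wells Well table (see [delta_ct()]).
#' @param housekeeping Housekeeping gene id.
#' @param unsorted Label of the reference (unsorted) sample.
#' @param efficiency Passed to [fold_enrichment()].
#' @return data.frame: sample, gene, delta_ct, fold_vs_unsorted.
#' @export
qpcr_fold_table <- function(wells, housekeeping, unsorted = "unsorted",
                            efficiency = 2) {
  dct <- delta_ct(wells, housekeeping)
  if (!unsorted %in% dct$sample)
    stop(sprintf("no unsorted reference sample '%s' in wells", unsorted))
  ref <- dct[dct$sample == unsorted, c("gene", "delta_ct")]
  res <- dct[dct$sample != unsorted, ]
  ref_dct <- ref$delta_ct[match(res$gene, ref$gene)]
  res$fold_vs_unsorted <- fold_enrichment(res$delta_ct, ref_dct,
                                          efficiency = efficiency)
  res[, c("sample", "gene", "delta_ct", "fold_vs_unsorted")]
}
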