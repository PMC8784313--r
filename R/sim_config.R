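#' Cell types modelled by the simulator
#'
#' The six major brain cell classes with published marker panels
#' (endothelial, neuron, microglia, astrocyte, oligodendrocyte, OPC) plus a
#' catch-all "other" class.
#'
#' @return Character vector of cell-type names.
#' @export
nuc_cell_types <- function() {
  c("endothelial", "neuron", "microglia", "astrocyte",
    "oligodendrocyte", "OPC", "other")
}

#' Default nuclear mixture fractions for whole brain
#'
#' Endothelial nuclei are a small minority of brain nuclei (~2%), neurons
#' roughly a third, microglia a few percent; the remainder is split between
#' macroglia and an unmodelled "other" class.  These are the simulator's
#' stated conditions, chosen to match the proportions reported for human
#' cortex (1-4% ErgHi, 1-8% ErgLo, and single-nucleus survey estimates for
#' the other classes).
#'
#' @return Named numeric vector summing to 1.
#' @export
default_mixture <- function() {
  c(endothelial = 0.02, neuron = 0.30, microglia = 0.05,
    astrocyte = 0.20, oligodendrocyte = 0.15, OPC = 0.05, other = 0.23)
}

#' Simulation configuration
#'
#' One object holds every tunable parameter of the synthetic cohort: genome
#' and marker-panel size, flow-event count, sequencing depth and read-class
#' mixture, fixation mode, qPCR noise, and the seed that fully determines
#' all outputs.
#'
#' @param n_genes Number of simulated genes.
#' @param n_marker_genes_per_type Marker genes per cell type.  Feasibility
#'   requires `n_genes >= n_types * n_marker_genes_per_type`.
#' @param n_events Number of flow-cytometry events to simulate.
#' @param read_depth Total aligned records per sequenced sample (before the
#'   unfixed recovery penalty).  Desk-scale stand-in for the 100M-read
#'   libraries of a real experiment; all downstream statistics are
#'   depth-normalised.
#' @param dna_contamination_fraction Proportion of records that are
#'   intergenic genomic-DNA reads (junctionless, outside gene bodies).
#' @param intronic_read_fraction Of gene-derived records, the proportion
#'   that are junctionless intronic reads (nascent-transcript signal).
#' @param fixation `"fixed"` (PFA cross-linked, full RNA recovery) or
#'   `"unfixed"` (RNA leak during sorting; total reads are multiplied by
#'   `rna_recovery_factor_unfixed`).
#' @param rna_recovery_factor_unfixed Scalar in (0, 1].
#' @param marker_exclusivity Share of a marker gene's total abundance
#'   carried by its own cell type (>= 0.9 by the generator contract).
#' @param read_length Simulated read length in bp.
#' @param ct_reference qPCR cycle threshold of a transcript at unit
#'   abundance.
#' @param qpcr_noise_sd Gaussian CT noise, in cycles.
#' @param qpcr_replicates Wells per (sample, gene).
#' @param seed Integer seed; identical configs give byte-identical outputs.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       n_marker_genes_per_type = 50L,
                       n_events = 50000L,
                       read_depth = 100000L,
                       dna_contamination_fraction = 0.25,
                       intronic_read_fraction = 0.5,
                       fixation = c("fixed", "unfixed"),
                       rna_recovery_factor_unfixed = 0.1,
                       marker_exclusivity = 0.95,
                       read_length = 150L,
                       ct_reference = 30,
                       qpcr_noise_sd = 0.15,
                       qpcr_replicates = 3L,
                       seed = 1L) {
  fixation <- match.arg(fixation)
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("`%s` must be a single number in [0, 1]", nm), call. = FALSE)
  }
  chk_count <- function(x, nm, min = 0L) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
      stop(sprintf("`%s` must be a single integer >= %d", nm, min), call. = FALSE)
  }
  chk_count(n_genes, "n_genes", 1L)
  chk_count(n_marker_genes_per_type, "n_marker_genes_per_type", 1L)
  chk_count(n_events, "n_events", 0L)
  chk_count(read_depth, "read_depth", 0L)
  chk_count(qpcr_replicates, "qpcr_replicates", 1L)
  chk_count(read_length, "read_length", 20L)
  chk_frac(dna_contamination_fraction, "dna_contamination_fraction")
  chk_frac(intronic_read_fraction, "intronic_read_fraction")
  chk_frac(marker_exclusivity, "marker_exclusivity")
  if (marker_exclusivity <= 0)
    stop("`marker_exclusivity` must be positive", call. = FALSE)
  if (!is.numeric(rna_recovery_factor_unfixed) ||
      rna_recovery_factor_unfixed <= 0 || rna_recovery_factor_unfixed > 1)
    stop("`rna_recovery_factor_unfixed` must be in (0, 1]", call. = FALSE)
  if (!is.numeric(qpcr_noise_sd) || qpcr_noise_sd < 0)
    stop("`qpcr_noise_sd` must be >= 0", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != floor(seed) || abs(seed) >= .Machine$integer.max)
    stop("`seed` must be a single integer below 2^31", call. = FALSE)

  structure(list(
    n_genes = as.integer(n_genes),
    n_marker_genes_per_type = as.integer(n_marker_genes_per_type),
    n_events = as.integer(n_events),
    read_depth = as.integer(read_depth),
    dna_contamination_fraction = dna_contamination_fraction,
    intronic_read_fraction = intronic_read_fraction,
    fixation = fixation,
    rna_recovery_factor_unfixed = rna_recovery_factor_unfixed,
    marker_exclusivity = marker_exclusivity,
    read_length = as.integer(read_length),
    ct_reference = ct_reference,
    qpcr_noise_sd = qpcr_noise_sd,
    qpcr_replicates = as.integer(qpcr_replicates),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
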