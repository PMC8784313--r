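# Independent oracles and small fixtures shared across the suite.
# Everything here is deliberately naive (text-level filters, brute-force
# scans, closed-form mixture algebra) so it checks the package from the
# outside rather than re-using its code paths.

# --- random SAM material ----------------------------------------------------

random_cigars <- function(n, p_unmapped = 0.1) {
  ops <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
  vapply(seq_len(n), function(i) {
    if (runif(1) < p_unmapped) return("*")
    k <- sample(1:6, 1)
    paste0(sample(1:500, k, replace = TRUE),
           sample(ops, k, replace = TRUE), collapse = "")
  }, "")
}

random_sam_lines <- function(n) {
  cig <- random_cigars(n)
  flag <- ifelse(cig == "*", 4L, sample(c(0L, 16L), n, replace = TRUE))
  sprintf("r%05d\t%d\tchr1\t%d\t255\t%s\t*\t0\t0\t*\t*",
          seq_len(n), flag, sample.int(1000000L, n, replace = TRUE), cig)
}

# Text-level equivalent of: awk '$6 ~ /N/ || $1 ~ /^@/'
oracle_text_filter <- function(lines) {
  keep <- startsWith(lines, "@")
  aln <- which(!keep)
  if (length(aln)) {
    col6 <- vapply(strsplit(lines[aln], "\t", fixed = TRUE), `[[`, "", 6L)
    keep[aln] <- grepl("N", col6, fixed = TRUE)
  }
  lines[keep]
}

# --- brute-force gene containment ------------------------------------------

brute_assign <- function(spans, genes) {
  out <- rep(NA_character_, nrow(spans))
  for (i in seq_len(nrow(spans))) {
    hit <- which(genes$chrom == spans$chrom[i] &
                   genes$start <= spans$start[i] &
                   genes$end >= spans$end[i])
    if (length(hit) == 1L) out[i] <- genes$gene_id[hit]
  }
  out
}

# --- closed-form mixture algebra for the enrichment analysis ---------------
# Marker genes carry exclusivity q of their 10 abundance units in their own
# type, (1-q)*10/(K-1) in each other type; a sample with own-type fraction f
# therefore expresses the marker at w(f) = f*10*q + (1-f)*10*(1-q)/(K-1).
# Because each cell type's total output is identical, per-sample TPM
# normalisation cancels and the expected log2 enrichment of a type-t marker
# between two compositions is log2(w(f_sorted,t) / w(f_unsorted,t)).

marker_abundance <- function(frac_own, q, K = 7) {
  frac_own * 10 * q + (1 - frac_own) * 10 * (1 - q) / (K - 1)
}

comp_fraction <- function(comp, type) {
  f <- comp / sum(comp)
  if (type %in% names(f)) unname(f[[type]]) else 0
}

analytic_panel_log2 <- function(sorted_comp, unsorted_comp, q, types, K = 7) {
  vapply(types, function(t)
    log2(marker_abundance(comp_fraction(sorted_comp, t), q, K) /
           marker_abundance(comp_fraction(unsorted_comp, t), q, K)), 0)
}

analytic_relative_enrichment <- function(sorted_comp, unsorted_comp, q,
                                         panel_sizes, target = "endothelial",
                                         K = 7) {
  vals <- analytic_panel_log2(sorted_comp, unsorted_comp, q,
                              names(panel_sizes), K)
  pooled <- rep(vals[setdiff(names(panel_sizes), target)],
                panel_sizes[setdiff(names(panel_sizes), target)])
  unname(vals[[target]] - median(pooled))
}

# Sorted-sample composition at a given purity, impurity split in proportion
# to the non-target mixture fractions.
purity_composition <- function(purity, mixture, target = "endothelial",
                               n = 1000) {
  rest <- mixture[setdiff(names(mixture), target)]
  comp <- c(purity, (1 - purity) * rest / sum(rest))
  names(comp)[1] <- target
  comp * n
}

# Compositions engineered from the annotation's own abundance values so the
# composition-weighted abundance of a target takes an exact desired ratio k
# between two samples (endothelial marker diluted into a neuron background).
ratio_compositions <- function(ann, gene, k) {
  hi <- ann$expr[gene, "endothelial"]
  lo <- ann$expr[gene, "neuron"]
  phi <- (hi / k - lo) / (hi - lo)   # w(phi) = hi/k
  list(sorted = c(endothelial = 1),
       unsorted = c(endothelial = phi, neuron = 1 - phi))
}

# --- compact simulation helpers --------------------------------------------

small_config <- function(seed = 1L, n_genes = 200L,
                         n_marker_genes_per_type = 10L, n_events = 5000L,
                         read_depth = 20000L, ...) {
  sim_config(n_genes = n_genes,
             n_marker_genes_per_type = n_marker_genes_per_type,
             n_events = n_events, read_depth = read_depth, seed = seed, ...)
}

# Simulate, junction-filter (in memory) and TPM-quantify one pair of
# sorted/unsorted samples; returns the sorted-vs-unsorted enrichment table.
simulate_enrichment <- function(sorted_comp, unsorted_comp, ann, config,
                                pseudocount = 0.5, streams = c(1L, 2L)) {
  quant <- function(comp, label, stream) {
    rd <- simulate_reads(comp, ann, config, stream = stream, sample_name = label)
    kept <- filter_records(rd$records)$records
    count_table(kept, ann, sample_label = label)
  }
  counts <- bind_expr_tables(list(quant(sorted_comp, "sorted", streams[1]),
                                  quant(unsorted_comp, "unsorted", streams[2])))
  tpm <- to_tpm(counts, ann)
  gene_enrichment(expr_row(tpm, "sorted"), expr_row(tpm, "unsorted"),
                  pseudocount = pseudocount)
}
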