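enr_of <- function(x, y, eps = 0, ...) {
  gene_enrichment(setNames(x, paste0("g", seq_along(x))),
                  setNames(y, paste0("g", seq_along(y))),
                  pseudocount = eps, ...)
}

test_that("log2 ratio identities and zero handling", {
  expect_equal(enr_of(8, 1)$log2_enrichment, 3)
  expect_equal(enr_of(5, 5)$log2_enrichment, 0)
  # antisymmetry
  x <- c(3, 0.5, 10, 7); y <- c(1, 2, 10, 0.1)
  expect_equal(enr_of(x, y)$log2_enrichment, -enr_of(y, x)$log2_enrichment)
  # eps = 0 with zero denominator: flagged non-finite, excluded from medians
  e <- enr_of(c(4, 4), c(0, 1))
  expect_false(e$finite[1])
  ps <- panel_summary(e, list(p = c("g1", "g2"), q = "g2"), target = "p")
  expect_identical(ps$per_panel$n[ps$per_panel$panel == "p"], 1L)
  # empty intersection errors
  expect_error(gene_enrichment(c(a = 1), c(b = 1)), "empty gene intersection")
})

test_that("mixed units warn and are rescaled to a scale-free ratio", {
  x <- setNames(c(10, 20, 30), c("g1", "g2", "g3")); attr(x, "unit") <- "TPM"
  y <- setNames(c(1, 2, 3) * 1000, c("g1", "g2", "g3")); attr(y, "unit") <- "FPKM"
  expect_warning(e <- gene_enrichment(x, y, pseudocount = 0), "mixed units")
  expect_equal(e$log2_enrichment, c(0, 0, 0))  # same shape, scale removed
  e2 <- suppressWarnings(gene_enrichment(x, y * 17, pseudocount = 0))
  expect_equal(e2$log2_enrichment, e$log2_enrichment)
})

test_that("pseudocount monotonically shrinks |log2| without sign flips", {
  withr::local_seed(60L)
  x <- runif(50, 0, 20); y <- runif(50, 0, 20)
  prev <- abs(enr_of(x, y, eps = 0)$log2_enrichment)
  sign0 <- sign(enr_of(x, y, eps = 0)$log2_enrichment)
  for (eps in c(0.1, 0.5, 2, 10)) {
    l2 <- enr_of(x, y, eps = eps)$log2_enrichment
    cur <- abs(l2)
    expect_true(all(cur <= prev + 1e-12))
    expect_true(all(sign(l2) == sign0 | l2 == 0))
    prev <- cur
  }
})

test_that("panel summary medians and relative enrichment", {
  e <- enr_of(c(8, 8, 8, 1, 1, 1), c(1, 1, 1, 1, 1, 1))
  panels <- list(endothelial = c("g1", "g2", "g3"), neuron = c("g4", "g5", "g6"))
  ps <- panel_summary(e, panels)
  expect_equal(ps$relative_enrichment, 3)
  expect_equal(ps$per_panel$median_log2, c(3, 0))

  # identical distributions across panels -> relative enrichment 0
  e2 <- enr_of(rep(2, 6), rep(1, 6))
  expect_equal(panel_summary(e2, panels)$relative_enrichment, 0)

  # empty panel flagged and excluded
  panels3 <- c(panels, list(microglia = "absent_gene"))
  ps3 <- panel_summary(e, panels3)
  expect_true(ps3$per_panel$excluded[ps3$per_panel$panel == "microglia"])
  expect_equal(ps3$relative_enrichment, 3)

  # median-of-medians alternative
  e4 <- enr_of(c(8, 8, 8, 1, 1, 2, 2, 2), rep(1, 8))
  p4 <- list(endothelial = paste0("g", 1:3), neuron = paste0("g", 4:5),
             astrocyte = paste0("g", 6:8))
  pooled <- panel_summary(e4, p4)$relative_enrichment
  mom <- panel_summary(e4, p4, other = "median_of_medians")$relative_enrichment
  expect_equal(pooled, 3 - median(c(0, 0, 1, 1, 1)))
  expect_equal(mom, 3 - median(c(0, 1)))
  expect_error(panel_summary(e4, p4, target = "OPC"), "not among panels")
})

test_that("marker refinement: thresholds, boundaries and duplicates", {
  ref <- enr_of(c(8, 2, 1, 4), c(1, 1, 1, 1))  # log2: 3, 1, 0, 2
  panels <- list(endothelial = c("g1", "g2", "g3"), neuron = c("g4"))
  out <- refine_markers(panels, ref, min_log2 = 1)
  # g2 sits exactly at the threshold: retained (inclusive)
  expect_setequal(out$panels$endothelial, c("g1", "g2"))
  expect_identical(out$removed$gene_id, "g3")

  # min_log2 = -Inf: only cross-panel duplicates removed
  dup <- list(endothelial = c("g1", "g2"), neuron = c("g2", "g4"))
  out2 <- refine_markers(dup, ref, min_log2 = -Inf)
  expect_identical(out2$panels$endothelial, "g1")
  expect_identical(out2$panels$neuron, "g4")
  expect_true(all(out2$removed$reason == "cross_panel_duplicate"))

  # a gene missing from a reference fails a finite threshold
  out3 <- refine_markers(list(endothelial = c("g1", "zz")), ref, min_log2 = 1)
  expect_identical(out3$panels$endothelial, "g1")
  # all genes removed -> warning, empty panel permitted
  expect_warning(refine_markers(list(endothelial = "g3"), ref, min_log2 = 1),
                 "removed every gene")
})

test_that("planted non-specific markers are removed against references", {
  cfg <- sim_config(seed = 61L)
  ann <- make_annotation(cfg)
  shared <- setdiff(rownames(ann$expr), unlist(ann$markers))
  panels <- ann$markers[setdiff(names(ann$markers), "other")]
  planted <- shared[1:5]
  panels$endothelial <- c(panels$endothelial[1:45], planted)

  # reference enrichment from Poisson-sampled gold-standard tables
  withr::local_seed(61L)
  depth <- function(w) stats::rpois(length(w), w / sum(w) * 2e5)
  mk_ref <- function() {
    endo <- setNames(depth(ann$expr[, "endothelial"]), rownames(ann$expr))
    bulk <- setNames(depth(as.numeric(ann$expr %*% default_mixture())),
                     rownames(ann$expr))
    gene_enrichment(endo, bulk, pseudocount = 0.5)
  }
  out <- refine_markers(panels, list(mk_ref(), mk_ref()), min_log2 = 1)
  expect_gte(mean(planted %in% out$removed$gene_id), 0.95)
  expect_lte(mean(panels$endothelial[1:45] %in% out$removed$gene_id), 0.05)
})

test_that("enrichment correlation endpoints and replicate consistency", {
  e <- enr_of(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(enrichment_correlation(e, e)$pearson, 1)
  expect_equal(enrichment_correlation(e, e)$spearman, 1)
  neg <- e; neg$log2_enrichment <- -neg$log2_enrichment
  expect_equal(enrichment_correlation(e, neg)$pearson, -1)
  e2 <- enr_of(c(1, 2), c(1, 1))
  expect_error(enrichment_correlation(e2, e2), ">= 3")

  # Two independent sorts of the same composition rank genes consistently.
  # Within a panel every marker has the same expected enrichment, so
  # within-panel ranks are pure sampling noise at any depth and replicate
  # rank correlation is bounded by the between-panel variance share (~0.94
  # for these panel sizes); reaching the 0.8 mark needs depth well above
  # the desk-scale default.  1M reads is still 100x below the real
  # libraries the analysis targets.
  cfg <- sim_config(read_depth = 1000000L, seed = 62L)
  ann <- make_annotation(cfg)
  mixture <- default_mixture()
  sorted <- purity_composition(0.95, mixture)
  unsorted <- mixture * 1000
  eA <- simulate_enrichment(sorted, unsorted, ann, cfg, streams = c(1L, 2L))
  eB <- simulate_enrichment(sorted, unsorted, ann, cfg, streams = c(3L, 4L))
  panel_genes <- unlist(ann$markers[setdiff(names(ann$markers), "other")])
  cc <- enrichment_correlation(eA[eA$gene_id %in% panel_genes, ],
                               eB[eB$gene_id %in% panel_genes, ])
  expect_gt(cc$spearman, 0.8)
})

test_that("panel medians match the closed-form mixture expectation", {
  cfg <- sim_config(seed = 63L)
  ann <- make_annotation(cfg)
  mixture <- default_mixture()
  sorted <- purity_composition(0.95, mixture)
  unsorted <- mixture * 1000
  enr <- simulate_enrichment(sorted, unsorted, ann, cfg)
  panels <- ann$markers[setdiff(names(ann$markers), "other")]
  ps <- panel_summary(enr, panels)

  want <- analytic_panel_log2(sorted, unsorted, cfg$marker_exclusivity,
                              names(panels))
  got <- setNames(ps$per_panel$median_log2, ps$per_panel$panel)
  expect_equal(unname(got[names(want)]), unname(want), tolerance = 0.35)

  want_rel <- analytic_relative_enrichment(sorted, unsorted,
                                           cfg$marker_exclusivity,
                                           lengths(panels))
  expect_equal(ps$relative_enrichment, want_rel, tolerance = 0.5)
})

test_that("sample QC applies both outlier rules without dropping data", {
  vals <- matrix(c(70, 930, 2000, 500), nrow = 2, byrow = TRUE,
                 dimnames = list(c("clean", "dirty"), c("PTPRC", "CLDN5")))
  # rows scaled to TPM-like sums for the rule; unit label is what matters
  tpm <- structure(vals, unit = "TPM", class = c("expr_table", "matrix", "array"))
  qc <- sample_qc(c(clean = 0.02, dirty = 0), tpm)
  expect_true(qc$pass[qc$sample == "clean"])
  expect_false(qc$pass[qc$sample == "dirty"])
  expect_match(qc$reasons[qc$sample == "dirty"], "A:")
  expect_match(qc$reasons[qc$sample == "dirty"], "B:")
  expect_identical(nrow(qc), 2L)  # flagged, not removed

  tpm2 <- tpm; colnames(tpm2) <- c("OTHER", "CLDN5")
  expect_warning(sample_qc(c(clean = 0.02), tpm2), "rule B skipped")
})

test_that("a microglia-contaminated sort is flagged by the PTPRC rule", {
  cfg <- sim_config(seed = 64L)
  ann <- make_annotation(cfg)
  quant <- function(comp, label, stream) {
    rd <- simulate_reads(comp, ann, cfg, stream = stream, sample_name = label)
    count_table(filter_records(rd$records)$records, ann, sample_label = label)
  }
  counts <- bind_expr_tables(list(
    quant(c(endothelial = 950, microglia = 10, neuron = 20, other = 20),
          "clean", 1),
    quant(c(endothelial = 700, microglia = 300), "contaminated", 2)))
  tpm <- to_tpm(counts, ann)
  qc <- sample_qc(c(clean = 0.02, contaminated = 0.02), tpm)
  expect_true(qc$pass[qc$sample == "clean"])
  expect_false(qc$pass[qc$sample == "contaminated"])
  expect_match(qc$reasons[qc$sample == "contaminated"], "PTPRC")
})
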