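# minimal hand-built annotation for closed-form checks
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1", strand = c("+", "-"),
    start = c(0L, 10000L), end = c(5000L, 16000L), n_exons = 2L,
    exonic_length = c(1000L, 2000L))
  structure(list(genes = genes, exons = NULL, introns = NULL, junctions = NULL,
                 expr = NULL, markers = NULL, cell_types = NULL,
                 chrom_lengths = c(chr1 = 20000L), intergenic = NULL,
                 seed = NA_integer_),
            class = "nucsort_annotation")
}

toy_record <- function(pos, cigar, qname = "r1", flag = 0L, chrom = "chr1") {
  data.frame(qname = qname, flag = flag, rname = chrom, pos = pos,
             mapq = 255L, cigar = cigar, rnext = "*", pnext = 0L, tlen = 0L,
             seq = "*", qual = "*", tags = "")
}

test_that("junction containment drives gene assignment", {
  ann <- toy_annotation()
  # junction [150, 1150) inside gA's span
  r1 <- toy_record(101L, "50M1000N50M")
  expect_identical(assign_reads(r1, ann), "gA")
  # junction reaching past gA's end -> unassigned
  r2 <- toy_record(4901L, "50M1000N50M")
  expect_identical(assign_reads(r2, ann), NA_character_)
  # junctionless read -> NA
  expect_identical(assign_reads(toy_record(101L, "150M"), ann), NA_character_)

  # stranded mode: gB is on '-', a '+' read inside gB fails, a '-' read passes
  r3 <- toy_record(10101L, "50M1000N50M")
  expect_identical(assign_reads(r3, ann, stranded = TRUE), NA_character_)
  r4 <- toy_record(10101L, "50M1000N50M", flag = 16L)
  expect_identical(assign_reads(r4, ann, stranded = TRUE), "gB")
  expect_identical(assign_reads(r4, ann, stranded = FALSE), "gB")
})

test_that("overlapping genes trigger ambiguity, never double counting", {
  ann <- toy_annotation()
  ann$genes <- rbind(ann$genes,
                     data.frame(gene_id = "gA2", chrom = "chr1", strand = "+",
                                start = 0L, end = 5000L, n_exons = 2L,
                                exonic_length = 1000L))
  r <- toy_record(101L, "50M1000N50M")
  expect_identical(assign_reads(r, ann), NA_character_)
  ct <- count_table(r, ann)
  expect_identical(sum(ct), 0L)
  expect_identical(unname(attr(ct, "unassigned")), 1L)
})

test_that("assignment agrees with the brute-force containment oracle", {
  cfg <- sim_config(n_genes = 300L, n_marker_genes_per_type = 15L,
                    read_depth = 10000L, dna_contamination_fraction = 0,
                    intronic_read_fraction = 0, seed = 51L)
  ann <- make_annotation(cfg)
  rd <- simulate_reads(c(neuron = 500, endothelial = 500), ann, cfg)
  rec <- rd$records
  got <- assign_reads(rec, ann)
  spans <- junction_spans(rec)
  want <- rep(NA_character_, nrow(rec))
  want[spans$row] <- brute_assign(spans, ann$genes)
  expect_identical(got, want)
  # >= 99% of reads land on their generating gene
  truth <- sub(".*XG:Z:([^\t]+).*", "\\1", rec$tags)
  expect_gte(mean(got == truth, na.rm = TRUE), 0.99)
  expect_gte(mean(!is.na(got)), 0.99)
})

test_that("count conservation and a constructed 30/70 split", {
  ann <- toy_annotation()
  rec <- rbind(
    do.call(rbind, replicate(30, toy_record(101L, "50M1000N50M"), simplify = FALSE)),
    do.call(rbind, replicate(70, toy_record(10101L, "50M1000N50M"), simplify = FALSE)),
    toy_record(101L, "150M"))  # junctionless -> unassigned
  ct <- count_table(rec, ann, sample_label = "s")
  expect_identical(unname(unclass(ct)["s", ]), c(30L, 70L))
  expect_identical(sum(ct) + unname(attr(ct, "unassigned")), nrow(rec))

  empty <- count_table(rec[0, ], ann, sample_label = "none")
  expect_true(all(unclass(empty) == 0L))
})

test_that("TPM closed forms, normalisation and scale invariance", {
  ann <- toy_annotation()
  ct <- structure(
    matrix(c(100L, 100L), nrow = 1, dimnames = list("s", c("gA", "gB"))),
    unit = "count", unassigned = c(s = 0L),
    class = c("expr_table", "matrix", "array"))
  tpm <- to_tpm(ct, ann)
  # equal counts, gB twice as long -> rates 2:1 in favour of the shorter gene
  expect_equal(unclass(tpm)["s", "gA"] / unclass(tpm)["s", "gB"], 2)
  expect_equal(sum(unclass(tpm)["s", ]), 1e6, tolerance = 1e-6)

  # equal counts, equal lengths -> (5e5, 5e5)
  ann2 <- ann; ann2$genes$exonic_length <- c(1000L, 1000L)
  expect_equal(unname(unclass(to_tpm(ct, ann2))["s", ]), c(5e5, 5e5))

  # scale invariance: counts x 7 changes nothing (to 1e-9 relative)
  ct7 <- ct; ct7[] <- ct[] * 7L
  expect_equal(unclass(to_tpm(ct7, ann)), unclass(tpm), tolerance = 1e-9)

  # zero row flagged, not NaN; zero exonic length is an error
  ct0 <- ct; ct0[] <- 0L
  tpm0 <- to_tpm(ct0, ann)
  expect_true(all(unclass(tpm0) == 0))
  expect_identical(attr(tpm0, "zero_samples"), "s")
  ann_bad <- ann; ann_bad$genes$exonic_length[1] <- 0L
  expect_error(to_tpm(ct, ann_bad), "zero exonic length")

  # RPM has no length term
  rpm <- to_rpm(ct)
  expect_equal(unname(unclass(rpm)["s", ]), c(5e5, 5e5))
})

test_that("detected_genes counts thresholded genes per sample", {
  vals <- matrix(c(0L, 1L, 5L, 0L, 0L, 0L), nrow = 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("g1", "g2", "g3")))
  ct <- structure(vals, unit = "count", class = c("expr_table", "matrix", "array"))
  expect_identical(detected_genes(ct), c(a = 2L, b = 0L))
  expect_identical(detected_genes(ct, min_count = 5), c(a = 1L, b = 0L))
})

test_that("a deep unsorted sample detects nearly all expressed genes", {
  cfg <- sim_config(seed = 52L)  # default 1000 genes / 100k reads
  ann <- make_annotation(cfg)
  comp <- round(default_mixture() * 10000)
  rd <- simulate_reads(comp, ann, cfg)
  kept <- filter_records(rd$records)$records
  ct <- count_table(kept, ann, "unsorted")
  expect_gte(detected_genes(ct) / nrow(ann$genes), 0.95)
})

test_that("doubling depth doubles counts but leaves TPM stable", {
  base <- sim_config(n_genes = 400L, n_marker_genes_per_type = 20L,
                     read_depth = 30000L, seed = 53L)
  deep <- sim_config(n_genes = 400L, n_marker_genes_per_type = 20L,
                     read_depth = 60000L, seed = 54L)
  ann <- make_annotation(base)
  comp <- round(default_mixture() * 1000)
  quant <- function(cfg, stream) {
    rd <- simulate_reads(comp, ann, cfg, stream = stream)
    kept <- filter_records(rd$records)$records
    count_table(kept, ann, sprintf("d%d", cfg$read_depth))
  }
  ct1 <- quant(base, 1); ct2 <- quant(deep, 2)
  r <- sum(ct2) / sum(ct1)
  expect_lt(abs(r - 2), 4 * sqrt(1 / sum(ct1) + 1 / sum(ct2)) * 2)
  t1 <- unclass(to_tpm(ct1, ann))[1, ]
  t2 <- unclass(to_tpm(ct2, ann))[1, ]
  well <- unclass(ct1)[1, ] >= 20 & unclass(ct2)[1, ] >= 20
  expect_lt(abs(median(log2(t2[well] / t1[well]))), 0.1)
})
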