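#' Default run configuration
#'
#' A fully serialisable description of one desk-scale experiment: simulate a
#' whole-brain nuclear suspension, gate and sort ErgHi and NeuN populations,
#' sequence sorted and unsorted samples, junction-filter, quantify, score
#' marker-panel enrichment, run the qPCR arm, and QC the samples.  A run is
#' reproducible from its config alone.
#'
#' @param seed Integer master seed.
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    sim = list(n_genes = 1000L, n_marker_genes_per_type = 50L,
               n_events = 50000L, read_depth = 100000L,
               dna_contamination_fraction = 0.25,
               intronic_read_fraction = 0.5,
               fixation = "fixed", rna_recovery_factor_unfixed = 0.1,
               marker_exclusivity = 0.95, read_length = 150L,
               ct_reference = 30, qpcr_noise_sd = 0.15, qpcr_replicates = 3L),
    mixture = as.list(default_mixture()),
    gates = list(dapi_min = 10^2.5, ssc_max = 10^2.5,
                 erg_hi_min = 2.5, erg_lo_min = 1.5, erg_lo_max = 2.5,
                 neun_min = 2.0),
    sort = list(populations = c("ErgHi", "NeuN"), n_target = 1000L),
    quant = list(stranded = FALSE, min_count = 1L),
    enrichment = list(pseudocount = 0.5, target = "endothelial",
                      other = "pooled", min_log2 = 1),
    qc = list(erg_fraction_min = 0.005, contamination_gene = "PTPRC",
              contamination_tpm_max = 500),
    qpcr = list(targets = c("CLDN5", "MAP2"), housekeeping = "UBC")
  ), class = "run_config")
}

#' @rdname default_run_config
#' @param path JSON file.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_run_config(seed = if (!is.null(cfg$seed)) cfg$seed else 1L)
  for (block in setdiff(names(base), "seed")) {
    if (!is.null(cfg[[block]])) {
      if (is.list(base[[block]]))
        base[[block]][names(cfg[[block]])] <- cfg[[block]]
      else base[[block]] <- cfg[[block]]
    }
  }
  base
}

#' @rdname default_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes simulate -> gate -> sort -> reads -> filter -> quantify ->
#' enrich -> qPCR -> QC and writes every intermediate table under `out_dir`:
#' annotation (BED + abundance + panels), events and gating fractions,
#' raw and junction-filtered SAM per sequenced sample, count/TPM tables,
#' per-sample enrichment and panel summaries, qPCR CTs and folds, QC flags,
#' and a machine-readable `manifest.json` reconciling record counts at every
#' stage.  Identical config and seed give bit-identical outputs.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage log lines.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(seed = config$seed, stages = list(), warnings = character(0))

  cfg_path <- file.path(out_dir, "config.json")
  write_run_config(config, cfg_path)
  manifest$config <- unclass(config)
  manifest$config_hash <- unname(md5sum(cfg_path))

  sc <- with_stage("simulate", do.call(sim_config, c(config$sim, list(seed = config$seed))))

  ann <- with_stage("simulate", make_annotation(sc))
  write_annotation_bed(ann, file.path(out_dir, "annotation.bed"))
  write_expression_tsv(ann, file.path(out_dir, "abundance.tsv"))
  write_marker_panels(ann$markers, file.path(out_dir, "panels.tsv"))
  log("stage simulate\tgenes\t%d", nrow(ann$genes))

  mixture <- unlist(config$mixture)
  profiles <- with_stage("simulate", cell_type_profiles(mixture))
  events <- with_stage("simulate", simulate_events(profiles, sc))
  write_events_tsv(events, file.path(out_dir, "events.tsv"))
  manifest$stages$events <- list(n_events = nrow(events))

  gates <- with_stage("gate", do.call(gate_set, config$gates))
  gated <- with_stage("gate", apply_gates(events, gates))
  write_tsv(gated$fractions, file.path(out_dir, "fractions.tsv"))
  manifest$stages$gating <- list(
    parent_n = gated$parent_n,
    counts = setNames(as.list(gated$fractions$count), gated$fractions$population))
  log("stage gate\tparent\t%d", gated$parent_n)

  # compositions: the unsorted sample is the parent population itself
  parent_ev <- gated$events[gated$events$label != "non-nucleus", ]
  compositions <- list(unsorted = vapply(split(parent_ev$true_class,
                                               parent_ev$true_class), length, 0L))
  sorts <- list()
  for (pop in config$sort$populations) {
    srt <- with_stage("sort", in_silico_sort(gated, pop, config$sort$n_target))
    sorts[[pop]] <- srt
    compositions[[pop]] <- srt$composition
    manifest$stages$sort[[pop]] <- list(
      n_selected = srt$n_selected, purity = srt$purity,
      shortfall = srt$shortfall,
      composition = as.list(srt$composition))
  }
  log("stage sort\tpopulations\t%s", paste(config$sort$populations, collapse = ","))

  counts_list <- list()
  all_filtered <- character(0)
  for (k in seq_along(compositions)) {
    s <- names(compositions)[k]
    reads <- with_stage("reads", simulate_reads(compositions[[s]], ann, sc,
                                                stream = k, sample_name = s))
    raw_path <- file.path(out_dir, sprintf("raw_%s.sam", s))
    write_sim_reads(reads, raw_path)
    flt_path <- file.path(out_dir, sprintf("filtered_%s.sam", s))
    flt <- with_stage("filter", filter_sam(raw_path, flt_path, quiet = quiet))
    stopifnot(flt$stats$n_kept + flt$stats$n_dropped == flt$stats$n_records)
    if (flt$stats$n_kept == 0L && flt$stats$n_records > 0L) {
      warning(sprintf("sample %s: all %d records removed by the junction filter",
                      s, flt$stats$n_records))
      all_filtered <- c(all_filtered, s)
    }
    sam <- read_sam(flt_path)
    ct <- with_stage("quant", count_table(sam$records, ann, sample_label = s,
                                          stranded = isTRUE(config$quant$stranded)))
    counts_list[[s]] <- ct
    manifest$stages$reads[[s]] <- list(
      simulated = reads$counts, kept = flt$stats$n_kept,
      dropped = flt$stats$n_dropped,
      assigned = unname(sum(unclass(ct))),
      unassigned = unname(attr(ct, "unassigned")))
    log("stage reads\t%s\ttotal\t%d\tkept\t%d", s, reads$counts$total,
        flt$stats$n_kept)
  }
  if (length(all_filtered))
    manifest$warnings <- c(manifest$warnings,
                           sprintf("all reads filtered in sample(s): %s",
                                   paste(all_filtered, collapse = ", ")))

  counts <- bind_expr_tables(counts_list)
  tpm <- with_stage("quant", to_tpm(counts, ann))
  write_expr_table(counts, file.path(out_dir, "counts.tsv"))
  write_expr_table(tpm, file.path(out_dir, "tpm.tsv"))
  manifest$stages$quant <- list(
    detected_genes = as.list(detected_genes(counts, config$quant$min_count)))

  # enrichment of each sorted population against the unsorted sample
  panel_rows <- list()
  target_map <- c(ErgHi = "endothelial", ErgLo = "microglia", NeuN = "neuron")
  summaries <- list()
  for (pop in config$sort$populations) {
    enr <- with_stage("enrich", gene_enrichment(
      expr_row(tpm, pop), expr_row(tpm, "unsorted"),
      pseudocount = config$enrichment$pseudocount,
      comparison_label = sprintf("%s-vs-unsorted", pop)))
    write_tsv(enr, file.path(out_dir, sprintf("enrichment_%s.tsv", pop)))
    tgt <- if (pop %in% names(target_map)) target_map[[pop]] else config$enrichment$target
    ps <- with_stage("enrich", panel_summary(enr, ann$markers, target = tgt,
                                             other = config$enrichment$other))
    summaries[[pop]] <- ps
    pr <- ps$per_panel
    pr$sample <- pop
    pr$relative_enrichment_of_target <- ps$relative_enrichment
    pr$target <- tgt
    panel_rows[[pop]] <- pr
    manifest$stages$enrichment[[pop]] <- list(
      target = tgt, relative_enrichment = ps$relative_enrichment)
  }
  write_tsv(do.call(rbind, panel_rows), file.path(out_dir, "panel_summary.tsv"))

  wells <- with_stage("qpcr", simulate_qpcr(
    compositions, config$qpcr$targets, config$qpcr$housekeeping, ann, sc))
  write_tsv(wells, file.path(out_dir, "qpcr_ct.tsv"))
  folds <- with_stage("qpcr", qpcr_fold_table(wells, config$qpcr$housekeeping,
                                              unsorted = "unsorted"))
  write_tsv(folds, file.path(out_dir, "qpcr_folds.tsv"))
  manifest$stages$qpcr <- list(
    folds = setNames(as.list(folds$fold_vs_unsorted),
                     paste(folds$sample, folds$gene, sep = ":")))

  erg_frac <- setNames(rep(NA_real_, nrow(tpm)), rownames(tpm))
  if ("ErgHi" %in% rownames(tpm) && !gated$parent_empty)
    erg_frac[["ErgHi"]] <-
      gated$fractions$fraction[gated$fractions$population == "ErgHi"]
  rules <- with_stage("qc", do.call(qc_rules, config$qc))
  qc <- with_stage("qc", sample_qc(erg_frac, tpm, rules))
  write_tsv(qc, file.path(out_dir, "qc.tsv"))
  manifest$stages$qc <- list(flagged = qc$sample[!qc$pass])

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("pipeline complete: %s", out_dir)
  invisible(manifest)
}
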