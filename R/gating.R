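#' Axis-aligned flow gates
#'
#' Rectangle gates on a DAPI+/SSC-low parent population and log10 Erg / NeuN
#' thresholds defining four mutually exclusive child populations (ErgHi,
#' ErgLo, NeuN, rest).  Lower bounds are inclusive, upper bounds exclusive.
#'
#' @param dapi_min Minimum raw DAPI intensity for a nucleus.
#' @param ssc_max Exclusive upper bound on raw side scatter.
#' @param erg_hi_min,erg_lo_min,erg_lo_max Thresholds on log10 Erg-AF647
#'   intensity; require `erg_lo_min < erg_lo_max <= erg_hi_min`.
#' @param neun_min Threshold on log10 NeuN-PE intensity.
#' @return Object of class `gate_set`.
#' @export
gate_set <- function(dapi_min = 10^2.5, ssc_max = 10^2.5,
                     erg_hi_min = 2.5, erg_lo_min = 1.5, erg_lo_max = 2.5,
                     neun_min = 2.0) {
  if (!(erg_lo_min < erg_lo_max && erg_lo_max <= erg_hi_min))
    stop("gates must satisfy erg_lo_min < erg_lo_max <= erg_hi_min")
  if (dapi_min <= 0 || ssc_max <= 0) stop("intensity thresholds must be positive")
  structure(list(dapi_min = dapi_min, ssc_max = ssc_max,
                 erg_hi_min = erg_hi_min, erg_lo_min = erg_lo_min,
                 erg_lo_max = erg_lo_max, neun_min = neun_min),
            class = "gate_set")
}

GATE_POPULATIONS <- c("ErgHi", "ErgLo", "NeuN", "rest")

#' Apply gates to an event table
#'
#' Every event receives exactly one label from \{ErgHi, ErgLo, NeuN, rest,
#' non-nucleus\}.  Events failing the DAPI+/SSC-low parent gate are
#' "non-nucleus"; within the parent gate, precedence is ErgHi, then NeuN,
#' then ErgLo (Erg/NeuN double positives go to ErgHi: Erg is the selection
#' marker of interest), then rest.  Population fractions are reported over
#' the parent population; their counts sum to the parent count exactly.
#'
#' @param events data.frame with columns dapi, ssc, erg_af647, neun_pe (and
#'   optionally true_class).
#' @param gates A [gate_set()].
#' @return Object of class `gate_result`: list with `events` (input plus a
#'   `label` column), `fractions` (population, count, fraction), `parent_n`,
#'   and `parent_empty` flag.  With an empty parent population fractions are
#'   `NA` and `parent_empty` is `TRUE` (never silent NaN).
#' @export
apply_gates <- function(events, gates = gate_set()) {
  stopifnot(inherits(gates, "gate_set"))
  need <- c("dapi", "ssc", "erg_af647", "neun_pe")
  if (!all(need %in% names(events)))
    stop("events must have columns: ", paste(need, collapse = ", "))
  n <- nrow(events)
  label <- rep("non-nucleus", n)
  parent <- events$dapi >= gates$dapi_min & events$ssc < gates$ssc_max
  if (n > 0L) {
    le <- log10(events$erg_af647)
    ln <- log10(events$neun_pe)
    hi <- parent & le >= gates$erg_hi_min
    nn <- parent & !hi & ln >= gates$neun_min
    lo <- parent & !hi & !nn & le >= gates$erg_lo_min & le < gates$erg_lo_max
    label[hi] <- "ErgHi"
    label[nn] <- "NeuN"
    label[lo] <- "ErgLo"
    label[parent & !hi & !nn & !lo] <- "rest"
  }
  parent_n <- sum(parent)
  counts <- vapply(GATE_POPULATIONS, function(p) sum(label == p), 0L)
  fractions <- data.frame(
    population = GATE_POPULATIONS,
    count = as.integer(counts),
    fraction = if (parent_n > 0L) as.numeric(counts) / parent_n else NA_real_,
    row.names = NULL)
  out <- events
  out$label <- factor(label, levels = c(GATE_POPULATIONS, "non-nucleus"))
  structure(list(events = out, fractions = fractions,
                 parent_n = parent_n, parent_empty = parent_n == 0L),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("gate_result: %d events, %d in DAPI+/SSC-low parent gate%s\n",
              nrow(x$events), x$parent_n,
              if (x$parent_empty) " [EMPTY PARENT - fractions undefined]" else ""))
  print(x$fractions)
  invisible(x)
}

# default mapping from gate label to the cell type the gate is meant to select
INTENDED_CLASS <- c(ErgHi = "endothelial", ErgLo = "microglia", NeuN = "neuron")

#' In-silico sort of gated events
#'
#' Selects up to `n_target` events carrying `label` (in event-stream order,
#' as a sorter would) and reports the composition by hidden true class plus
#' the purity with respect to the intended class.  The composition is the
#' input contract for [simulate_reads()].
#'
#' @param gated A [apply_gates()] result (or a data.frame with `label` and
#'   `true_class` columns).
#' @param label Gate population to sort (e.g. "ErgHi").
#' @param n_target Number of nuclei requested.
#' @param intended_class Cell type the gate selects; defaults to the ErgHi ->
#'   endothelial, ErgLo -> microglia, NeuN -> neuron mapping.
#' @return Object of class `sort_result`: list with `composition` (named
#'   true-class counts), `purity`, `n_selected`, `n_target`, `shortfall`
#'   flag, and the selected row `indices`.  A shortfall triggers a warning
#'   and returns all available events.
#' @export
in_silico_sort <- function(gated, label, n_target,
                           intended_class = INTENDED_CLASS[[label]]) {
  ev <- if (inherits(gated, "gate_result")) gated$events else gated
  if (!all(c("label", "true_class") %in% names(ev)))
    stop("in_silico_sort needs gated events with `label` and `true_class` columns")
  if (!is.numeric(n_target) || n_target < 1) stop("`n_target` must be >= 1")
  idx <- which(ev$label == label)
  shortfall <- length(idx) < n_target
  if (shortfall)
    warning(sprintf("only %d events with label %s available (requested %d)",
                    length(idx), label, n_target))
  sel <- idx[seq_len(min(length(idx), n_target))]
  tc <- ev$true_class[sel]
  composition <- vapply(split(tc, tc), length, 0L)
  structure(list(
    composition = composition,
    purity = if (length(sel)) mean(tc == intended_class) else NA_real_,
    intended_class = intended_class,
    n_selected = length(sel), n_target = as.integer(n_target),
    shortfall = shortfall, indices = sel
  ), class = "sort_result")
}

#' @export
print.sort_result <- function(x, ...) {
  cat(sprintf("sort_result: %d/%d nuclei selected (purity %.4f for %s)%s\n",
              x$n_selected, x$n_target, x$purity, x$intended_class,
              if (x$shortfall) " [SHORTFALL]" else ""))
  print(x$composition)
  invisible(x)
}
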