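#' Is an alignment splice-junction spanning?
#'
#' A read evidences a spliced RNA molecule (rather than genomic DNA) iff its
#' CIGAR contains at least one reference-skip (N) operation.  Unmapped
#' records (CIGAR `"*"`) are not junction spanning.  Vectorised; malformed
#' CIGAR strings raise an error naming the offending record.
#'
#' The implementation validates the CIGAR grammar and tests the projected
#' operation alphabet for N -- for valid CIGARs this coincides with the
#' text-level "column 6 contains the character N" rule, because N can only
#' occur as an operation code.
#'
#' @param cigar Character vector of CIGAR strings.
#' @param qname Optional record names used in error messages.
#' @return Logical vector.
#' @export
is_junction_spanning <- function(cigar, qname = NULL) {
  ok <- cigar_is_valid(cigar)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    id <- if (!is.null(qname)) qname[bad] else sprintf("#%d", bad)
    stop(sprintf("malformed CIGAR string '%s' in record %s", cigar[bad], id),
         call. = FALSE)
  }
  res <- rep(FALSE, length(cigar))
  mapped <- cigar != "*"
  # op alphabet = CIGAR with the length digits removed
  res[mapped] <- grepl("N", gsub("[0-9]", "", cigar[mapped]), fixed = TRUE)
  res
}

sam_is_secondary <- function(flag) bitwAnd(flag, 0x900L) != 0L

#' Filter a SAM stream down to junction-spanning reads
#'
#' The genomic-DNA background removal step: header lines pass through
#' byte-identical and in order; alignment records are kept iff
#' [is_junction_spanning()].  Secondary and supplementary alignments (flag
#' bits 0x100/0x800) are dropped before the junction test unless
#' `keep_secondary = TRUE`, to avoid double-counting junctions downstream.
#' Record order is preserved; `kept + dropped` equals the input alignment
#' count exactly.
#'
#' @param input Path to a SAM file, or a character vector of SAM lines.
#' @param output Path to write the filtered SAM; `NULL` returns the filtered
#'   lines in the result instead.
#' @param keep_secondary Keep secondary/supplementary alignments.
#' @param quiet Suppress the one-line count log.
#' @return Invisibly, a list with `stats` (n_header, n_records, n_kept,
#'   n_dropped, n_secondary_dropped) and, when `output` is `NULL`, `lines`.
#' @export
filter_sam <- function(input, output = NULL, keep_secondary = FALSE,
                       quiet = FALSE) {
  lines <- if (length(input) == 1L && !grepl("[\t\n]", input) && file.exists(input))
    readLines(input) else input
  is_hdr <- startsWith(lines, "@")
  aln <- lines[!is_hdr]
  keep_aln <- logical(length(aln))
  n_sec <- 0L
  if (length(aln) > 0L) {
    fields <- strsplit(aln, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 11L)) {
      bad <- which(nf < 11L)[1]
      stop(sprintf("truncated SAM record at line %d (%d fields, need 11)",
                   which(!is_hdr)[bad], nf[bad]), call. = FALSE)
    }
    flag <- as.integer(vapply(fields, `[[`, "", 2L))
    cig <- vapply(fields, `[[`, "", 6L)
    qn <- vapply(fields, `[[`, "", 1L)
    primary <- keep_secondary | !sam_is_secondary(flag)
    n_sec <- sum(!primary)
    keep_aln <- primary & is_junction_spanning(cig, qname = qn)
  }
  keep_line <- is_hdr
  keep_line[!is_hdr] <- keep_aln
  out_lines <- lines[keep_line]
  stats <- list(n_header = sum(is_hdr), n_records = length(aln),
                n_kept = sum(keep_aln), n_dropped = length(aln) - sum(keep_aln),
                n_secondary_dropped = n_sec)
  if (!quiet)
    message(sprintf("filter_sam\tread\t%d\tkept\t%d\tdropped\t%d",
                    stats$n_records, stats$n_kept, stats$n_dropped))
  if (!is.null(output)) {
    writeLines(out_lines, output)
    invisible(list(stats = stats, output = output))
  } else {
    invisible(list(stats = stats, lines = out_lines))
  }
}

#' @rdname filter_sam
#' @param records Alignment data.frame (see [read_sam()]).
#' @return `filter_records`: list with `records` (kept rows) and `stats`.
#' @export
filter_records <- function(records, keep_secondary = FALSE) {
  primary <- keep_secondary | !sam_is_secondary(records$flag)
  keep <- primary & is_junction_spanning(records$cigar, records$qname)
  list(records = records[keep, , drop = FALSE],
       stats = list(n_records = nrow(records), n_kept = sum(keep),
                    n_dropped = nrow(records) - sum(keep),
                    n_secondary_dropped = sum(!primary)))
}
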