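# CIGAR grammar: one or more <length><op> tokens, op in MIDNSHP=X; "*" for
# unmapped records.  These helpers are the package's native SAM layer -- the
# junction filter is defined on plain SAM text, so no binary BAM machinery is
# used anywhere.

CIGAR_REGEX <- "^([0-9]+[MIDNSHP=X])+$"
CIGAR_REF_OPS <- c("M", "D", "N", "=", "X")

cigar_is_valid <- function(cigar) {
  cigar == "*" | grepl(CIGAR_REGEX, cigar)
}

#' Parse a CIGAR string into operations
#'
#' @param cigar A single CIGAR string.
#' @return data.frame with `length` (integer) and `op` (character) columns;
#'   zero rows for `"*"`.
#' @export
cigar_ops <- function(cigar) {
  stopifnot(length(cigar) == 1L)
  if (cigar == "*")
    return(data.frame(length = integer(0), op = character(0)))
  if (!grepl(CIGAR_REGEX, cigar))
    stop(sprintf("malformed CIGAR string: '%s'", cigar), call. = FALSE)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  data.frame(length = as.integer(sub("[MIDNSHP=X]$", "", toks)),
             op = sub("^[0-9]+", "", toks))
}

#' Reference length consumed by a CIGAR
#'
#' Sum of lengths over ops in \{M, D, N, =, X\}; `NA` for `"*"`.
#' Vectorised.
#'
#' @param cigar Character vector of CIGAR strings.
#' @export
cigar_reference_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(NA_integer_)
    ops <- cigar_ops(cg)
    sum(ops$length[ops$op %in% CIGAR_REF_OPS])
  }, 0L, USE.NAMES = FALSE)
}

# First reference-skip (N) operation of each CIGAR: reference offset of the
# skip from the alignment start, and skip length.  Fast path for the
# single-junction aMbNcM shape the simulator emits; general parse otherwise.
# Input must contain an N op.
cigar_first_junction <- function(cigar) {
  n <- length(cigar)
  pre <- nlen <- rep(NA_integer_, n)
  simple <- grepl("^[0-9]+M[0-9]+N[0-9]+M$", cigar)
  if (any(simple)) {
    pre[simple] <- as.integer(sub("^([0-9]+)M.*$", "\\1", cigar[simple]))
    nlen[simple] <- as.integer(sub("^[0-9]+M([0-9]+)N.*$", "\\1", cigar[simple]))
  }
  for (i in which(!simple)) {
    ops <- cigar_ops(cigar[i])
    j <- match("N", ops$op)
    if (is.na(j)) next
    before <- ops[seq_len(j - 1L), , drop = FALSE]
    pre[i] <- sum(before$length[before$op %in% CIGAR_REF_OPS])
    nlen[i] <- ops$length[j]
  }
  data.frame(pre_ref = pre, n_length = nlen)
}

sam_header_lines <- function(chrom_lengths) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths), as.integer(chrom_lengths)))
}

SAM_COLUMNS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
                 "rnext", "pnext", "tlen", "seq", "qual")

#' Read / write plain-text SAM
#'
#' Minimal SAM dialect: a `@HD`/`@SQ` header followed by 11-column alignment
#' records; optional tags are kept verbatim in a single `tags` column.
#' `"*"` is permitted for SEQ/QUAL.
#'
#' @param path SAM file path (or, for `parse_sam_lines`, a character vector
#'   of lines).
#' @return List with `header` (character vector of lines) and `records`
#'   (data.frame with the 11 standard columns plus `tags`).
#' @export
read_sam <- function(path) {
  parse_sam_lines(readLines(path))
}

#' @rdname read_sam
#' @param lines Character vector of SAM lines.
#' @export
parse_sam_lines <- function(lines) {
  is_hdr <- startsWith(lines, "@")
  header <- lines[is_hdr]
  aln <- lines[!is_hdr]
  if (length(aln) == 0L) {
    rec <- as.data.frame(setNames(rep(list(character(0)), 11L), SAM_COLUMNS))
    rec$flag <- integer(0); rec$pos <- integer(0); rec$tags <- character(0)
    return(list(header = header, records = rec))
  }
  fields <- strsplit(aln, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1]
    line_no <- which(!is_hdr)[bad]
    stop(sprintf("truncated SAM record at line %d (%d fields, need 11)",
                 line_no, nf[bad]), call. = FALSE)
  }
  col <- function(k) vapply(fields, `[[`, "", k)
  records <- data.frame(
    qname = col(1), flag = as.integer(col(2)), rname = col(3),
    pos = as.integer(col(4)), mapq = as.integer(col(5)), cigar = col(6),
    rnext = col(7), pnext = as.integer(col(8)), tlen = as.integer(col(9)),
    seq = col(10), qual = col(11),
    tags = vapply(fields, function(f)
      if (length(f) > 11L) paste(f[-(1:11)], collapse = "\t") else "", ""),
    row.names = NULL)
  list(header = header, records = records)
}

#' @rdname read_sam
#' @param header Character vector of header lines.
#' @param records Alignment record data.frame as returned by [read_sam()].
#' @export
write_sam <- function(header, records, path) {
  body <- do.call(paste, c(unname(records[SAM_COLUMNS]), sep = "\t"))
  if (!is.null(records$tags)) {
    has <- !is.na(records$tags) & records$tags != ""
    body[has] <- paste(body[has], records$tags[has], sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

# Extract the value of a Z-type tag (e.g. "XG") from the tags column.
sam_tag <- function(records, tag) {
  pat <- sprintf(".*%s:Z:([^\t]+).*", tag)
  out <- rep(NA_character_, nrow(records))
  has <- grepl(sprintf("%s:Z:", tag), records$tags, fixed = TRUE)
  out[has] <- sub(pat, "\\1", records$tags[has])
  out
}
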