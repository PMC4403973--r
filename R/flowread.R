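#' Construct a 454 flowgram read
#'
#' A `flow_read` is the lossless in-memory model of one 454 pyrosequencing
#' read: the flowgram (one signal intensity per nucleotide flow, in flow
#' units where 1.0 corresponds to one incorporated base), the called bases,
#' their Phred quality scores, and the per-base index of the flow that
#' produced each call.
#'
#' All read-internal coordinates are 1-based inclusive, matching the SFF
#' clip-point convention. Flow values are held as reals in flow units;
#' conversion to/from the hundredths stored on disk happens only at the file
#' boundary.
#'
#' @param read_id Character scalar, the read identifier.
#' @param flow_chars Character scalar: nucleotide flow order over the whole
#'   flowgram (e.g. `"TACG"` repeated), one character per flow.
#' @param flow_values Numeric vector of non-negative flow signal intensities,
#'   one per flow, in flow units.
#' @param flow_index_per_base Integer vector, one 1-based flow index per
#'   called base; non-decreasing.
#' @param bases Character scalar: called bases over `{A,C,G,T,N}`.
#' @param quals Integer vector of Phred scores (0--40), one per base.
#' @param clip_qual Integer pair, 1-based inclusive quality clip points.
#' @param clip_adapter Integer pair, 1-based inclusive adapter clip points
#'   (`c(0, 0)` when absent).
#'
#' @return An object of class `flow_read`.
#' @export
flow_read <- function(read_id, flow_chars, flow_values, flow_index_per_base,
                      bases, quals, clip_qual = c(1L, nchar(bases)),
                      clip_adapter = c(0L, 0L)) {
  r <- structure(list(
    read_id = as.character(read_id),
    flow_chars = as.character(flow_chars),
    flow_values = as.numeric(flow_values),
    flow_index_per_base = as.integer(flow_index_per_base),
    bases = toupper(as.character(bases)),
    quals = as.integer(quals),
    clip_qual = as.integer(clip_qual),
    clip_adapter = as.integer(clip_adapter)
  ), class = "flow_read")
  validate_flow_read(r)
  r
}

#' Validate a flow_read's internal invariants
#'
#' Checks length agreement between bases, quality scores and flow indices,
#' that flow indices are non-decreasing and within the flowgram, and that
#' every non-N base matches the nucleotide of its calling flow.
#'
#' @param r A `flow_read`.
#' @return `r`, invisibly; stops on violation.
#' @export
validate_flow_read <- function(r) {
  n <- nchar(r$bases)
  if (length(r$quals) != n || length(r$flow_index_per_base) != n)
    stop("flow_read '", r$read_id,
         "': bases, quals and flow_index_per_base lengths differ")
  if (nchar(r$flow_chars) != length(r$flow_values))
    stop("flow_read '", r$read_id,
         "': flow_chars length does not match flow_values length")
  if (n > 0) {
    fi <- r$flow_index_per_base
    if (any(diff(fi) < 0)) stop("flow_read '", r$read_id,
                                "': flow_index_per_base is decreasing")
    if (any(fi < 1L) || any(fi > length(r$flow_values)))
      stop("flow_read '", r$read_id, "': flow index out of flowgram range")
    bs <- strsplit(r$bases, "")[[1]]
    fc <- strsplit(r$flow_chars, "")[[1]]
    bad <- bs != "N" & bs != fc[fi]
    if (any(bad))
      stop("flow_read '", r$read_id, "': base at position ",
           which(bad)[1], " does not match its calling flow nucleotide")
  }
  if (any(r$flow_values < 0)) stop("flow_read '", r$read_id,
                                   "': negative flow value")
  invisible(r)
}

#' @export
print.flow_read <- function(x, ...) {
  cat("<flow_read> ", x$read_id, ": ", nchar(x$bases), " bases, ",
      length(x$flow_values), " flows\n", sep = "")
  b <- x$bases
  if (nchar(b) > 60) b <- paste0(substr(b, 1, 57), "...")
  cat("  bases: ", b, "\n", sep = "")
  invisible(x)
}

#' @export
length.flow_read <- function(x) nchar(x$bases)

# Truncate a flow_read to its first n bases, keeping flowgram intact.
truncate_flow_read <- function(r, n) {
  n <- as.integer(n)
  r$bases <- substr(r$bases, 1L, n)
  r$quals <- r$quals[seq_len(n)]
  r$flow_index_per_base <- r$flow_index_per_base[seq_len(n)]
  r$clip_qual <- c(min(r$clip_qual[1], max(n, 1L)), min(r$clip_qual[2], n))
  r
}
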