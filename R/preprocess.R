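#' Basic read trimming: ambiguities, length, homopolymer filters
#'
#' Removes a read when it contains one or more ambiguous bases (`N`), OR is
#' shorter than `min_len` bases, OR contains a homopolymer run longer than
#' `max_homopolymer` bases. Filters are applied in that order and each
#' removed read is counted once, under its first failing rule. Surviving
#' reads pass through unmodified. Homopolymer runs are counted on the called
#' base string.
#'
#' @param reads List of [flow_read] objects.
#' @param min_len Minimum retained read length in bases (a read of exactly
#'   `min_len` is kept; the inequality is strict).
#' @param max_homopolymer Longest permitted homopolymer run, in bases.
#' @return List with elements `kept` (list of [flow_read]) and `report`
#'   (one-row data.frame: `input_count`, `kept_count`, `removed_ambiguous`,
#'   `removed_short`, `removed_homopolymer`).
#' @export
basic_trim <- function(reads, min_len = 200L, max_homopolymer = 8L) {
  seqs <- vapply(reads, function(r) r$bases, "")
  ambiguous <- grepl("N", seqs, fixed = TRUE)
  short <- !ambiguous & nchar(seqs) < min_len
  hp_re <- sprintf("([ACGT])\\1{%d,}", max_homopolymer)
  homopolymer <- !ambiguous & !short & grepl(hp_re, seqs)
  keep <- !(ambiguous | short | homopolymer)
  report <- data.frame(
    input_count = length(reads),
    kept_count = sum(keep),
    removed_ambiguous = sum(ambiguous),
    removed_short = sum(short),
    removed_homopolymer = sum(homopolymer)
  )
  list(kept = reads[keep], report = report)
}

#' Strict quality trimming with a sliding average-Phred window
#'
#' Scans windows of `window` bases starting at positions 1, 2, ... (step one
#' base). The read is truncated at the last base before the first window
#' whose mean Phred score falls below `q_cutoff`; quality scores and per-base
#' flow indices are truncated consistently. A read shorter than `window` is
#' kept untrimmed when its overall mean quality is at least `q_cutoff`, else
#' rejected. After trimming, reads shorter than `min_len` are rejected.
#'
#' @param read A [flow_read] with quality scores.
#' @param window Sliding window width in bases.
#' @param q_cutoff Minimum mean Phred score per window.
#' @param min_len Minimum retained length after trimming.
#' @return The (possibly truncated) [flow_read], or `NULL` when rejected.
#' @export
strict_trim <- function(read, window = 100L, q_cutoff = 30L, min_len = 200L) {
  q <- read$quals
  n <- length(q)
  if (n < window) {
    if (mean(q) < q_cutoff) return(NULL)
    if (n < min_len) return(NULL)
    return(read)
  }
  # rolling mean over all windows of size `window`
  cs <- cumsum(c(0, q))
  wmean <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
  fail <- which(wmean < q_cutoff)
  if (length(fail)) {
    cut_at <- fail[1] - 1L          # keep bases before the failing window
    if (cut_at < min_len) return(NULL)
    read <- truncate_flow_read(read, cut_at)
  }
  if (nchar(read$bases) < min_len) return(NULL)
  read
}

#' Strict-trim a set of reads
#'
#' Applies [strict_trim] to each read and tallies the outcome.
#'
#' @inheritParams basic_trim
#' @inheritParams strict_trim
#' @return List with `kept` (trimmed reads) and `report` (one-row
#'   data.frame: `input_count`, `kept_count`, `trimmed_by_quality`,
#'   `removed_low_quality`).
#' @export
strict_trim_set <- function(reads, window = 100L, q_cutoff = 30L,
                            min_len = 200L) {
  out <- lapply(reads, strict_trim, window = window, q_cutoff = q_cutoff,
                min_len = min_len)
  kept <- !vapply(out, is.null, TRUE)
  trimmed <- kept & mapply(function(a, b) length(b) < length(a),
                           reads, out) > 0
  list(
    kept = out[kept],
    report = data.frame(
      input_count = length(reads),
      kept_count = sum(kept),
      trimmed_by_quality = sum(trimmed),
      removed_low_quality = sum(!kept)
    )
  )
}
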