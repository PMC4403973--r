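#' Reference-based two-parent chimera detection
#'
#' For each read (in a common alignment space with the references), the
#' mismatch count to every single reference and to every two-parent
#' chimera — a prefix of one reference followed, from a breakpoint column
#' onward, by a suffix of another — is computed from per-reference prefix
#' mismatch arrays in O(refs * columns) per read. A read is called chimeric
#' when its best chimera explains at least `margin` fewer mismatches than
#' its best single reference. Columns where the read has a terminal gap are
#' ignored; internal gaps count as mismatches.
#'
#' @param reads_aligned Data.frame of reads in alignment space (`id`,
#'   `seq`).
#' @param refs_aligned Data.frame of references in the same column space.
#' @param margin Minimum mismatch improvement to call a chimera.
#' @return Named logical vector (TRUE = chimeric).
#' @export
detect_chimeras <- function(reads_aligned, refs_aligned, margin = 3L) {
  widths <- unique(c(nchar(reads_aligned$seq), nchar(refs_aligned$seq)))
  if (length(widths) != 1)
    stop("reads and references are not in a common alignment space")
  if (nrow(refs_aligned) < 2) {
    warning("fewer than 2 references; no chimeras can be formed")
    return(stats::setNames(rep(FALSE, nrow(reads_aligned)),
                           reads_aligned$id))
  }
  L <- widths
  Rm <- do.call(rbind, strsplit(refs_aligned$seq, ""))
  Rm[Rm == "."] <- "-"
  out <- logical(nrow(reads_aligned))
  for (i in seq_len(nrow(reads_aligned))) {
    rv <- strsplit(reads_aligned$seq[i], "")[[1]]
    rv[rv == "."] <- "-"
    nb <- which(rv != "-")
    if (!length(nb)) { out[i] <- FALSE; next }
    a <- nb[1]; b <- nb[length(nb)]
    cols <- a:b
    mism <- sweep(Rm[, cols, drop = FALSE], 2, rv[cols], `!=`) * 1L
    pre <- if (length(cols) == 1L) mism else t(apply(mism, 1, cumsum))
    totals <- pre[, ncol(pre)]
    best_single <- min(totals)
    # breakpoint after column t (t = 0..|cols|): prefix from one ref,
    # suffix from another; t = 0 and t = |cols| reduce to single refs
    pre0 <- cbind(0L, pre)
    left_min <- apply(pre0, 2, min)
    right_min <- apply(totals - pre0, 2, min)
    best_chimera <- min(left_min + right_min)
    out[i] <- (best_single - best_chimera) >= margin
  }
  stats::setNames(out, reads_aligned$id)
}

#' Mock-community error report
#'
#' Flags chimeric reads (excluded from error counting), labels every other
#' read against its best reference with the canonicalized affine alignment
#' of [assign_reference]/[label_errors], and aggregates the
#' abundance-weighted global error rate — erroneous nucleotides over total
#' nucleotides — together with per-read counts.
#'
#' @param records Data.frame of reads: `id`, `seq`, optional `abundance`
#'   (a read of abundance N contributes N copies).
#' @param references Data.frame of aligned reference sequences (`id`,
#'   `seq`, equal lengths; gap-free references are their own alignment).
#' @param margin Chimera-calling margin (see [detect_chimeras]).
#' @return List of class `error_report`: `per_read` (data.frame `read_id`,
#'   `best_reference`, `n_sub`, `n_ins`, `n_del`, `n_bases`, `is_chimera`,
#'   `abundance`), `error_rate` (fraction), `chimera_pct` (percent of
#'   abundance), `events` (per-read event tables), `n_unmatched`.
#' @export
compute_error_report <- function(records, references, margin = 3L) {
  if (length(unique(nchar(references$seq))) != 1)
    stop("references must be aligned to a common length")
  ab <- if (is.null(records$abundance)) rep(1L, nrow(records)) else records$abundance

  proj <- align_to_template(records, references)
  aligned_ids <- vapply(proj$reads, function(r) r$read_id, "")
  reads_aligned <- data.frame(
    id = aligned_ids,
    seq = vapply(proj$reads, function(r) r$aligned, ""),
    stringsAsFactors = FALSE)
  refs_final <- data.frame(
    id = references$id,
    seq = project_template(references$seq, proj$template_column_map,
                           proj$n_columns),
    stringsAsFactors = FALSE)
  chim <- detect_chimeras(reads_aligned, refs_final, margin = margin)

  degapped_refs <- data.frame(id = references$id,
                              seq = gsub("[-.]", "", references$seq),
                              stringsAsFactors = FALSE)
  attr(degapped_refs, "kmer_sets") <- ref_kmer_sets(degapped_refs)

  n <- nrow(records)
  per_read <- data.frame(read_id = records$id,
                         best_reference = NA_character_,
                         n_sub = 0L, n_ins = 0L, n_del = 0L,
                         n_bases = nchar(records$seq),
                         is_chimera = FALSE, abundance = ab,
                         stringsAsFactors = FALSE)
  per_read$is_chimera <- records$id %in% names(chim)[chim]
  events <- vector("list", n)
  names(events) <- records$id
  n_unmatched <- length(proj$unaligned_ids)
  asgs <- align_batch(records$seq, degapped_refs)
  for (i in seq_len(n)) {
    if (per_read$is_chimera[i]) next
    if (records$id[i] %in% proj$unaligned_ids) next
    asg <- asgs[[i]]
    if (asg$unmatched) { n_unmatched <- n_unmatched + 1L; next }
    per_read$best_reference[i] <- asg$reference_id
    ev <- label_errors(asg$read_aln, asg$ref_aln)
    events[[i]] <- ev
    per_read$n_sub[i] <- sum(ev$n[ev$type == "substitution"])
    per_read$n_ins[i] <- sum(ev$n[ev$type == "insertion"])
    per_read$n_del[i] <- sum(ev$n[ev$type == "deletion"])
  }
  ok <- !per_read$is_chimera & !is.na(per_read$best_reference)
  if (!any(ok)) stop("no non-chimeric reads matched a reference")
  w <- per_read$abundance[ok]
  n_err <- per_read$n_sub[ok] + per_read$n_ins[ok] + per_read$n_del[ok]
  structure(list(
    per_read = per_read,
    error_rate = sum(w * n_err) / sum(w * per_read$n_bases[ok]),
    chimera_pct = 100 * sum(per_read$abundance[per_read$is_chimera]) / sum(ab),
    events = events,
    n_unmatched = n_unmatched), class = "error_report")
}

# Place aligned template records into the padded final column space
# produced by align_to_template (pad columns become gaps).
project_template <- function(template_seqs, column_map, n_columns) {
  vapply(template_seqs, function(s) {
    v <- strsplit(s, "")[[1]]
    v[v == "."] <- "-"
    vec <- rep("-", n_columns)
    vec[column_map] <- v
    paste(vec, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' @export
print.error_report <- function(x, ...) {
  cat("<error_report> ", nrow(x$per_read), " reads (",
      sum(x$per_read$abundance), " weighted)\n", sep = "")
  cat(sprintf("  error rate: %.5f   chimeras: %.2f%%   unmatched: %d\n",
              x$error_rate, x$chimera_pct, x$n_unmatched))
  invisible(x)
}

#' Per-position error-rate profile
#'
#' At each read position p, the abundance-weighted rate of each error type:
#' events of that type anchored at p divided by the (weighted) number of
#' non-chimeric reads covering p.
#'
#' @param report An `error_report` from [compute_error_report].
#' @return Data.frame: `position`, `ins_rate`, `del_rate`, `sub_rate`,
#'   `total_rate`, `coverage`.
#' @export
positional_profile <- function(report) {
  pr <- report$per_read
  ok <- !pr$is_chimera & !is.na(pr$best_reference)
  if (!any(ok)) stop("empty report")
  maxlen <- max(pr$n_bases[ok])
  cov <- numeric(maxlen)
  for (i in which(ok))
    cov[seq_len(pr$n_bases[i])] <- cov[seq_len(pr$n_bases[i])] + pr$abundance[i]
  acc <- matrix(0, maxlen, 3,
                dimnames = list(NULL, c("insertion", "deletion",
                                        "substitution")))
  for (i in which(ok)) {
    ev <- report$events[[pr$read_id[i]]]
    if (is.null(ev) || !nrow(ev)) next
    for (k in seq_len(nrow(ev)))
      acc[ev$position[k], ev$type[k]] <-
        acc[ev$position[k], ev$type[k]] + ev$n[k] * pr$abundance[i]
  }
  data.frame(position = seq_len(maxlen),
             ins_rate = acc[, "insertion"] / cov,
             del_rate = acc[, "deletion"] / cov,
             sub_rate = acc[, "substitution"] / cov,
             total_rate = rowSums(acc) / cov,
             coverage = cov)
}
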