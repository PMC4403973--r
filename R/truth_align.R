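#' Assign a read to its best reference and align it
#'
#' Candidate references are shortlisted by shared 8-mer count, then each
#' candidate is aligned with a global--local affine-gap alignment (the read
#' global, the reference local; match +1, mismatch -1, gap open -2, gap
#' extend -1). The highest-scoring candidate wins; ties break by fewest
#' indel columns, then lexicographic reference id. Gaps inside homopolymer
#' runs are canonicalized to the 3' end of the run so that equivalent-score
#' gap placements label identically.
#'
#' @param bases Read sequence (character scalar, no gaps).
#' @param references Data.frame with columns `id`, `seq`.
#' @param k K-mer size for the prescreen.
#' @param top Number of shortlisted candidates to align.
#' @return List: `reference_id`, `read_aln`, `ref_aln` (gapped strings of
#'   equal length), `score`, `ref_start` (1-based start of the aligned
#'   region on the reference), `unmatched` (TRUE when the read shares no
#'   k-mer with any reference; other fields NA then).
#' @export
assign_reference <- function(bases, references, k = 8L, top = 5L) {
  align_batch(bases, references, k = k, top = top)[[1]]
}

# Vectorized workhorse behind assign_reference: shortlists candidates per
# read by shared k-mers, then aligns all reads shortlisting a given
# reference in one pairwiseAlignment call (the per-call S4 overhead
# dominates otherwise). Returns one result list per input sequence.
align_batch <- function(seqs, references, k = 8L, top = 5L) {
  kmers <- attr(references, "kmer_sets")
  if (is.null(kmers)) kmers <- ref_kmer_sets(references, k)
  n <- length(seqs)
  cand <- vector("list", n)
  for (i in seq_len(n)) {
    nk <- nchar(seqs[i]) - k + 1L
    if (nk < 1L) { cand[[i]] <- integer(0); next }
    rk <- unique(substring(seqs[i], seq_len(nk), seq_len(nk) + k - 1L))
    shared <- vapply(kmers, function(s) sum(rk %in% s), 0L)
    if (all(shared == 0L)) { cand[[i]] <- integer(0); next }
    ord <- order(-shared, references$id)
    ord <- ord[shared[ord] > 0L]
    cand[[i]] <- ord[seq_len(min(top, length(ord)))]
  }

  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  res <- vector("list", n)
  key <- vector("list", n)
  better <- function(a, b) {
    a$score > b$score ||
      (a$score == b$score &&
         (a$indel < b$indel || (a$indel == b$indel && a$id < b$id)))
  }
  for (r in seq_len(nrow(references))) {
    idx <- which(vapply(cand, function(cc) r %in% cc, TRUE))
    if (!length(idx)) next
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(seqs[idx]),
      Biostrings::DNAString(references$seq[r]),
      type = "global-local", substitutionMatrix = mat,
      gapOpening = 1, gapExtension = 1)
    pa <- as.character(Biostrings::pattern(al))
    sa <- as.character(Biostrings::subject(al))
    sc <- Biostrings::score(al)
    st <- Biostrings::start(Biostrings::subject(al))
    # pattern()/subject() drop terminal-insertion columns (read bases
    # overhanging the local subject window); restore them as gap columns
    ps <- Biostrings::start(Biostrings::pattern(al))
    pe <- Biostrings::end(Biostrings::pattern(al))
    full <- nchar(seqs[idx])
    clipped <- which(ps > 1L | pe < full)
    for (t in clipped) {
      lead <- ps[t] - 1L
      trail <- full[t] - pe[t]
      pa[t] <- paste0(substr(seqs[idx[t]], 1L, lead), pa[t],
                      substr(seqs[idx[t]], pe[t] + 1L, full[t]))
      sa[t] <- paste0(strrep("-", lead), sa[t], strrep("-", trail))
    }
    nind <- (nchar(pa) - nchar(gsub("-", "", pa, fixed = TRUE))) +
      (nchar(sa) - nchar(gsub("-", "", sa, fixed = TRUE)))
    for (t in seq_along(idx)) {
      i <- idx[t]
      kk <- list(score = sc[t], indel = nind[t], id = references$id[r])
      if (is.null(key[[i]]) || better(kk, key[[i]])) {
        key[[i]] <- kk
        res[[i]] <- list(reference_id = references$id[r], read_aln = pa[t],
                         ref_aln = sa[t], score = sc[t], ref_start = st[t])
      }
    }
  }
  lapply(seq_len(n), function(i) {
    if (is.null(res[[i]]))
      return(list(reference_id = NA_character_, read_aln = NA_character_,
                  ref_aln = NA_character_, score = NA_real_,
                  ref_start = NA_integer_, unmatched = TRUE))
    canon <- canonicalize_gaps(res[[i]]$read_aln, res[[i]]$ref_aln)
    out <- res[[i]]
    out$read_aln <- canon$a
    out$ref_aln <- canon$b
    out$unmatched <- FALSE
    out
  })
}

# Precompute the k-mer set of each reference; attach with
# attr(references, "kmer_sets") to avoid recomputation across reads.
ref_kmer_sets <- function(references, k = 8L) {
  lapply(references$seq, function(s) {
    n <- nchar(s) - k + 1L
    unique(substring(s, seq_len(n), seq_len(n) + k - 1L))
  })
}

# Shift gaps to the 3' end of homopolymer runs in both sequences of a
# pairwise alignment; score-preserving swaps only, iterated to fixpoint.
canonicalize_gaps <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  L <- length(av)
  repeat {
    changed <- FALSE
    j <- 1L
    while (j < L) {
      if (av[j] == "-" && av[j + 1L] != "-" &&
          bv[j] != "-" && bv[j] == bv[j + 1L]) {
        av[j] <- av[j + 1L]; av[j + 1L] <- "-"
        changed <- TRUE
      } else if (bv[j] == "-" && bv[j + 1L] != "-" &&
                 av[j] != "-" && av[j] == av[j + 1L]) {
        bv[j] <- bv[j + 1L]; bv[j + 1L] <- "-"
        changed <- TRUE
      }
      j <- j + 1L
    }
    if (!changed) break
  }
  list(a = paste(av, collapse = ""), b = paste(bv, collapse = ""))
}

#' Label per-position errors from a pairwise alignment
#'
#' First canonicalizes the alignment (gaps inside homopolymer runs shifted
#' to the 3' end of the run; score-preserving), then walks the columns: a
#' mismatched column is a substitution at that read position; a read base
#' over a reference gap is an insertion; a reference base over a read gap
#' is a deletion anchored to
#' the called base immediately 3' of the missing reference base (the read's
#' last base for a terminal deletion). Unlisted positions are clean.
#'
#' @param read_aln,ref_aln Gapped alignment strings of equal length.
#' @return Data.frame with columns `position`, `type`
#'   (`insertion`/`deletion`/`substitution`) and `n` (events anchored
#'   there).
#' @export
label_errors <- function(read_aln, ref_aln) {
  if (nchar(read_aln) != nchar(ref_aln))
    stop("alignment strings differ in length")
  canon <- canonicalize_gaps(read_aln, ref_aln)
  av <- strsplit(canon$a, "")[[1]]
  bv <- strsplit(canon$b, "")[[1]]
  rpos <- cumsum(av != "-")            # read position at/before each column
  n_read <- max(rpos, 1L)
  pos <- integer(0); type <- character(0)
  for (j in seq_along(av)) {
    if (av[j] != "-" && bv[j] != "-") {
      if (av[j] != bv[j]) { pos <- c(pos, rpos[j]); type <- c(type, "substitution") }
    } else if (av[j] != "-" && bv[j] == "-") {
      pos <- c(pos, rpos[j]); type <- c(type, "insertion")
    } else if (av[j] == "-" && bv[j] != "-") {
      anchor <- if (rpos[j] < n_read) rpos[j] + 1L else n_read
      pos <- c(pos, anchor); type <- c(type, "deletion")
    }
  }
  if (!length(pos))
    return(data.frame(position = integer(), type = character(),
                      n = integer(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(n = rep(1L, length(pos))),
                          by = list(position = pos, type = type), FUN = sum)
  agg <- agg[order(agg$position, agg$type), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Label every read of a set against its best reference
#'
#' Convenience wrapper running [assign_reference] and [label_errors] over a
#' read set, producing the labelled instance table used for classifier
#' training: the feature table joined with a `label` column (`clean` or the
#' error type anchored at that position; a position carrying several event
#' types keeps the first of insertion/deletion/substitution in alphabetical
#' order of type, i.e. deletion < insertion < substitution).
#'
#' @param reads List of [flow_read] objects (basic-trimmed).
#' @param references Data.frame with columns `id`, `seq`.
#' @return List: `instances` (feature table + `read_id`, `position`,
#'   `label`), `assignments` (read_id, reference_id, score, unmatched),
#'   `labels` (per-read event tables).
#' @export
label_reads <- function(reads, references) {
  attr(references, "kmer_sets") <- ref_kmer_sets(references)
  feats <- extract_features_set(reads)
  feats$label <- "clean"
  assignments <- data.frame(read_id = vapply(reads, function(r) r$read_id, ""),
                            reference_id = NA_character_, score = NA_real_,
                            unmatched = FALSE, stringsAsFactors = FALSE)
  labels <- vector("list", length(reads))
  names(labels) <- assignments$read_id
  # row offset of each read's first feature row (reads are row-blocked)
  n_bases <- vapply(reads, function(r) nchar(r$bases), 0L)
  offsets <- cumsum(c(0L, n_bases))[seq_along(reads)]
  asgs <- align_batch(vapply(reads, function(r) r$bases, ""), references)
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    asg <- asgs[[i]]
    assignments$reference_id[i] <- asg$reference_id
    assignments$score[i] <- asg$score
    assignments$unmatched[i] <- asg$unmatched
    if (asg$unmatched) next
    ev <- label_errors(asg$read_aln, asg$ref_aln)
    labels[[i]] <- ev
    if (nrow(ev)) {
      for (k in seq_len(nrow(ev))) {
        row <- offsets[i] + ev$position[k]
        if (feats$label[row] == "clean") feats$label[row] <- ev$type[k]
      }
    }
  }
  list(instances = feats, assignments = assignments, labels = labels)
}
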