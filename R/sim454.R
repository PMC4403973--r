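#' Simulation parameters for 454-like flowgram reads
#'
#' The error model reproduces the known 454 error sources: homopolymer
#' length miscalls from analog signal noise (standard deviation growing with
#' run length), signal degradation towards the read end, and the CAFIE pair
#' of phase artifacts — carry-forward (signal appearing in an earlier flow of
#' the same nucleotide) and incomplete extension (residual signal deferred to
#' a later flow of the same nucleotide).
#'
#' The flow signal for a true homopolymer of length n is drawn from
#' Normal(n, (sd0 + sd_slope * n) * (1 + positional_decay * flow)). Defaults
#' are chosen to yield a raw per-base error rate around 0.5%, typical of
#' basic-trimmed 454 amplicon data.
#'
#' Phred scores follow Q = clamp(round(40 - 60*|signal - called| -
#' 0.01*flow), 2, 40): quality falls as the signal approaches the rounding
#' boundary and degrades slowly along the flowgram.
#'
#' @param flow_order Cyclic nucleotide flow order.
#' @param n_flows Number of flows per read.
#' @param sd0 Baseline flow signal standard deviation (flow units).
#' @param sd_slope Additional standard deviation per unit of true
#'   homopolymer length.
#' @param carry_forward_rate Per-positive-flow probability of carry-forward
#'   leakage into the most recent preceding flow of the same nucleotide.
#' @param incomplete_extension_rate Per-positive-flow probability of
#'   deferring a residual fraction of signal to the next flow of the same
#'   nucleotide.
#' @param positional_decay Per-flow multiplicative noise inflation.
#' @param seed Integer seed; all outputs are reproducible given the params.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(flow_order = "TACG", n_flows = 800L, sd0 = 0.08,
                       sd_slope = 0.03, carry_forward_rate = 0.005,
                       incomplete_extension_rate = 0.005,
                       positional_decay = 0.001, seed = 1L) {
  stopifnot(n_flows >= 1, sd0 > 0,
            carry_forward_rate >= 0, carry_forward_rate <= 1,
            incomplete_extension_rate >= 0, incomplete_extension_rate <= 1)
  structure(list(flow_order = flow_order, n_flows = as.integer(n_flows),
                 sd0 = sd0, sd_slope = sd_slope,
                 carry_forward_rate = carry_forward_rate,
                 incomplete_extension_rate = incomplete_extension_rate,
                 positional_decay = positional_decay,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Generate a set of related reference sequences with abundance weights
#'
#' One random ancestor sequence is mutated (substitutions at random
#' positions) into `n_species` references at the requested pairwise
#' divergence. Abundance weights are log-uniform over the 0.5%--50% range
#' typical of uneven mock communities, normalized to sum to 1.
#'
#' @param n_species Number of reference sequences (>= 1).
#' @param length Reference length in bases (>= 50).
#' @param divergence Target pairwise divergence in [0, 1] (each reference
#'   carries `divergence/2 * length` substitutions relative to the
#'   ancestor).
#' @param seed Integer seed.
#' @return List with `records` (data.frame `id`, `seq`) and `weights`
#'   (named numeric summing to 1).
#' @export
generate_references <- function(n_species, length, divergence, seed = 1L) {
  stopifnot(n_species >= 1, length >= 50, divergence >= 0, divergence <= 1)
  set.seed(seed)
  nt <- c("A", "C", "G", "T")
  ancestor <- sample(nt, length, replace = TRUE)
  n_mut <- round(divergence / 2 * length)
  mutate <- function() {
    s <- ancestor
    pos <- sample.int(length, n_mut)
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(nt, b), 1), "")
    paste(s, collapse = "")
  }
  seqs <- vapply(seq_len(n_species), function(i) mutate(), "")
  attempts <- 0L
  while (anyDuplicated(seqs)) {
    attempts <- attempts + 1L
    if (attempts > 100L)
      stop("could not generate ", n_species,
           " distinct references at divergence ", divergence)
    warning("reference collision at divergence ", divergence,
            "; regenerating", call. = FALSE)
    dup <- which(duplicated(seqs))
    seqs[dup] <- vapply(dup, function(i) mutate(), "")
  }
  w <- exp(stats::runif(n_species, log(0.005), log(0.5)))
  w <- w / sum(w)
  ids <- sprintf("REF%03d", seq_len(n_species))
  names(w) <- ids
  list(records = data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE),
       weights = w)
}

#' Simulate flowgram reads with exact ground-truth error annotation
#'
#' For each read a reference is drawn by weight and its flowgram walked in
#' flow order: the true incorporation count at each flow is perturbed by
#' carry-forward, incomplete extension and Gaussian intensity noise (see
#' [sim_params]), quantized to stored hundredths, and called as
#' floor(signal + 0.5). Every divergence between the called bases and the
#' source reference is bookkept during generation (not re-aligned):
#' surplus calls are insertions (anchored at the 3' end of the flow's call
#' block), missing calls are deletions anchored to the next called base, and
#' a deletion whose gap is filled by an insertion with no intervening called
#' base is recorded as a substitution at the inserted base.
#'
#' @param references Data.frame with columns `id`, `seq` (as from
#'   [generate_references]).
#' @param weights Numeric vector of sampling weights summing to 1.
#' @param n_reads Number of reads to simulate.
#' @param params A [sim_params] object.
#' @return List with `reads` (list of [flow_read]) and `truth` (list per
#'   read: `read_id`, `reference_id`, `events` data.frame with columns
#'   `position`, `type`, `n`, and `truncated` flag).
#' @export
simulate_reads <- function(references, weights, n_reads, params = sim_params()) {
  stopifnot(abs(sum(weights) - 1) < 1e-6,
            length(weights) == nrow(references))
  set.seed(params$seed)
  fc <- strsplit(strrep(params$flow_order,
                        ceiling(params$n_flows / nchar(params$flow_order))),
                 "")[[1]][seq_len(params$n_flows)]
  flow_chars <- paste(fc, collapse = "")
  ref_vecs <- lapply(references$seq, function(s) strsplit(s, "")[[1]])
  ref_pick <- sample.int(nrow(references), n_reads, replace = TRUE,
                         prob = weights)

  reads <- vector("list", n_reads)
  truth <- vector("list", n_reads)
  for (r in seq_len(n_reads)) {
    ref <- ref_vecs[[ref_pick[r]]]
    sim <- simulate_one_flowgram(ref, fc, params)
    id <- sprintf("SIM%06d", r)
    reads[[r]] <- flow_read(
      read_id = id, flow_chars = flow_chars, flow_values = sim$signal,
      flow_index_per_base = sim$flow_index, bases = sim$bases,
      quals = sim$quals
    )
    truth[[r]] <- list(read_id = id,
                       reference_id = references$id[ref_pick[r]],
                       events = sim$events, truncated = sim$truncated)
  }
  list(reads = reads, truth = truth)
}

# Core single-read flowgram simulation; returns signal, calls and truth.
simulate_one_flowgram <- function(ref, fc, params) {
  n_flows <- length(fc)
  L <- length(ref)
  # true incorporation counts per flow
  t_cnt <- integer(n_flows)
  pos <- 1L
  for (i in seq_len(n_flows)) {
    if (pos > L) break
    k <- 0L
    while (pos + k <= L && ref[pos + k] == fc[i]) k <- k + 1L
    t_cnt[i] <- k
    pos <- pos + k
  }
  truncated <- pos <= L

  s <- as.numeric(t_cnt)
  positive <- which(t_cnt > 0L)
  # carry-forward: additive leakage into the most recent same-nucleotide flow
  if (params$carry_forward_rate > 0 && length(positive)) {
    hit <- positive[stats::runif(length(positive)) < params$carry_forward_rate]
    for (i in hit) {
      j <- prev_same_flow(fc, i)
      if (!is.na(j)) s[j] <- s[j] + stats::runif(1, 0.2, 0.7)
    }
  }
  # incomplete extension: residual moved to the next same-nucleotide flow
  if (params$incomplete_extension_rate > 0 && length(positive)) {
    hit <- positive[stats::runif(length(positive)) <
                      params$incomplete_extension_rate]
    for (i in hit) {
      res <- stats::runif(1, 0.2, 0.7)
      s[i] <- s[i] - res
      j <- next_same_flow(fc, i)
      if (!is.na(j)) s[j] <- s[j] + res
    }
  }
  decay <- 1 + params$positional_decay * seq_len(n_flows)
  sd_vec <- (params$sd0 + params$sd_slope * t_cnt) * decay
  s <- s + stats::rnorm(n_flows, 0, sd_vec)
  s <- round(pmax(s, 0) * 100) / 100   # quantize as stored on disk
  m_cnt <- as.integer(floor(s + 0.5))  # round half up

  bases <- rep.int(fc, m_cnt)
  flow_index <- rep.int(seq_len(n_flows), m_cnt)
  q_flow <- pmin(pmax(as.integer(round(40 - 60 * abs(s - m_cnt) -
                                         0.01 * seq_len(n_flows))), 2L), 40L)
  quals <- rep.int(q_flow, m_cnt)

  events <- bookkeep_events(t_cnt, m_cnt, fc)
  list(signal = s, bases = paste(bases, collapse = ""),
       flow_index = flow_index, quals = quals,
       events = events, truncated = truncated)
}

prev_same_flow <- function(fc, i) {
  j <- i - which(rev(fc[seq_len(i - 1L)]) == fc[i])[1]
  if (length(j) == 0 || is.na(j)) NA_integer_ else j
}

next_same_flow <- function(fc, i) {
  if (i >= length(fc)) return(NA_integer_)
  off <- which(fc[(i + 1L):length(fc)] == fc[i])[1]
  if (is.na(off)) NA_integer_ else i + off
}

# Derive per-position truth events from per-flow true vs called counts,
# expressed in the same coordinate system the reference-based labelling
# uses: insertions anchored at the 3' end of a flow's call block, deletions
# anchored to the next called base, terminal deletions (before the first or
# after the last called base) dropped (they fall outside a read-global /
# reference-local alignment), and a nearby deletion+insertion pair rewritten
# as the substitution columns an affine aligner (mismatch -1, gap -2/-1)
# prefers whenever that shift explains the pair with at most two mismatched
# columns.
bookkeep_events <- function(t_cnt, m_cnt, fc) {
  n_bases <- sum(m_cnt)
  read_chars <- rep.int(fc, m_cnt)
  block_start <- cumsum(c(1L, m_cnt))[seq_along(m_cnt)]
  called_upto <- cumsum(m_cnt)      # bases called at or before each flow
  total <- n_bases
  ins <- list()  # each unit: flow, position
  del <- list()  # each unit: flow, anchor position
  for (i in which(m_cnt != t_cnt)) {
    if (m_cnt[i] > t_cnt[i]) {
      k <- m_cnt[i] - t_cnt[i]
      posns <- (block_start[i] + m_cnt[i] - k):(block_start[i] + m_cnt[i] - 1L)
      for (p in posns) ins[[length(ins) + 1L]] <- c(flow = i, position = p)
    } else {
      if (called_upto[i] == 0L) next                 # leading terminal
      if (called_upto[i] == total) next              # trailing terminal
      k <- t_cnt[i] - m_cnt[i]
      anchor <- block_start[i] + m_cnt[i]  # first base called after block
      for (u in seq_len(k))
        del[[length(del) + 1L]] <- c(flow = i, position = anchor)
    }
  }
  # rewrite del+ins pairs that an aligner would express as substitutions
  sub_pos <- integer(0)
  if (length(del) && length(ins)) {
    used_ins <- logical(length(ins))
    keep_del <- logical(length(del))
    for (d in seq_along(del)) {
      fi <- del[[d]][["flow"]]
      p <- del[[d]][["position"]]
      D <- fc[fi]
      found <- FALSE
      ord <- order(vapply(ins, function(u) abs(u[["flow"]] - fi), 0))
      for (g in ord) {
        if (used_ins[g]) next
        fj <- ins[[g]][["flow"]]
        q <- ins[[g]][["position"]]
        lo <- min(fi, fj); hi <- max(fi, fj)
        clean_between <- !any(m_cnt[seq.int(lo, hi)][-c(1L, hi - lo + 1L)] !=
                                t_cnt[seq.int(lo, hi)][-c(1L, hi - lo + 1L)])
        if (hi - lo <= 1L) clean_between <- TRUE
        if (!clean_between) next
        if (fj >= fi && q >= p) {
          # shift left: read[p..q] against ref [D, read[p..q-1]]
          seg <- read_chars[p:q]
          mm_at <- p:q
          mism <- c(seg[1] != D,
                    if (q > p) seg[-1] != seg[-length(seg)] else logical(0))
        } else if (fj <= fi && q < p) {
          # shift right: read[q..p-1] against ref [read[q+1..p-1], D]
          seg <- read_chars[q:(p - 1L)]
          mm_at <- q:(p - 1L)
          mism <- c(if (p - 1L > q) seg[-length(seg)] != seg[-1] else logical(0),
                    seg[length(seg)] != D)
        } else next
        if (sum(mism) <= 2L) {
          sub_pos <- c(sub_pos, mm_at[mism])
          used_ins[g] <- TRUE
          found <- TRUE
          break
        }
      }
      keep_del[d] <- !found
    }
    del <- del[keep_del]
    ins <- ins[!used_ins]
  }
  tab <- function(pos, type) {
    if (!length(pos)) return(NULL)
    agg <- table(pos)
    data.frame(position = as.integer(names(agg)), type = type,
               n = as.integer(agg), stringsAsFactors = FALSE)
  }
  ev <- rbind(tab(vapply(ins, function(u) u[["position"]], 0), "insertion"),
              tab(vapply(del, function(u) u[["position"]], 0), "deletion"),
              tab(sub_pos, "substitution"))
  if (is.null(ev))
    ev <- data.frame(position = integer(), type = character(),
                     n = integer(), stringsAsFactors = FALSE)
  ev <- ev[order(ev$position, ev$type), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Flatten simulation truth to one row per event
#'
#' @param truth The `truth` element returned by [simulate_reads].
#' @return Data.frame with columns `read_id`, `reference_id`, `position`,
#'   `type`, `n`.
#' @export
truth_table <- function(truth) {
  rows <- lapply(truth, function(tr) {
    if (nrow(tr$events) == 0) return(NULL)
    cbind(data.frame(read_id = tr$read_id, reference_id = tr$reference_id,
                     stringsAsFactors = FALSE),
          tr$events)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(read_id = character(), reference_id = character(),
                      position = integer(), type = character(),
                      n = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Construct two-parent chimeras from reference sequences
#'
#' Each chimera joins a prefix of one parent (up to a uniform breakpoint
#' drawn from [10, L-10]) to the suffix of a second, distinct parent —
#' the PCR artifact that reference-based chimera detection must flag.
#'
#' @param references Data.frame with columns `id`, `seq` (>= 2 rows).
#' @param n Number of chimeras.
#' @param seed Integer seed.
#' @return Data.frame: `id`, `seq`, `parent_a`, `parent_b`, `breakpoint`.
#' @export
make_chimeras <- function(references, n, seed = 1L) {
  stopifnot(nrow(references) >= 2)
  set.seed(seed)
  L <- min(nchar(references$seq))
  out <- data.frame(id = sprintf("CHIM%04d", seq_len(n)),
                    seq = character(n), parent_a = character(n),
                    parent_b = character(n), breakpoint = integer(n),
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    pr <- sample.int(nrow(references), 2L)
    bp <- sample(seq.int(10L, L - 10L), 1L)
    out$seq[k] <- paste0(substr(references$seq[pr[1]], 1L, bp),
                         substr(references$seq[pr[2]], bp + 1L,
                                nchar(references$seq[pr[2]])))
    out$parent_a[k] <- references$id[pr[1]]
    out$parent_b[k] <- references$id[pr[2]]
    out$breakpoint[k] <- bp
  }
  out
}
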