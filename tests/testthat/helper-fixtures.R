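# Shared fixtures and independent reference implementations used as oracles.

# Build a consistent flow_read from a base string by walking the flow order:
# each homopolymer run is called from one flow with signal equal to its
# length (plus optional per-flow overrides for uncalled-signal tests).
make_flow_read <- function(bases, read_id = "t1", flow_order = "TACG",
                           quals = NULL, flow_overrides = NULL,
                           n_cycles = NULL) {
  bv <- strsplit(bases, "")[[1]]
  if (is.null(n_cycles)) n_cycles <- length(bv) + 4L
  fc <- rep(strsplit(flow_order, "")[[1]], n_cycles)
  values <- numeric(length(fc))
  flow_index <- integer(length(bv))
  pos <- 1L
  for (i in seq_along(fc)) {
    if (pos > length(bv)) break
    k <- 0L
    while (pos + k <= length(bv) && bv[pos + k] == fc[i]) k <- k + 1L
    if (k > 0) {
      values[i] <- k
      flow_index[pos:(pos + k - 1L)] <- i
      pos <- pos + k
    }
  }
  if (pos <= length(bv)) stop("flow order cannot call these bases")
  if (!is.null(flow_overrides))
    values[as.integer(names(flow_overrides))] <- unname(flow_overrides)
  if (is.null(quals)) quals <- rep(40L, length(bv))
  flow_read(read_id, paste(fc, collapse = ""), values, flow_index,
            bases, quals)
}

# Random DNA string
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# A memoized mid-size simulation scenario shared across test files.
.scenario_env <- new.env(parent = emptyenv())
get_scenario <- function() {
  if (is.null(.scenario_env$sc)) {
    refs <- generate_references(10, 400, 0.10, seed = 31)
    sim <- simulate_reads(refs$records, refs$weights, 400,
                          sim_params(seed = 32))
    kept <- basic_trim(sim$reads)$kept
    .scenario_env$sc <- list(refs = refs, sim = sim, kept = kept)
  }
  .scenario_env$sc
}

# Naive reference implementation of the masking-aware preclustering:
# straightforward double loop with the same ordering and budget rules,
# written independently of the package's vectorized version.
naive_precluster <- function(mreads, diff_pct = 0.02) {
  ids <- vapply(mreads, function(r) r$read_id, "")
  ab <- vapply(mreads, function(r) r$abundance, 0L)
  ulen <- vapply(mreads, function(r) nchar(r$original), 0L)
  ord <- order(-ab, -ulen, ids)
  seqs <- lapply(mreads, function(r) {
    v <- strsplit(r$aligned, "")[[1]]; v[v == "."] <- "-"; v
  })
  span <- lapply(seqs, function(v) range(which(v != "-")))
  seeds <- integer(0)
  seed_ab <- integer(0)
  map <- stats::setNames(character(length(mreads)), ids)
  for (i in ord) {
    budget <- floor(diff_pct * ulen[i])
    hit <- 0L
    for (s in seeds) {
      a <- max(span[[i]][1], span[[s]][1])
      b <- min(span[[i]][2], span[[s]][2])
      if (a > b) next
      d <- 0L
      for (col in a:b) {
        if (col %in% mreads[[i]]$mask_columns) next
        if (col %in% mreads[[s]]$mask_columns) next
        if (seqs[[i]][col] != seqs[[s]][col]) d <- d + 1L
      }
      if (d <= budget) { hit <- s; break }
    }
    if (hit > 0L) {
      map[ids[i]] <- ids[hit]
      seed_ab[which(seeds == hit)] <- seed_ab[which(seeds == hit)] + ab[i]
    } else {
      seeds <- c(seeds, i)
      seed_ab <- c(seed_ab, ab[i])
      map[ids[i]] <- ids[i]
    }
  }
  list(map = map,
       clusters = data.frame(seed_id = ids[seeds], abundance = seed_ab,
                             stringsAsFactors = FALSE))
}

# Random masked-aligned-read instance generator for the oracle tests.
random_cluster_instance <- function(n_reads, n_cols, seed) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), n_cols, replace = TRUE)
  mreads <- lapply(seq_len(n_reads), function(i) {
    v <- base
    nmut <- sample(0:6, 1)
    if (nmut > 0) {
      at <- sample(n_cols, nmut)
      v[at] <- sample(c("A", "C", "G", "T", "-"), nmut, replace = TRUE)
    }
    # terminal gaps
    lead <- sample(0:3, 1); trail <- sample(0:3, 1)
    if (lead > 0) v[seq_len(lead)] <- "."
    if (trail > 0) v[seq.int(n_cols - trail + 1L, n_cols)] <- "."
    aligned <- paste(v, collapse = "")
    nb <- which(!v %in% c("-", "."))
    masks <- if (length(nb) && stats::runif(1) < 0.5)
      sample(nb, min(length(nb), sample(1:4, 1))) else integer()
    masked_aligned_read(sprintf("r%03d", i), aligned,
                        abundance = sample(1:50, 1),
                        mask_columns = masks)
  })
  mreads
}

# Exhaustive brute-force chimera scorer: every ordered parent pair and
# every breakpoint enumerated explicitly (per-pair prefix mismatch sums).
brute_force_chimera <- function(read_seq, ref_seqs, margin = 3L) {
  rv <- strsplit(read_seq, "")[[1]]; rv[rv == "."] <- "-"
  nb <- which(rv != "-")
  if (!length(nb)) return(FALSE)
  cols <- nb[1]:nb[length(nb)]
  mism <- lapply(ref_seqs, function(s) {
    v <- strsplit(s, "")[[1]]; v[v == "."] <- "-"
    as.integer(v[cols] != rv[cols])
  })
  best_single <- min(vapply(mism, sum, 0L))
  best_chim <- Inf
  for (p in seq_along(mism)) for (q in seq_along(mism)) {
    cp <- c(0L, cumsum(mism[[p]]))
    cq <- c(0L, cumsum(mism[[q]]))
    total_q <- sum(mism[[q]])
    for (t in seq_along(cp)) {            # breakpoint after t-1 columns
      sc <- cp[t] + (total_q - cq[t])
      if (sc < best_chim) best_chim <- sc
    }
  }
  (best_single - best_chim) >= margin
}
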