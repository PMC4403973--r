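#' Construct a masked aligned read
#'
#' Alignment-space view of one read: the gapped sequence in template column
#' space, its abundance, the set of alignment columns flagged by the
#' classifier (mapped from read positions), and the original unaligned
#' sequence retained for restoration after clustering.
#'
#' @param read_id Read identifier.
#' @param aligned Gapped string over `{A,C,G,T,-,.}`.
#' @param abundance Positive integer.
#' @param mask_columns Integer vector of 1-based alignment columns.
#' @param original Original unaligned sequence; must equal the degapped
#'   aligned string.
#' @return Object of class `masked_aligned_read`.
#' @export
masked_aligned_read <- function(read_id, aligned, abundance = 1L,
                                mask_columns = integer(), original = NULL) {
  degapped <- gsub("[-.]", "", aligned)
  if (is.null(original)) original <- degapped
  if (!identical(degapped, original))
    stop("masked_aligned_read '", read_id,
         "': degapped alignment does not equal the original sequence")
  if (abundance < 1) stop("abundance must be >= 1")
  structure(list(read_id = as.character(read_id), aligned = aligned,
                 abundance = as.integer(abundance),
                 mask_columns = as.integer(sort(unique(mask_columns))),
                 original = original),
            class = "masked_aligned_read")
}

#' Align reads into a template alignment's column space (NAST-style)
#'
#' Each read is pairwise-aligned (read global, template local; same affine
#' scores as [assign_reference]) to its best template record, selected by
#' shared k-mer count, and its bases are projected onto the template's
#' columns. Insertions relative to the template are accommodated by opening
#' shared pad columns between template columns, only as wide as the longest
#' insertion observed at that point across the read set; reads without an
#' insertion there carry gaps in the pad columns. Columns outside a read's
#' aligned span are filled with the terminal-gap character `.`.
#'
#' @param records Data.frame of reads: columns `id`, `seq`, optional
#'   `abundance`.
#' @param template Data.frame of aligned template records (`id`, `seq`,
#'   equal lengths; may contain `-`/`.` gaps).
#' @param masks Optional named list mapping read id to flagged 1-based read
#'   positions; transferred to alignment columns.
#' @return List: `reads` (list of [masked_aligned_read]), `maps` (named
#'   list: per read, integer vector mapping read position to alignment
#'   column), `n_columns`, `unaligned_ids` (reads sharing no k-mer with any
#'   template record, excluded).
#' @export
align_to_template <- function(records, template, masks = NULL) {
  tw <- unique(nchar(template$seq))
  if (length(tw) != 1) stop("template columns are not uniform length")
  degapped <- data.frame(id = template$id,
                         seq = gsub("[-.]", "", template$seq),
                         stringsAsFactors = FALSE)
  attr(degapped, "kmer_sets") <- ref_kmer_sets(degapped)
  # template base -> column maps
  tmaps <- lapply(template$seq,
                  function(s) which(!strsplit(s, "")[[1]] %in% c("-", ".")))
  names(tmaps) <- template$id
  ab <- if (is.null(records$abundance)) rep(1L, nrow(records)) else records$abundance

  n <- nrow(records)
  placements <- vector("list", n)   # per read: template-column of each base (NA = insertion)
  ins_after <- vector("list", n)    # per read: column after which each inserted base sits
  unaligned <- character(0)
  asgs <- align_batch(records$seq, degapped)
  for (i in seq_len(n)) {
    asg <- asgs[[i]]
    if (asg$unmatched) { unaligned <- c(unaligned, records$id[i]); next }
    tmap <- tmaps[[asg$reference_id]]
    av <- strsplit(asg$read_aln, "")[[1]]
    bv <- strsplit(asg$ref_aln, "")[[1]]
    tpos <- asg$ref_start - 1L
    base_col <- integer(0)   # per read base: template column or NA
    after_col <- integer(0)  # for NA entries: column the insertion follows
    for (j in seq_along(av)) {
      if (bv[j] != "-") tpos <- tpos + 1L
      if (av[j] != "-") {
        if (bv[j] != "-") {
          base_col <- c(base_col, tmap[tpos])
          after_col <- c(after_col, NA_integer_)
        } else {
          base_col <- c(base_col, NA_integer_)
          after_col <- c(after_col, if (tpos >= 1L) tmap[tpos] else 0L)
        }
      }
    }
    placements[[i]] <- base_col
    ins_after[[i]] <- after_col
  }

  # shared pad slots: widest insertion after each template column
  pad <- integer(tw + 1L)  # index c+1 = slot after column c (c = 0..tw)
  for (i in seq_len(n)) {
    ac <- ins_after[[i]]
    if (is.null(ac) || !anyNA(placements[[i]])) next
    runs <- rle(ac[!is.na(ac)])
    for (k in seq_along(runs$values)) {
      c0 <- runs$values[k] + 1L
      pad[c0] <- max(pad[c0], runs$lengths[k])
    }
  }
  # final column of each template column, and start of each pad slot
  shift <- cumsum(pad)                       # pads at/before slot after c
  col_of <- seq_len(tw) + shift[seq_len(tw)] # template col c -> final col
  slot_start <- c(0L, col_of) + 1L           # first pad col after template col c (index c+1)
  total <- tw + sum(pad)

  keep <- setdiff(seq_len(n), match(unaligned, records$id))
  out_reads <- vector("list", length(keep))
  maps <- vector("list", length(keep))
  for (oi in seq_along(keep)) {
    i <- keep[oi]
    bc <- placements[[i]]
    ac <- ins_after[[i]]
    bases <- strsplit(records$seq[i], "")[[1]]
    cols <- integer(length(bases))
    ins_count <- integer(tw + 1L)
    for (p in seq_along(bases)) {
      if (!is.na(bc[p])) {
        cols[p] <- col_of[bc[p]]
      } else {
        slot <- ac[p] + 1L
        ins_count[slot] <- ins_count[slot] + 1L
        cols[p] <- slot_start[slot] + ins_count[slot] - 1L
      }
    }
    vec <- rep(".", total)
    span <- range(cols)
    vec[span[1]:span[2]] <- "-"
    vec[cols] <- bases
    mask_pos <- masks[[records$id[i]]]
    out_reads[[oi]] <- masked_aligned_read(
      read_id = records$id[i], aligned = paste(vec, collapse = ""),
      abundance = ab[i],
      mask_columns = if (length(mask_pos)) cols[mask_pos] else integer(),
      original = records$seq[i])
    maps[[oi]] <- cols
  }
  names(maps) <- records$id[keep]
  list(reads = out_reads, maps = maps, n_columns = total,
       template_column_map = col_of, unaligned_ids = unaligned)
}

#' Abundance-sorted preclustering that skips masked columns
#'
#' Reads are sorted by abundance (descending; ties by longer unaligned
#' length, then lexicographic id) and processed most-abundant first as
#' candidate seeds. Each read is compared against the already-fixed seeds in
#' order and merged into the first seed from which it differs at no more
#' than `floor(diff_pct * unaligned length)` columns. Differences are
#' counted per column over the overlap of the two reads' aligned spans;
#' a column is skipped when it is masked in either read; an internal gap
#' against a base counts as a difference; terminal (leading/trailing) gap
#' columns are skipped. A merged read adopts its seed's sequence and its
#' abundance is added to the seed's; unmerged reads become seeds.
#'
#' @param mreads List of [masked_aligned_read] of equal aligned length.
#' @param diff_pct Mismatch budget as a fraction of the (less abundant)
#'   read's unaligned length.
#' @return List of class `cluster_result`: `map` (named character, read id
#'   -> seed id; a seed maps to itself), `clusters` (data.frame `seed_id`,
#'   `abundance`), `merge_log` (data.frame `read_id`, `seed_id`,
#'   `diffs_counted`, `diffs_skipped`), `order` (processing order of ids).
#' @export
precluster_masked <- function(mreads, diff_pct = 0.02) {
  n <- length(mreads)
  if (n == 0)
    return(structure(list(map = character(), clusters = data.frame(
      seed_id = character(), abundance = integer()),
      merge_log = data.frame(read_id = character(), seed_id = character(),
                             diffs_counted = integer(),
                             diffs_skipped = integer()),
      order = character()), class = "cluster_result"))
  widths <- vapply(mreads, function(r) nchar(r$aligned), 0L)
  if (length(unique(widths)) != 1) stop("aligned reads differ in length")
  L <- widths[1]

  ids <- vapply(mreads, function(r) r$read_id, "")
  ab <- vapply(mreads, function(r) r$abundance, 0L)
  ulen <- vapply(mreads, function(r) nchar(r$original), 0L)
  ord <- order(-ab, -ulen, ids)

  M <- matrix("", n, L)
  for (i in seq_len(n)) M[i, ] <- strsplit(mreads[[i]]$aligned, "")[[1]]
  M[M == "."] <- "-"
  is_base <- M != "-"
  starts <- apply(is_base, 1, function(z) which(z)[1])
  ends <- apply(is_base, 1, function(z) { w <- which(z); w[length(w)] })
  maskm <- matrix(FALSE, n, L)
  for (i in seq_len(n)) maskm[i, mreads[[i]]$mask_columns] <- TRUE

  seed_rows <- integer(0)
  seed_ab <- integer(0)
  map <- character(n); names(map) <- ids
  log_read <- character(0); log_seed <- character(0)
  log_diff <- integer(0); log_skip <- integer(0)

  for (i in ord) {
    budget <- floor(diff_pct * ulen[i])
    merged <- FALSE
    for (k in seq_along(seed_rows)) {
      s <- seed_rows[k]
      a <- max(starts[i], starts[s]); b <- min(ends[i], ends[s])
      if (a > b) next
      cols <- a:b
      differ <- M[i, cols] != M[s, cols]
      skip <- maskm[i, cols] | maskm[s, cols]
      diffs <- sum(differ & !skip)
      if (diffs <= budget) {
        map[ids[i]] <- ids[s]
        seed_ab[k] <- seed_ab[k] + ab[i]
        log_read <- c(log_read, ids[i]); log_seed <- c(log_seed, ids[s])
        log_diff <- c(log_diff, diffs)
        log_skip <- c(log_skip, sum(differ & skip))
        merged <- TRUE
        break
      }
    }
    if (!merged) {
      seed_rows <- c(seed_rows, i)
      seed_ab <- c(seed_ab, ab[i])
      map[ids[i]] <- ids[i]
    }
  }
  structure(list(
    map = map,
    clusters = data.frame(seed_id = ids[seed_rows], abundance = seed_ab,
                          stringsAsFactors = FALSE),
    merge_log = data.frame(read_id = log_read, seed_id = log_seed,
                           diffs_counted = log_diff,
                           diffs_skipped = log_skip,
                           stringsAsFactors = FALSE),
    order = ids[ord]), class = "cluster_result")
}

#' Restore masked positions and emit corrected reads
#'
#' Reads merged into a seed take the seed's sequence (their abundance is
#' already accumulated on the seed); unmerged reads — the seeds — are
#' emitted byte-identical to their pre-masking originals, so any masked
#' positions that never merged revert to the originally called nucleotides.
#'
#' @param result A `cluster_result` from [precluster_masked].
#' @param originals Named character vector mapping read id to the original
#'   unaligned sequence.
#' @return Data.frame of corrected reads: `id`, `seq`, `abundance` (total
#'   abundance equals the input total).
#' @export
restore_masks <- function(result, originals) {
  seeds <- result$clusters$seed_id
  miss <- setdiff(seeds, names(originals))
  if (length(miss))
    stop("missing original sequence for unmerged read '", miss[1], "'")
  data.frame(id = seeds, seq = unname(originals[seeds]),
             abundance = result$clusters$abundance,
             stringsAsFactors = FALSE)
}

# Dereplicate identical called sequences: abundance = copy count, masks
# transferred as the union over copies (a position flagged in any copy is
# treated as suspect for the unique sequence).
dereplicate_reads <- function(records, masks = NULL) {
  key <- records$seq
  first <- !duplicated(key)
  rep_id <- records$id[first][match(key, key[first])]
  ab <- if (is.null(records$abundance)) rep(1L, nrow(records)) else records$abundance
  agg_ab <- tapply(ab, rep_id, sum)
  out <- records[first, c("id", "seq"), drop = FALSE]
  out$abundance <- as.integer(agg_ab[out$id])
  merged_masks <- NULL
  if (!is.null(masks)) {
    merged_masks <- lapply(split(records$id, rep_id), function(members) {
      sort(unique(unlist(masks[members], use.names = FALSE)))
    })
    merged_masks <- merged_masks[out$id]
  }
  rownames(out) <- NULL
  list(records = out, masks = merged_masks,
       membership = stats::setNames(rep_id, records$id))
}
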