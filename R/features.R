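#' Annotate homopolymer position codes
#'
#' Length-preserving map over the called bases: `N` for a non-homopolymer
#' position, `A` and `Z` for the first and last position of a homopolymer
#' run, and `B`, `C`, `D`, ... for the second, third, fourth, ... interior
#' positions. A run of length 2 is coded `"AZ"`; the maximal permitted run
#' of 8 is `"ABCDEFGZ"`.
#'
#' @param bases DNA string over `{A,C,G,T,N}` with runs of at most 8 (basic
#'   trimming guarantees this).
#' @return Code string of the same length.
#' @export
annotate_homopolymers <- function(bases) {
  if (nchar(bases) == 0) return("")
  r <- rle(strsplit(bases, "")[[1]])
  if (any(r$lengths > 8L))
    stop("homopolymer run longer than 8 bases; apply basic_trim first")
  codes <- lapply(r$lengths, function(len) {
    if (len == 1L) "N"
    else if (len == 2L) c("A", "Z")
    else c("A", LETTERS[2:(len - 1L)], "Z")
  })
  paste(unlist(codes), collapse = "")
}

#' Highest uncalled flow signal between two adjacent bases
#'
#' The maximum flow value over the flows strictly between the calling flows
#' of two neighbouring bases — the strongest signal that did not result in a
#' base call. Zero when the calling flows are identical or adjacent.
#'
#' @param read A [flow_read].
#' @param base_i,base_j Adjacent 1-based base indices (`|base_i - base_j| == 1`).
#' @return Non-negative real, in flow units.
#' @export
max_uncalled_between <- function(read, base_i, base_j) {
  n <- nchar(read$bases)
  if (base_i < 1 || base_i > n || base_j < 1 || base_j > n)
    stop("base index out of range")
  if (abs(base_i - base_j) != 1L) stop("bases must be adjacent")
  fi <- read$flow_index_per_base[base_i]
  fj <- read$flow_index_per_base[base_j]
  lo <- min(fi, fj); hi <- max(fi, fj)
  if (hi - lo <= 1L) return(0)
  max(read$flow_values[(lo + 1L):(hi - 1L)])
}

#' Is a base position sensitive to carry-forward?
#'
#' TRUE iff a flow of the same nucleotide occurs among the flows strictly
#' between this base's calling flow and the previous called base's flow —
#' the nucleotide was flowed but uncalled immediately upstream, the
#' signature of a carry-forward artifact. The first base of a read uses the
#' flowgram start as its upstream boundary.
#'
#' @param read A [flow_read].
#' @param position 1-based base index.
#' @return Logical scalar.
#' @export
carry_forward_sensitive <- function(read, position) {
  n <- nchar(read$bases)
  if (position < 1 || position > n) stop("position out of range")
  fc <- strsplit(read$flow_chars, "")[[1]]
  base <- substr(read$bases, position, position)
  fi <- read$flow_index_per_base[position]
  lo <- if (position == 1L) 0L else read$flow_index_per_base[position - 1L]
  if (fi - lo <= 1L) return(FALSE)
  any(fc[(lo + 1L):(fi - 1L)] == base)
}

#' Extract the 13 per-position classifier attributes from a read
#'
#' For every called base: five attributes of the position itself (position
#' in the read, Phred score, homopolymer code, carry-forward sensitivity,
#' flow signal intensity at the calling flow) and eight derived from the
#' two neighbouring bases (their Phred scores, homopolymer codes, flow
#' intensities, and the highest uncalled flow signal between this base and
#' each neighbour). Missing neighbours at the read ends take sentinel
#' values: Phred -1, code `N`, intensity 0, max-uncalled 0.
#'
#' @param read A [flow_read] that passed basic trimming (no `N` bases,
#'   homopolymer runs of at most 8).
#' @return Data.frame with `read_id`, `position` and the 13 attribute
#'   columns, in the fixed schema order given by [feature_columns()].
#' @export
extract_features <- function(read) {
  if (grepl("N", read$bases, fixed = TRUE))
    stop("read '", read$read_id,
         "' contains ambiguous bases; apply basic_trim first")
  n <- nchar(read$bases)
  if (n == 0)
    return(cbind(data.frame(read_id = character(), position = integer()),
                 stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 13)),
                                 feature_columns())))
  fi <- read$flow_index_per_base
  fv <- read$flow_values
  hp <- strsplit(annotate_homopolymers(read$bases), "")[[1]]
  intensity <- fv[fi]
  cfs <- vapply(seq_len(n), function(p) carry_forward_sensitive(read, p), TRUE)
  # max uncalled flow value between consecutive bases (length n-1)
  gap_max <- if (n >= 2) {
    vapply(seq_len(n - 1L), function(p) {
      lo <- fi[p]; hi <- fi[p + 1L]
      if (hi - lo <= 1L) 0 else max(fv[(lo + 1L):(hi - 1L)])
    }, 0)
  } else numeric(0)

  data.frame(
    read_id = read$read_id,
    position = seq_len(n),
    phred = read$quals,
    homopolymer_code = hp,
    carry_forward = cfs,
    flow_intensity = intensity,
    prev_phred = c(-1L, read$quals[-n]),
    prev_homopolymer_code = c("N", hp[-n]),
    prev_flow_intensity = c(0, intensity[-n]),
    prev_max_uncalled = c(0, gap_max),
    next_phred = c(read$quals[-1L], -1L),
    next_homopolymer_code = c(hp[-1L], "N"),
    next_flow_intensity = c(intensity[-1L], 0),
    next_max_uncalled = c(gap_max, 0),
    stringsAsFactors = FALSE
  )
}

#' Fixed order of the 13 attribute columns
#' @return Character vector of the attribute column names.
#' @export
feature_columns <- function() {
  c("position", "phred", "homopolymer_code", "carry_forward",
    "flow_intensity", "prev_phred", "prev_homopolymer_code",
    "prev_flow_intensity", "prev_max_uncalled", "next_phred",
    "next_homopolymer_code", "next_flow_intensity", "next_max_uncalled")
}

#' Extract features for a set of reads
#' @param reads List of [flow_read] objects.
#' @return Row-bound data.frame of [extract_features] output.
#' @export
extract_features_set <- function(reads) {
  out <- do.call(rbind, lapply(reads, extract_features))
  rownames(out) <- NULL
  out
}

hp_code_levels <- c("N", "A", "B", "C", "D", "E", "F", "G", "Z")

# Encode the feature data.frame as a fixed numeric matrix for the kernel:
# homopolymer codes one-hot over the 9 levels, booleans as 0/1.
encode_features <- function(df) {
  onehot <- function(codes, prefix) {
    m <- outer(codes, hp_code_levels, `==`) * 1
    colnames(m) <- paste0(prefix, hp_code_levels)
    m
  }
  num <- cbind(position = df$position, phred = df$phred,
               carry_forward = as.numeric(df$carry_forward),
               flow_intensity = df$flow_intensity,
               prev_phred = df$prev_phred,
               prev_flow_intensity = df$prev_flow_intensity,
               prev_max_uncalled = df$prev_max_uncalled,
               next_phred = df$next_phred,
               next_flow_intensity = df$next_flow_intensity,
               next_max_uncalled = df$next_max_uncalled)
  cbind(num, onehot(df$homopolymer_code, "hp_"),
        onehot(df$prev_homopolymer_code, "prev_hp_"),
        onehot(df$next_homopolymer_code, "next_hp_"))
}
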