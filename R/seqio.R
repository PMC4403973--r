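#' Read sequence records with optional quality and abundance annotation
#'
#' Thin, lossless wrappers over the standard amplicon formats. Abundance
#' encoded in headers with the dereplication dialect `"id;size=N"` is parsed
#' when present (default abundance 1). Gap characters `-` and `.` are
#' preserved for `aligned-fasta`.
#'
#' @param path Input file path (the FASTA file for `fasta+qual`).
#' @param format One of `"fasta"`, `"fasta+qual"`, `"fastq"`,
#'   `"aligned-fasta"`.
#' @param qual_path Path to the `.qual` file when `format = "fasta+qual"`.
#' @return A data.frame with columns `id`, `seq`, `abundance` and, for
#'   quality-bearing formats, a list column `qual` of integer Phred vectors.
#' @export
read_sequences <- function(path,
                           format = c("fasta", "fasta+qual", "fastq",
                                      "aligned-fasta"),
                           qual_path = NULL) {
  format <- match.arg(format)
  if (format == "fastq") {
    # Biostrings notes dropped metadata columns on construction; benign here
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    ids <- names(x)
    seqs <- as.character(x)
    quals <- lapply(as(Biostrings::quality(x), "IntegerList"), as.integer)
  } else {
    x <- Biostrings::readBStringSet(path)
    ids <- names(x)
    seqs <- toupper(as.character(x))
    quals <- NULL
    if (format == "aligned-fasta") {
      if (length(unique(nchar(seqs))) > 1)
        stop("aligned-fasta records have unequal lengths")
    } else if (any(grepl("[-.]", seqs))) {
      stop("gap characters found; use format = \"aligned-fasta\"")
    }
  }
  ids <- sub("\\s.*$", "", ids)
  parsed <- parse_size_annotation(ids)
  out <- data.frame(id = parsed$id, seq = unname(seqs),
                    abundance = parsed$abundance,
                    stringsAsFactors = FALSE)
  if (format == "fastq") out$qual <- I(unname(quals))
  if (format == "fasta+qual") {
    if (is.null(qual_path)) stop("fasta+qual requires qual_path")
    q <- read_qual_file(qual_path)
    qparsed <- parse_size_annotation(names(q))
    if (!identical(qparsed$id, parsed$id))
      stop("FASTA and QUAL ids do not match")
    bad <- which(lengths(q) != nchar(out$seq))
    if (length(bad))
      stop("quality/sequence length mismatch for record '", out$id[bad[1]], "'")
    out$qual <- I(unname(q))
  }
  rownames(out) <- NULL
  out
}

#' Write sequence records
#'
#' Inverse of [read_sequences]: abundances other than 1 are encoded as
#' `"id;size=N"`; qualities are written Sanger Phred+33 for FASTQ and as
#' space-separated integers for QUAL.
#'
#' @param records Data.frame as returned by [read_sequences] (columns `id`,
#'   `seq`, optional `abundance` and `qual`).
#' @inheritParams read_sequences
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path,
                            format = c("fasta", "fasta+qual", "fastq",
                                       "aligned-fasta"),
                            qual_path = NULL) {
  format <- match.arg(format)
  ab <- if (is.null(records$abundance)) rep(1L, nrow(records)) else records$abundance
  ids <- ifelse(ab != 1L, paste0(records$id, ";size=", ab), records$id)
  if (format %in% c("fasta", "aligned-fasta")) {
    if (format == "aligned-fasta" && length(unique(nchar(records$seq))) > 1)
      stop("aligned-fasta records must have equal lengths")
    x <- Biostrings::BStringSet(records$seq)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path)
  } else if (format == "fastq") {
    if (is.null(records$qual)) stop("fastq requires a qual column")
    x <- Biostrings::DNAStringSet(records$seq)
    names(x) <- ids
    qstr <- vapply(records$qual,
                   function(q) rawToChar(as.raw(pmin(q, 93L) + 33L)), "")
    xq <- Biostrings::QualityScaledDNAStringSet(
      x, Biostrings::PhredQuality(qstr))
    Biostrings::writeQualityScaledXStringSet(xq, path)
  } else { # fasta+qual
    if (is.null(records$qual)) stop("fasta+qual requires a qual column")
    if (is.null(qual_path)) stop("fasta+qual requires qual_path")
    x <- Biostrings::BStringSet(records$seq)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path)
    lines <- character(2L * nrow(records))
    lines[c(TRUE, FALSE)] <- paste0(">", ids)
    lines[c(FALSE, TRUE)] <- vapply(records$qual,
                                    function(q) paste(q, collapse = " "), "")
    writeLines(lines, qual_path)
  }
  invisible(path)
}

parse_size_annotation <- function(ids) {
  has <- grepl(";size=\\d+;?$", ids)
  ab <- rep(1L, length(ids))
  ab[has] <- as.integer(sub("^.*;size=(\\d+);?$", "\\1", ids[has]))
  list(id = sub(";size=\\d+;?$", "", ids), abundance = ab)
}

# Minimal 454 .qual parser: FASTA-style headers, space-separated Phred ints.
read_qual_file <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no records in QUAL file: ", path)
  grp <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  vals <- lapply(split(lines[!hdr], grp[!hdr]), function(block) {
    as.integer(strsplit(paste(block, collapse = " "), "\\s+")[[1]] |>
                 (\(x) x[nzchar(x)])())
  })
  out <- vector("list", length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    key <- as.character(i)
    out[[i]] <- if (key %in% names(vals)) vals[[key]] else integer()
  }
  out
}

#' Convert flow reads to sequence records
#'
#' Extracts the called bases and qualities of a [flow_read] list into the
#' record data.frame used by [write_sequences] (abundance 1 per read).
#'
#' @param reads List of [flow_read] objects.
#' @return Data.frame with columns `id`, `seq`, `abundance`, `qual`.
#' @export
reads_to_records <- function(reads) {
  data.frame(
    id = vapply(reads, function(r) r$read_id, ""),
    seq = vapply(reads, function(r) r$bases, ""),
    abundance = 1L,
    qual = I(lapply(reads, function(r) r$quals)),
    stringsAsFactors = FALSE
  )
}
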