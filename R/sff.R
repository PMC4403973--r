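#' Read a Standard Flowgram Format (SFF) file
#'
#' Parses a Roche 454 SFF file (big-endian, magic `0x2E736666`, version 1)
#' into a list of [flow_read] objects. Stored flowgram values (hundredths)
#' are converted to flow units (stored 100 -> 1.00); the delta-encoded
#' per-base flow indices are accumulated to absolute 1-based indices. An
#' index section, when present, is skipped transparently.
#'
#' @param path Path to an SFF file.
#' @return List of [flow_read] objects (empty list for a record-less file).
#' @export
read_sff <- function(path) {
  if (!file.exists(path)) stop("SFF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  u8  <- function(n) readBin(con, "integer", n = n, size = 1, signed = FALSE,
                             endian = "big")
  u16 <- function(n = 1) readBin(con, "integer", n = n, size = 2,
                                 signed = FALSE, endian = "big")
  u32 <- function(n = 1) readBin(con, "integer", n = n, size = 4,
                                 signed = TRUE, endian = "big")
  chars <- function(n) if (n > 0) rawToChar(readBin(con, "raw", n)) else ""

  magic <- u32(1)
  if (length(magic) != 1 || magic != 0x2E736666L)
    stop("not an SFF file (bad magic number at offset 0): ", path)
  version <- u8(4)
  if (!identical(version, c(0L, 0L, 0L, 1L)))
    stop("unsupported SFF version at offset 4: ",
         paste(version, collapse = "."))
  index_offset_raw <- readBin(con, "raw", 8)
  index_offset <- sum(as.integer(index_offset_raw) * 256^(7:0))
  index_length <- u32(1)
  n_reads <- u32(1)
  header_length <- u16()
  key_length <- u16()
  n_flows <- u16()
  fmt_code <- u8(1)
  if (fmt_code != 1L) stop("unsupported flowgram format code: ", fmt_code)
  flow_chars <- chars(n_flows)
  key_sequence <- chars(key_length)
  consumed <- 31L + n_flows + key_length
  pad <- header_length - consumed
  if (pad < 0) stop("malformed SFF common header (header_length too small)")
  if (pad > 0) readBin(con, "raw", pad)

  reads <- vector("list", n_reads)
  for (k in seq_len(n_reads)) {
    # skip the index block if it sits between records
    if (index_offset > 0 && seek(con, NA) == index_offset) {
      skip <- index_length + (-index_length %% 8)
      readBin(con, "raw", skip)
    }
    rh_len <- u16()
    if (length(rh_len) == 0)
      stop("truncated SFF: record ", k, " of ", n_reads, " missing")
    name_len <- u16()
    n_bases <- u32(1)
    clips <- u16(4)
    name <- chars(name_len)
    rh_pad <- rh_len - (16L + name_len)
    if (rh_pad < 0) stop("malformed SFF read header in record ", k)
    if (rh_pad > 0) readBin(con, "raw", rh_pad)

    flow_raw <- u16(n_flows)
    idx_delta <- u8(n_bases)
    bases <- chars(n_bases)
    quals <- u8(n_bases)
    if (length(flow_raw) < n_flows || length(quals) < n_bases)
      stop("truncated SFF: record ", k, " (", name, ") incomplete")
    data_len <- 2L * n_flows + 3L * n_bases
    data_pad <- -data_len %% 8
    if (data_pad > 0) readBin(con, "raw", data_pad)

    reads[[k]] <- flow_read(
      read_id = name,
      flow_chars = flow_chars,
      flow_values = flow_raw / 100,
      flow_index_per_base = cumsum(idx_delta),
      bases = bases,
      quals = quals,
      clip_qual = clips[1:2],
      clip_adapter = clips[3:4]
    )
  }
  reads
}

#' Write flow reads to a Standard Flowgram Format (SFF) file
#'
#' Writes a spec-conformant big-endian SFF file (version 1, no index block)
#' readable by [read_sff] and by third-party SFF readers. Flow units are
#' rescaled to stored hundredths and clamped to the unsigned 16-bit range.
#'
#' @param reads List of [flow_read] objects sharing one flow order.
#' @param path Output file path.
#' @param key_sequence Key sequence recorded in the common header (the
#'   default, empty, means reads carry no key bases).
#' @return `path`, invisibly.
#' @export
write_sff <- function(reads, path, key_sequence = "") {
  flow_orders <- unique(vapply(reads, function(r) r$flow_chars, ""))
  if (length(flow_orders) > 1)
    stop("all reads must share one flow order; found ",
         length(flow_orders), " distinct orders")
  flow_chars <- if (length(flow_orders)) flow_orders else "TACG"
  n_flows <- nchar(flow_chars)

  con <- file(path, "wb")
  on.exit(close(con))
  w8  <- function(x) writeBin(as.integer(x), con, size = 1, endian = "big")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "big")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "big")

  key_length <- nchar(key_sequence)
  header_core <- 31L + n_flows + key_length
  header_length <- header_core + (-header_core %% 8)

  w32(0x2E736666L)                    # magic ".sff"
  w8(c(0L, 0L, 0L, 1L))               # version
  writeBin(raw(8), con)               # index_offset (none)
  w32(0L)                             # index_length
  w32(length(reads))
  w16(header_length)
  w16(key_length)
  w16(n_flows)
  w8(1L)                              # flowgram format code
  writeChar(flow_chars, con, eos = NULL)
  if (key_length > 0) writeChar(key_sequence, con, eos = NULL)
  if (header_length > header_core) writeBin(raw(header_length - header_core), con)

  for (r in reads) {
    n_bases <- nchar(r$bases)
    name_len <- nchar(r$read_id)
    rh_core <- 16L + name_len
    rh_len <- rh_core + (-rh_core %% 8)
    w16(rh_len)
    w16(name_len)
    w32(n_bases)
    w16(c(r$clip_qual, r$clip_adapter))
    if (name_len > 0) writeChar(r$read_id, con, eos = NULL)
    if (rh_len > rh_core) writeBin(raw(rh_len - rh_core), con)

    stored <- pmin(pmax(round(r$flow_values * 100), 0), 65535)
    w16(stored)
    deltas <- diff(c(0L, r$flow_index_per_base))
    if (any(deltas > 255L))
      stop("read '", r$read_id, "': flow index gap exceeds 255 flows, ",
           "not representable in SFF")
    w8(deltas)
    if (n_bases > 0) writeChar(r$bases, con, eos = NULL)
    w8(r$quals)
    data_len <- 2L * n_flows + 3L * n_bases
    data_pad <- -data_len %% 8
    if (data_pad > 0) writeBin(raw(data_pad), con)
  }
  invisible(path)
}
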