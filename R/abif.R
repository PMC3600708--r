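#' Read an ABIF (.fsa/.ab1) container into a trace
#'
#' Best-effort extraction of the four dye channels from an Applied
#' Biosystems ABIF file (the binary container written by capillary
#' genetic analyzers).  The big-endian tagged directory is parsed and the
#' `DATA` entries are taken as channels: analyzed streams 9-12 when
#' present, otherwise raw streams 1-4, mapped in order to FAM, HEX, NED,
#' ROX (filter set order; verify against the instrument's dye set).
#' This adapter is optional -- the package's canonical interchange format
#' is the plain TSV of [read_trace()] -- and unrecognized containers give
#' an error advising TSV conversion.
#'
#' @param path Path to an ABIF file.
#' @param channels Channel names assigned to the extracted streams.
#' @return An `msat_trace`.
#' @export
read_abif <- function(path, channels = c("FAM", "HEX", "NED", "ROX")) {
  con <- file(path, "rb")
  on.exit(close(con))
  fail <- function(...) stop(path, ": ", ..., "; convert to trace TSV ",
                             "(scan,FAM,HEX,NED,ROX) instead", call. = FALSE)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "ABIF")) fail("not an ABIF container")
  readBin(con, integer(), 1, size = 2, endian = "big")   # version
  ## header directory entry describing the directory itself
  hdr <- read_abif_entry(con)
  if (is.null(hdr) || hdr$name != "tdir") fail("missing ABIF directory")
  entries <- vector("list", hdr$numelements)
  for (i in seq_len(hdr$numelements)) {
    seek(con, hdr$dataoffset + (i - 1) * 28)
    entries[[i]] <- read_abif_entry(con)
    if (is.null(entries[[i]])) fail("truncated ABIF directory")
  }
  tags <- vapply(entries, function(e) e$name, character(1))
  nums <- vapply(entries, function(e) e$number, numeric(1))
  data_idx <- which(tags == "DATA")
  pick <- function(wanted) {
    sel <- data_idx[match(wanted, nums[data_idx])]
    if (anyNA(sel)) NULL else sel
  }
  sel <- pick(9:12) %||% pick(1:4)
  if (is.null(sel)) fail("no DATA channel quartet (9-12 or 1-4) found")
  streams <- lapply(entries[sel], function(e) {
    if (e$elementtype != 4L)  # int16 streams expected for DATA
      fail("unsupported DATA element type ", e$elementtype)
    seek(con, e$dataoffset)
    v <- readBin(con, integer(), e$numelements, size = 2, endian = "big")
    if (length(v) != e$numelements) fail("truncated DATA stream")
    v
  })
  n <- min(lengths(streams))
  df <- data.frame(scan = seq_len(n))
  for (i in seq_along(channels)) df[[channels[i]]] <- streams[[i]][seq_len(n)]
  class(df) <- c("msat_trace", "data.frame")
  df
}

read_abif_entry <- function(con) {
  name <- readChar(con, 4, useBytes = TRUE)
  if (length(name) == 0 || nchar(name) < 4) return(NULL)
  number <- readBin(con, integer(), 1, size = 4, endian = "big")
  elementtype <- readBin(con, integer(), 1, size = 2, endian = "big")
  elementsize <- readBin(con, integer(), 1, size = 2, endian = "big")
  numelements <- readBin(con, integer(), 1, size = 4, endian = "big")
  datasize <- readBin(con, integer(), 1, size = 4, endian = "big")
  dataoffset <- readBin(con, integer(), 1, size = 4, endian = "big")
  if (!length(dataoffset)) return(NULL)
  list(name = name, number = number, elementtype = elementtype,
       elementsize = elementsize, numelements = numelements,
       datasize = datasize, dataoffset = dataoffset)
}
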