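# Write a minimal big-endian ABIF container holding four int16 DATA
# streams, for exercising the optional instrument-file adapter.
write_minimal_abif <- function(path, streams, numbers = 9:12,
                               version = 101L) {
  stopifnot(length(streams) == length(numbers))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("ABIF", con, nchars = 4, eos = NULL)
  writeBin(as.integer(version), con, size = 2, endian = "big")

  write_entry <- function(name, number, elementtype, elementsize,
                          numelements, datasize, dataoffset) {
    writeChar(name, con, nchars = 4, eos = NULL)
    writeBin(as.integer(number), con, size = 4, endian = "big")
    writeBin(as.integer(elementtype), con, size = 2, endian = "big")
    writeBin(as.integer(elementsize), con, size = 2, endian = "big")
    writeBin(as.integer(numelements), con, size = 4, endian = "big")
    writeBin(as.integer(datasize), con, size = 4, endian = "big")
    writeBin(as.integer(dataoffset), con, size = 4, endian = "big")
    writeBin(0L, con, size = 4, endian = "big")   # datahandle
  }

  data_start <- 128L
  sizes <- vapply(streams, function(s) 2L * length(s), integer(1))
  offsets <- data_start + c(0L, cumsum(sizes))[seq_along(streams)]
  dir_offset <- data_start + sum(sizes)

  ## header directory entry describing the directory, then pad to 128
  write_entry("tdir", 1L, 1023L, 28L, length(streams),
              28L * length(streams), dir_offset)
  pad <- data_start - (4L + 2L + 28L)
  writeBin(raw(pad), con)
  for (s in streams) writeBin(as.integer(s), con, size = 2, endian = "big")
  for (i in seq_along(streams))
    write_entry("DATA", numbers[i], 4L, 2L, length(streams[[i]]),
                sizes[i], offsets[i])
  invisible(path)
}
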