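## Plain-text interchange formats.  Tabular files carry '#key=value'
## comment headers embedding provenance (panel, method, parameters, seed)
## so any output can be reproduced from its manifest line.

meta_header <- function(meta) {
  if (!length(meta)) return(character())
  paste0("#", names(meta), "=", vapply(meta, function(v)
    paste(format(v, trim = TRUE), collapse = ","), character(1)))
}

read_meta <- function(path) {
  lines <- readLines(path, n = 50)
  lines <- lines[startsWith(lines, "#")]
  if (!length(lines)) return(list())
  kv <- strsplit(sub("^#", "", lines), "=", fixed = TRUE)
  setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
           vapply(kv, `[`, character(1), 1))
}

write_table_meta <- function(df, path, meta = list(), sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(meta), con)
  write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a fluorescence trace as TSV
#'
#' One row per scan, columns `scan`, `FAM`, `HEX`, `NED`, `ROX`;
#' '#key=value' comment lines carry provenance metadata.
#'
#' @param trace An `msat_trace`.
#' @param path File path.
#' @param meta Named list of metadata values.
#' @return `read_trace()` returns an `msat_trace` with metadata in
#'   attribute `"meta"`.
#' @export
write_trace <- function(trace, path, meta = list()) {
  write_table_meta(trace, path, meta)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.delim(path, comment.char = "#")
  need <- c("scan", "FAM", "HEX", "NED", "ROX")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: trace TSV must have columns %s", path,
                 paste(need, collapse = ",")), call. = FALSE)
  if (any(diff(df$scan) <= 0))
    stop(path, ": scan column must be strictly increasing", call. = FALSE)
  class(df) <- c("msat_trace", "data.frame")
  attr(df, "meta") <- read_meta(path)
  df
}

#' Write / read a peak table as CSV
#'
#' Columns as produced by [detect_peaks()] (plus sizing columns after
#' [size_peaks()]).
#'
#' @inheritParams write_trace
#' @param peaks Peak data frame.
#' @return `read_peaks()` returns the data frame with metadata attribute.
#' @export
write_peaks <- function(peaks, path, meta = list()) {
  write_table_meta(peaks, path, meta, sep = ",")
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("channel", "apex_scan", "height") %in% names(df)))
    stop(path, ": not a peak table (need channel,apex_scan,height)",
         call. = FALSE)
  attr(df, "meta") <- read_meta(path)
  df
}

#' Write / read genotype truth tables as CSV
#'
#' One row per (subject, marker): columns `id`, `marker`, `a1`, `a2`
#' (template allele sizes in bp).
#'
#' @param genotypes List of `msat_genotype` objects.
#' @param path File path.
#' @param meta Named metadata list.
#' @return `read_genotypes()` returns a list of `msat_genotype`.
#' @export
write_genotypes <- function(genotypes, path, meta = list()) {
  if (inherits(genotypes, "msat_genotype")) genotypes <- list(genotypes)
  df <- do.call(rbind, lapply(genotypes, function(g)
    cbind(data.frame(id = g$id), g$alleles)))
  write_table_meta(df, path, meta, sep = ",")
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  lapply(split(df, df$id), function(d)
    new_genotype(d$id[1], data.frame(marker = d$marker, a1 = d$a1,
                                     a2 = d$a2)))
}

#' Write / read a genotype profile
#'
#' JSON document with the run id, group, flags, sizing method, ladder
#' fit RMSE, per-marker calls (sizes to 0.01 bp, integer bins) and any
#' provenance metadata.  A CSV flavour of the call table is produced by
#' `write_profile_csv()`.
#'
#' @param profile An `msat_profile`.
#' @param path File path.
#' @param meta Named metadata list.
#' @return `read_profile()` returns an `msat_profile`.
#' @export
write_profile <- function(profile, path, meta = list()) {
  calls <- profile$calls
  calls$size_bp <- round(calls$size_bp, 2)
  doc <- list(id = profile$id, group = profile$group,
              method = profile$method,
              ladder_rmse = profile$ladder_rmse,
              flags = as.list(profile$flags),
              calls = calls, meta = meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  calls <- if (length(doc$calls)) as.data.frame(doc$calls)
  else cbind(data.frame(marker = character()), empty_calls())
  p <- new_profile(doc$id, calls, flags = unlist(doc$flags) %||% character(),
                   group = doc$group, method = doc$method,
                   ladder_rmse = doc$ladder_rmse %||% NA_real_)
  p
}

#' @rdname write_profile
#' @export
write_profile_csv <- function(profile, path, meta = list()) {
  calls <- profile$calls
  calls$size_bp <- round(calls$size_bp, 2)
  df <- cbind(data.frame(run = profile$id), calls)
  df$flags <- paste(profile$flags, collapse = ";")
  write_table_meta(df, path, meta, sep = ",")
}
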