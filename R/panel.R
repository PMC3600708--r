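#' Analysis method parameters
#'
#' Container for the per-group analysis settings used throughout the
#' pipeline: peak detection algorithm label, sizing method, minimum peak
#' half-width (in scan points, per multiplex group), the mono cut-off for
#' mononucleotide allele calling, the per-dye range filters, the peak
#' height threshold and the dinucleotide stutter filter threshold.
#'
#' Range filters are *exclusion* intervals: a sized peak whose size falls
#' inside the closed interval for its dye and group is removed before
#' marker assignment.  For the built-in panel each filter spans exactly the
#' gap between the two same-dye marker windows of its group, so
#' bleed-through and nonspecific products landing between markers are
#' discarded while in-window peaks are untouched.
#'
#' @param peak_algorithm Label for the detection algorithm ("advanced").
#' @param sizing_method One of "local_southern", "global_southern",
#'   "cubic_ls".
#' @param min_peak_half_width Named numeric, minimum half-width at half
#'   height in scan points per group (group "1" = 4, group "2" = 2).
#' @param mono_cutoff Height-ratio threshold for additional mononucleotide
#'   alleles; peaks with ratio strictly greater than this are called.
#' @param range_filters Data frame with columns `group`, `dye`, `min_bp`,
#'   `max_bp`: closed exclusion intervals in base pairs.
#' @param peak_height_threshold Minimum baseline-corrected peak height in
#'   fluorescence units.
#' @param stutter_threshold Dinucleotide stutter filter: a peak one repeat
#'   unit below a taller peak with height ratio at or below this value is
#'   discarded before allele selection.
#' @return A list of class `msat_params`.
#' @export
analysis_params <- function(peak_algorithm = "advanced",
                            sizing_method = c("local_southern",
                                              "global_southern", "cubic_ls"),
                            min_peak_half_width = c("1" = 4, "2" = 2),
                            mono_cutoff = 0.95,
                            range_filters = builtin_range_filters(),
                            peak_height_threshold = 50,
                            stutter_threshold = 0.8) {
  sizing_method <- match.arg(sizing_method)
  stopifnot(mono_cutoff > 0, mono_cutoff < 1,
            all(min_peak_half_width >= 1),
            peak_height_threshold > 0,
            stutter_threshold > 0, stutter_threshold < 1)
  if (nrow(range_filters)) {
    stopifnot(all(c("group", "dye", "min_bp", "max_bp") %in%
                    names(range_filters)),
              all(range_filters$min_bp <= range_filters$max_bp))
  }
  structure(list(peak_algorithm = peak_algorithm,
                 sizing_method = sizing_method,
                 min_peak_half_width = min_peak_half_width,
                 mono_cutoff = mono_cutoff,
                 range_filters = range_filters,
                 peak_height_threshold = peak_height_threshold,
                 stutter_threshold = stutter_threshold),
            class = "msat_params")
}

#' Per-dye range filters of the built-in analysis method
#'
#' Closed exclusion intervals in bp; peaks inside are removed before
#' marker assignment (dye colour mapping: blue = FAM, green = HEX,
#' yellow = NED).
#'
#' @return Data frame with columns `group`, `dye`, `min_bp`, `max_bp`.
#' @export
builtin_range_filters <- function() {
  data.frame(
    group  = c(1L, 1L, 1L, 2L, 2L, 2L),
    dye    = c("FAM", "HEX", "NED", "FAM", "HEX", "NED"),
    min_bp = c(146, 136, 116, 181, 151, 131),
    max_bp = c(194, 159, 174, 250, 199, 174)
  )
}

builtin_markers <- function() {
  m <- data.frame(
    name        = c("BAT25", "BAT26", "D3S3623", "D5S346", "D6S262",
                    "D7S481", "D2S123", "D3S1262", "D9S171", "D17S250",
                    "D18S61"),
    group       = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L),
    dye         = c("FAM", "HEX", "FAM", "NED", "HEX", "NED",
                    "HEX", "HEX", "NED", "NED", "FAM"),
    window_min  = c(115, 105, 200, 70, 160, 175, 200, 120, 100, 175, 145),
    window_max  = c(145, 135, 230, 115, 190, 205, 240, 150, 130, 210, 180),
    repeat_unit = c(1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),
    product_min = c(130, 120, 207, NA, 167, 181, 203, 132, 102, 188, 150),
    product_max = c(130, 120, 223, NA, 183, 199, 233, 146, 122, 203, 176),
    primer_conc = c(0.25, 2.00, 0.25, NA, 0.50, 0.50, 1.00, 2.00, 0.25,
                    0.50, 0.50)
  )
  m
}

#' Default integer bins for a marker table
#'
#' Bin centers cover each marker window on its repeat lattice.  With full
#' adenylation (+A) apparent fragment sizes sit one nucleotide above the
#' template lattice, so dinucleotide centers start at `window_min + 1` and
#' step by 2, absorbing the +1 shift; mononucleotide centers are every
#' integer in the window.
#'
#' @param markers Marker data frame (see [builtin_panel()]).
#' @param max_offset Maximum bin offset in bp (default 0.5).
#' @return Named list: per marker a list with `centers` and `max_offset`.
#' @export
default_bins <- function(markers, max_offset = 0.5) {
  bins <- lapply(seq_len(nrow(markers)), function(i) {
    u <- markers$repeat_unit[i]
    lo <- markers$window_min[i]
    hi <- markers$window_max[i]
    centers <- if (u == 1L) seq(lo, hi, by = 1) else seq(lo + 1, hi, by = 2)
    bin_set(centers, max_offset = max_offset, marker = markers$name[i])
  })
  names(bins) <- markers$name
  bins
}

#' The built-in 11-marker multiplex panel
#'
#' Assay definition for two multiplex PCR groups: group 1 carries Bat25,
#' Bat26, D3S3623, D5S346, D6S262 and D7S481 (six markers), group 2
#' carries D2S123, D3S1262, D9S171, D17S250 and D18S61 (five markers).
#' Each marker records its dye (FAM/HEX/NED), parameter window, repeat
#' unit length, expected PCR product size range (absent for D5S346) and
#' primer concentration.  The panel bundles the analysis method
#' parameters, the GS500 ROX internal size standard and default integer
#' bins per marker.
#'
#' @param params Analysis parameters, see [analysis_params()].
#' @param ladder Internal size-standard specification, see [gs500_ladder()].
#' @return A list of class `msat_panel` with elements `markers` (data
#'   frame), `params`, `ladder`, `bins`, `name` and `version`.
#' @export
#' @examples
#' p <- builtin_panel()
#' nrow(p$markers)       # 11
#' table(p$markers$group)
builtin_panel <- function(params = analysis_params(),
                          ladder = gs500_ladder()) {
  markers <- builtin_markers()
  panel <- structure(list(name = "msatools-11plex",
                          version = "1.0",
                          markers = markers,
                          params = params,
                          ladder = ladder,
                          bins = default_bins(markers)),
                     class = "msat_panel")
  check_panel(panel)
  panel
}

## Structural invariants; stop() with the offending fields on violation.
check_panel <- function(panel) {
  m <- panel$markers
  bad <- character()
  if (anyDuplicated(m$name)) bad <- c(bad, "markers$name: duplicated")
  if (any(m$window_min >= m$window_max))
    bad <- c(bad, "window_min/window_max: window_min must be < window_max")
  if (!all(m$repeat_unit %in% c(1L, 2L)))
    bad <- c(bad, "repeat_unit: must be 1 or 2")
  if (!all(m$dye %in% c("FAM", "HEX", "NED")))
    bad <- c(bad, "dye: must be FAM, HEX or NED")
  pr <- !is.na(m$product_min)
  if (any(pr & (m$product_min < m$window_min - 15 |
                  m$product_max > m$window_max + 15)))
    bad <- c(bad, "product range: outside window +/- 15 bp")
  rf <- panel$params$range_filters
  key <- paste(m$group, m$dye)
  if (!all(key %in% paste(rf$group, rf$dye)))
    bad <- c(bad, "range_filters: missing dye/group combination")
  for (i in seq_len(nrow(m))) {
    f <- rf[rf$group == m$group[i] & rf$dye == m$dye[i], ]
    if (nrow(f) && m$window_min[i] <= f$max_bp && m$window_max[i] >= f$min_bp)
      bad <- c(bad, sprintf("range_filters: %s window overlaps %s/%d filter",
                            m$name[i], m$dye[i], m$group[i]))
  }
  for (nm in names(panel$bins)) {
    b <- panel$bins[[nm]]
    w <- m[m$name == nm, , drop = FALSE]
    if (nrow(w) != 1) next   # duplicate/missing marker reported above
    if (any(b$centers < w$window_min | b$centers > w$window_max))
      bad <- c(bad, sprintf("bins$%s: centers outside marker window", nm))
    if (b$max_offset <= 0 || b$max_offset > w$repeat_unit / 2)
      bad <- c(bad, sprintf("bins$%s: max_offset outside (0, unit/2]", nm))
  }
  if (length(bad))
    stop("malformed panel:\n  ", paste(bad, collapse = "\n  "), call. = FALSE)
  invisible(panel)
}

#' @export
print.msat_panel <- function(x, ...) {
  cat(sprintf("<msat_panel '%s' v%s: %d markers, %d groups>\n",
              x$name, x$version, nrow(x$markers),
              length(unique(x$markers$group))))
  print(x$markers[, c("name", "group", "dye", "window_min", "window_max",
                      "repeat_unit")], row.names = FALSE)
  invisible(x)
}

#' Validate panel design rules
#'
#' Checks, per multiplex group and dye, the minimum size gap between
#' same-dye markers, flagging pairs closer than `min_gap` (the assay was
#' designed so that same-dye products are at least 40 nt apart), and flags
#' marker windows that fall outside the interpolation range of the
#' internal size standard.
#'
#' @param panel An `msat_panel`.
#' @param basis Which size ranges to compare: `"product_ranges"` (Table of
#'   expected PCR product sizes; markers without a recorded product range
#'   are skipped) or `"marker_windows"` (the wider parameter windows).
#' @param min_gap Minimum allowed gap in nucleotides (default 40).
#' @return A list of class `msat_validation` with a per-pair `gaps` data
#'   frame (`group`, `dye`, `marker_a`, `marker_b`, `gap`, `pass`), the
#'   overall `min_gap` observed, `pass` (all gaps ok), `skipped` markers
#'   and a `window_range` data frame flagging windows outside the ladder
#'   interpolation interval.
#' @export
validate_panel <- function(panel,
                           basis = c("product_ranges", "marker_windows"),
                           min_gap = 40) {
  basis <- match.arg(basis)
  check_panel(panel)
  m <- panel$markers
  if (basis == "product_ranges") {
    lo <- m$product_min; hi <- m$product_max
  } else {
    lo <- m$window_min; hi <- m$window_max
  }
  skipped <- m$name[is.na(lo)]
  keep <- !is.na(lo)
  gaps <- do.call(rbind, lapply(split(which(keep),
                                      paste(m$group[keep], m$dye[keep])),
    function(idx) {
      if (length(idx) < 2) return(NULL)
      idx <- idx[order(lo[idx])]
      i <- idx[-length(idx)]; j <- idx[-1]
      data.frame(group = m$group[i], dye = m$dye[i],
                 marker_a = m$name[i], marker_b = m$name[j],
                 gap = lo[j] - hi[i])
    }))
  if (is.null(gaps))
    gaps <- data.frame(group = integer(), dye = character(),
                       marker_a = character(), marker_b = character(),
                       gap = numeric())
  rownames(gaps) <- NULL
  gaps$pass <- gaps$gap >= min_gap
  ## Local Southern needs two standards on each side, so the usable
  ## interval excludes the outermost ladder fragment on each end.
  sizes <- panel$ladder$sizes
  interp <- c(sizes[2], sizes[length(sizes) - 1])
  wr <- data.frame(name = m$name,
                   inside = m$window_min >= interp[1] &
                     m$window_max <= interp[2])
  structure(list(basis = basis, gaps = gaps,
                 min_gap = if (nrow(gaps)) min(gaps$gap) else NA_real_,
                 required_gap = min_gap,
                 pass = all(gaps$pass) && all(wr$inside),
                 skipped = skipped, window_range = wr),
            class = "msat_validation")
}

#' @export
print.msat_validation <- function(x, ...) {
  cat(sprintf("<msat_validation basis=%s: %s (min same-dye gap %s nt, need >= %d)>\n",
              x$basis, if (x$pass) "PASS" else "FLAGGED",
              format(x$min_gap), x$required_gap))
  if (nrow(x$gaps)) print(x$gaps, row.names = FALSE)
  if (length(x$skipped))
    cat("skipped (no size range):", paste(x$skipped, collapse = ", "), "\n")
  if (!all(x$window_range$inside))
    cat("windows outside ladder interpolation range:",
        paste(x$window_range$name[!x$window_range$inside], collapse = ", "),
        "\n")
  invisible(x)
}

#' Write / read a panel as JSON
#'
#' Serializes the complete panel (markers, analysis parameters, ladder and
#' bins) to a single JSON document with sizes in bp and primer
#' concentrations in micromolar.  `read_panel()` restores an identical
#' `msat_panel`.
#'
#' @param panel An `msat_panel`.
#' @param path File path.
#' @return `read_panel()` returns the panel; `write_panel()` the path,
#'   invisibly.
#' @export
write_panel <- function(panel, path) {
  check_panel(panel)
  doc <- list(
    name = panel$name, version = panel$version, units = "bp",
    markers = panel$markers,
    params = list(
      peak_algorithm = panel$params$peak_algorithm,
      sizing_method = panel$params$sizing_method,
      min_peak_half_width = as.list(panel$params$min_peak_half_width),
      mono_cutoff = panel$params$mono_cutoff,
      range_filters = panel$params$range_filters,
      peak_height_threshold = panel$params$peak_height_threshold,
      stutter_threshold = panel$params$stutter_threshold
    ),
    ladder = list(dye = panel$ladder$dye, sizes = panel$ladder$sizes),
    bins = lapply(panel$bins, function(b)
      list(centers = b$centers, max_offset = b$max_offset))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  mhw <- unlist(doc$params$min_peak_half_width)
  params <- analysis_params(
    peak_algorithm = doc$params$peak_algorithm,
    sizing_method = doc$params$sizing_method,
    min_peak_half_width = mhw,
    mono_cutoff = doc$params$mono_cutoff,
    range_filters = doc$params$range_filters,
    peak_height_threshold = doc$params$peak_height_threshold,
    stutter_threshold = doc$params$stutter_threshold)
  markers <- doc$markers
  markers$group <- as.integer(markers$group)
  markers$repeat_unit <- as.integer(markers$repeat_unit)
  bins <- lapply(names(doc$bins), function(nm)
    bin_set(doc$bins[[nm]]$centers, doc$bins[[nm]]$max_offset, marker = nm))
  names(bins) <- names(doc$bins)
  panel <- structure(list(name = doc$name, version = doc$version,
                          markers = markers, params = params,
                          ladder = ladder_spec(doc$ladder$sizes,
                                               dye = doc$ladder$dye),
                          bins = bins),
                     class = "msat_panel")
  check_panel(panel)
  panel
}
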