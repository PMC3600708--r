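#' Bin set for one marker
#'
#' Integer bin centers on the marker's repeat lattice with a maximum
#' offset: a fragment is assigned the nearest center within
#' `max_offset` bp (default 0.5, allowing up to one nucleotide of
#' experimental variation per fragment size).
#'
#' @param centers Integer bp values (dinucleotide markers: 2 apart;
#'   mononucleotide: 1 apart).
#' @param max_offset Maximum offset in bp, in `(0, lattice spacing / 2]`.
#' @param marker Optional marker name.
#' @return A list of class `msat_bins`.
#' @export
bin_set <- function(centers, max_offset = 0.5, marker = NULL) {
  centers <- sort(as.numeric(centers))
  stopifnot(length(centers) >= 1, max_offset > 0)
  if (length(centers) > 1) {
    spacing <- min(diff(centers))
    if (max_offset > spacing / 2 + 1e-9)
      stop("max_offset exceeds half the bin spacing", call. = FALSE)
  }
  structure(list(marker = marker, centers = centers,
                 max_offset = max_offset), class = "msat_bins")
}

#' Assign fragment sizes to bins
#'
#' Returns the nearest bin center within `max_offset` of each size, `NA`
#' if none qualifies.  An exact tie between two centers is broken toward
#' the lower center.
#'
#' @param size_bp Numeric vector of sizes.
#' @param bins An `msat_bins`.
#' @return Numeric vector of bin labels (center values), `NA` = unbinned.
#' @export
assign_bin <- function(size_bp, bins) {
  centers <- bins$centers
  vapply(size_bp, function(s) {
    if (is.na(s)) return(NA_real_)
    d <- abs(centers - s)
    j <- which(d == min(d))[1]        # ties: lower center (sorted)
    if (d[j] <= bins$max_offset + 1e-12) centers[j] else NA_real_
  }, numeric(1))
}

#' Apply the per-dye range filters
#'
#' Removes sized peaks whose size falls inside the closed exclusion
#' interval configured for their dye and group (the analysis method's
#' "range filter" setting).  For the built-in panel these intervals occupy the
#' gaps between same-dye marker windows, so bleed-through images of HEX
#' markers in the FAM channel and other between-marker artifacts are
#' discarded before marker assignment.  Unsized peaks pass through
#' untouched (they are excluded later by marker windows).
#'
#' @param sized_peaks Data frame from [size_peaks()].
#' @param params [analysis_params()].
#' @param group Multiplex group.
#' @return The retained peaks.
#' @export
range_filter <- function(sized_peaks, params, group) {
  rf <- params$range_filters
  rf <- rf[rf$group == group, , drop = FALSE]
  if (!nrow(sized_peaks) || !nrow(rf)) return(sized_peaks)
  drop <- rep(FALSE, nrow(sized_peaks))
  for (i in seq_len(nrow(rf))) {
    drop <- drop | (sized_peaks$channel == rf$dye[i] &
                      !is.na(sized_peaks$size_bp) &
                      sized_peaks$size_bp >= rf$min_bp[i] &
                      sized_peaks$size_bp <= rf$max_bp[i])
  }
  out <- sized_peaks[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_calls <- function() {
  data.frame(size_bp = numeric(), bin = numeric(), height = numeric(),
             ratio = numeric(), rank = integer())
}

finish_calls <- function(sel) {
  if (!nrow(sel)) return(empty_calls())
  sel <- sel[order(-sel$height, sel$size_bp), , drop = FALSE]
  sel$ratio <- sel$height / sel$height[1]
  sel$rank <- seq_len(nrow(sel))
  rownames(sel) <- NULL
  sel[, c("size_bp", "bin", "height", "ratio", "rank")]
}

#' Mononucleotide allele calling (mono cut-off rule)
#'
#' The highest peak among the stutter peaks is allele 1; every other peak
#' whose height ratio to allele 1 is strictly greater than `mono_cutoff`
#' (>95% of the maximum peak height with the default 0.95) is an
#' additional allele.  A height tie for the tallest peak is broken toward
#' the smaller size.  Whenever any in-window peak exists at least one
#' allele is returned.
#'
#' @param marker_peaks Sized, filtered peaks within the marker window
#'   (columns `size_bp`, `height`).
#' @param mono_cutoff Height-ratio threshold (default 0.95); the boundary
#'   ratio exactly equal to the cut-off is not called.
#' @param bins Optional `msat_bins` for bin labels.
#' @return Calls data frame: `size_bp`, `bin`, `height`, `ratio`, `rank`.
#' @export
call_mono <- function(marker_peaks, mono_cutoff = 0.95, bins = NULL) {
  if (is.null(marker_peaks) || !nrow(marker_peaks)) return(empty_calls())
  p <- as.data.frame(marker_peaks)
  p <- p[order(-p$height, p$size_bp), , drop = FALSE]
  hmax <- p$height[1]
  sel <- p[p$height / hmax > mono_cutoff | seq_len(nrow(p)) == 1L, ,
           drop = FALSE]
  sel$bin <- if (!is.null(bins)) assign_bin(sel$size_bp, bins)
  else round(sel$size_bp)
  finish_calls(sel)
}

#' Dinucleotide allele calling with stutter filtering
#'
#' A peak lying one repeat unit below a taller peak with height ratio at
#' or below `stutter_threshold` is discarded as stutter (comparisons use
#' the original, pre-discard heights so whole stutter ladders cascade
#' away).  The surviving peaks are assigned to bins; among binned
#' survivors the tallest is allele 1 and the second tallest, if any,
#' allele 2.  No binned survivor means a no-call.
#'
#' @param marker_peaks Sized, filtered peaks within the marker window.
#' @param bins An `msat_bins` for the marker.
#' @param stutter_threshold Height-ratio threshold (default 0.8): true
#'   heterozygotes one repeat apart have near-equal peaks and are
#'   retained, typical stutter (ratio well below 0.8) is removed.
#' @param repeat_unit Repeat unit length in bp (default 2).
#' @param tol Size tolerance when testing the one-repeat-below relation.
#' @return Calls data frame as in [call_mono()] (at most two rows).
#' @export
call_dinucleotide <- function(marker_peaks, bins, stutter_threshold = 0.8,
                              repeat_unit = 2, tol = 0.6) {
  if (is.null(marker_peaks) || !nrow(marker_peaks)) return(empty_calls())
  p <- as.data.frame(marker_peaks)
  is_stutter <- vapply(seq_len(nrow(p)), function(i) {
    above <- abs(p$size_bp - (p$size_bp[i] + repeat_unit)) <= tol &
      p$height > p$height[i]
    any(above & p$height[i] / p$height <= stutter_threshold, na.rm = TRUE)
  }, logical(1))
  sel <- p[!is_stutter, , drop = FALSE]
  sel$bin <- assign_bin(sel$size_bp, bins)
  sel <- sel[!is.na(sel$bin), , drop = FALSE]
  if (!nrow(sel)) return(empty_calls())
  ## one call per bin (tallest), then the two tallest bins
  sel <- sel[order(-sel$height), , drop = FALSE]
  sel <- sel[!duplicated(sel$bin), , drop = FALSE]
  finish_calls(utils::head(sel, 2L))
}

new_profile <- function(id, calls, flags = character(), group = NA,
                        method = NA_character_, ladder_rmse = NA_real_) {
  structure(list(id = id, group = group, calls = calls, flags = flags,
                 method = method, ladder_rmse = ladder_rmse),
            class = "msat_profile")
}

#' @export
print.msat_profile <- function(x, ...) {
  cat(sprintf("<msat_profile '%s' group %s: %d calls%s>\n", x$id,
              paste(x$group, collapse = "+"), nrow(x$calls),
              if (length(x$flags)) paste0("; flags: ",
                                          paste(x$flags, collapse = ", "))
              else ""))
  if (nrow(x$calls)) print(x$calls, row.names = FALSE)
  invisible(x)
}

#' Genotype one electrophoresis run
#'
#' Full calling pipeline for a single trace (or pre-detected peak table):
#' peak detection, ladder matching, fragment sizing, range filtering,
#' marker window assignment and per-marker allele calling (mono cut-off
#' rule for mononucleotide markers, stutter-aware two-allele selection
#' for dinucleotide markers).  Deterministic given its inputs.  A ladder
#' failure yields a run-level no-call profile flagged `ladder_failure`
#' rather than an error.
#'
#' @param x An `msat_trace`, or a peak data frame from [detect_peaks()]
#'   (must include the ladder channel peaks).
#' @param panel An `msat_panel`.
#' @param group Multiplex group of the run.
#' @param method Sizing method (default the panel's configured method).
#' @param bins Per-marker bins (default the panel's).
#' @param id Run identifier recorded on the profile.
#' @param strict_ladder Passed to [match_ladder()].
#' @param size_correction Constant bp offset added to sized peaks before
#'   filtering and binning -- the hook for an inter-run correction factor
#'   derived from control samples.  Off (0) by default: the assay
#'   deliberately measures total variation without it.
#' @return An `msat_profile`: `id`, `group`, `calls` data frame (`marker`,
#'   `size_bp`, `bin`, `height`, `ratio`, `rank`), `flags` (character:
#'   `ladder_failure`, `<marker>:no_call`, `<marker>:nonspecific`,
#'   `<marker>:unequal_amplification`, `<marker>:instability`),
#'   `method`, `ladder_rmse`.
#' @export
genotype_run <- function(x, panel, group = 1, method = NULL,
                         bins = panel$bins, id = "run1",
                         strict_ladder = TRUE, size_correction = 0) {
  params <- panel$params
  method <- method %||% params$sizing_method
  peaks <- if (inherits(x, "msat_trace")) detect_peaks(x, params, group)
  else as.data.frame(x)
  no_call <- function(flag) {
    calls <- cbind(data.frame(marker = character()), empty_calls())
    new_profile(id, calls, flags = flag, group = group, method = method)
  }
  rox <- peaks[peaks$channel == panel$ladder$dye, , drop = FALSE]
  fit <- tryCatch(match_ladder(rox, panel$ladder, strict = strict_ladder),
                  error = function(e) e)
  if (inherits(fit, "error")) return(no_call("ladder_failure"))
  analyte <- peaks[peaks$channel != panel$ladder$dye, , drop = FALSE]
  sized <- size_peaks(analyte, fit, method)
  sized$size_bp <- sized$size_bp + size_correction
  kept <- range_filter(sized[sized$sized, , drop = FALSE], params, group)

  m <- panel$markers[panel$markers$group == group, , drop = FALSE]
  flags <- character()
  calls <- lapply(seq_len(nrow(m)), function(i) {
    w <- kept[kept$channel == m$dye[i] &
                kept$size_bp >= m$window_min[i] &
                kept$size_bp <= m$window_max[i], , drop = FALSE]
    b <- bins[[m$name[i]]]
    cl <- if (m$repeat_unit[i] == 1L)
      call_mono(w, params$mono_cutoff, bins = b)
    else
      call_dinucleotide(w, b, params$stutter_threshold,
                        repeat_unit = m$repeat_unit[i])
    nm <- m$name[i]
    if (!nrow(cl)) flags <<- c(flags, paste0(nm, ":no_call"))
    if (m$repeat_unit[i] == 1L && nrow(cl) > 2L)
      flags <<- c(flags, paste0(nm, ":instability"))
    if (m$repeat_unit[i] == 2L && nrow(w) && any(is.na(assign_bin(
      w$size_bp[w$height >= max(w$height) * 0.5], b))))
      flags <<- c(flags, paste0(nm, ":nonspecific"))
    if (nrow(cl) == 2L && cl$ratio[2] < 0.5)
      flags <<- c(flags, paste0(nm, ":unequal_amplification"))
    if (nrow(cl)) cbind(data.frame(marker = nm), cl) else NULL
  })
  calls <- do.call(rbind, calls[!vapply(calls, is.null, logical(1))])
  if (is.null(calls)) calls <- cbind(data.frame(marker = character()),
                                     empty_calls())
  rownames(calls) <- NULL
  new_profile(id, calls, flags = flags, group = group, method = method,
              ladder_rmse = fit$rmse)
}

#' Perfect-call profile from a ground-truth genotype
#'
#' Converts a simulator genotype into the profile an error-free pipeline
#' would report: apparent size = template allele + `shift` (the
#' adenylation offset), one call per distinct allele with heights set to
#' a nominal constant.  Used as reference/expected profile in QC and
#' downstream analyses.
#'
#' @param genotype An `msat_genotype`.
#' @param panel An `msat_panel`.
#' @param shift Apparent-size lattice shift (default +1, full
#'   adenylation).
#' @param height Nominal call height.
#' @return An `msat_profile`.
#' @export
profile_from_truth <- function(genotype, panel, shift = 1, height = 2000) {
  rows <- lapply(seq_len(nrow(genotype$alleles)), function(i) {
    g <- genotype$alleles[i, ]
    sizes <- unique(c(g$a1, g$a2)) + shift
    data.frame(marker = g$marker, size_bp = sizes, bin = round(sizes),
               height = height, ratio = 1,
               rank = seq_along(sizes))
  })
  calls <- do.call(rbind, rows)
  groups <- sort(unique(panel$markers$group[match(calls$marker,
                                                  panel$markers$name)]))
  new_profile(genotype$id, calls, group = groups, method = "truth")
}
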