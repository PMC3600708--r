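#' Detect apex peaks in an electropherogram
#'
#' Baseline-corrected local-maximum detection per dye channel with
#' minimum-half-width filtering.  The baseline is a running minimum over a
#' wide centred window, interpolated and smoothed; candidate apexes are
#' local maxima of a 5-point moving average of the corrected signal;
#' apex position is refined to sub-scan precision by quadratic
#' interpolation of log intensity (exact for Gaussian pulses), and apex
#' height is the 3-point median around the apex so a one-scan electrical
#' impulse riding on a genuine peak cannot inflate the measured height.
#' Peak half-width (half width at half height,
#' in scan points, by linear interpolation on the raw corrected signal)
#' must reach the group's minimum (group 1: 4 points, group 2: 2 points),
#' which rejects one-scan electrical spikes while retaining genuine
#' amplicon peaks.
#'
#' @param trace An `msat_trace` (or data frame with `scan` plus channel
#'   columns).
#' @param params Analysis parameters ([analysis_params()]).
#' @param group Multiplex group (selects the minimum peak half-width).
#' @param channels Channels to scan (default all four).
#' @return Data frame with columns `channel`, `apex_scan`, `height`,
#'   `half_width_points`, `area`, sorted by channel then scan.  A flat or
#'   empty trace yields zero rows.
#' @export
detect_peaks <- function(trace, params = analysis_params(), group = 1,
                         channels = c("FAM", "HEX", "NED", "ROX")) {
  stopifnot(is.data.frame(trace), "scan" %in% names(trace))
  min_hw <- params$min_peak_half_width[[as.character(group)]]
  if (is.null(min_hw)) stop("no minimum peak half width for group ", group)
  channels <- intersect(channels, names(trace))
  out <- lapply(channels, function(ch) {
    pk <- detect_channel(trace[[ch]], threshold = params$peak_height_threshold,
                         min_hw = min_hw)
    if (nrow(pk)) pk$channel <- ch
    pk
  })
  out <- do.call(rbind, out[vapply(out, nrow, integer(1)) > 0])
  if (is.null(out))
    return(data.frame(channel = character(), apex_scan = numeric(),
                      height = numeric(), half_width_points = numeric(),
                      area = numeric()))
  ## apex_scan is reported on the trace's own scan axis
  out$apex_scan <- out$apex_scan + trace$scan[1] - 1
  rownames(out) <- NULL
  out[order(out$channel, out$apex_scan),
      c("channel", "apex_scan", "height", "half_width_points", "area")]
}

## Running-minimum baseline: block minima on a coarse grid (window
## half-width `half`), linearly interpolated, then lightly smoothed.
trace_baseline <- function(y, half = 300L, stride = 50L) {
  n <- length(y)
  centers <- unique(c(seq(1L, n, by = stride), n))
  b <- vapply(centers, function(i)
    min(y[max(1L, i - half):min(n, i + half)]), numeric(1))
  approx(centers, b, xout = seq_len(n), rule = 2)$y
}

moving_avg <- function(y, k = 5L) {
  f <- stats::filter(y, rep(1 / k, k), sides = 2)
  f[is.na(f)] <- y[is.na(f)]
  as.numeric(f)
}

## Core single-channel detector on an intensity vector (scan = index).
detect_channel <- function(y, threshold, min_hw, search_cap = 400L) {
  n <- length(y)
  empty <- data.frame(apex_scan = numeric(), height = numeric(),
                      half_width_points = numeric(), area = numeric())
  if (n < 5 || diff(range(y)) == 0) return(empty)
  y1 <- y - trace_baseline(y)
  s <- moving_avg(y1, 5L)
  i <- 2:(n - 1)
  cand <- i[s[i] > s[i - 1] & s[i] >= s[i + 1]]
  if (!length(cand)) return(empty)
  ## refine to the raw local maximum near each smoothed candidate
  cand <- unique(vapply(cand, function(j) {
    w <- max(1L, j - 3L):min(n, j + 3L)
    w[which.max(y1[w])]
  }, integer(1)))
  cand <- cand[y1[cand] >= 0.9 * threshold]
  if (!length(cand)) return(empty)
  ## collapse candidates closer than 5 scans (noise doublets on one apex)
  cand <- sort(cand)
  keep <- logical(length(cand))
  grp <- cumsum(c(TRUE, diff(cand) > 5))
  for (g in split(seq_along(cand), grp))
    keep[g[which.max(y1[cand[g]])]] <- TRUE
  cand <- cand[keep]

  m <- length(cand)
  apex <- height <- hw <- area <- numeric(m)
  for (q in seq_len(m)) {
    j <- cand[q]
    ## apex height from the 3-point median: a one-scan impulse riding on
    ## a genuine peak cannot inflate the measured height
    h <- if (j > 1 && j < n) median(y1[(j - 1):(j + 1)]) else y1[j]
    half <- h / 2
    ## left half-height crossing (linear interpolation)
    lo <- max(1L, j - search_cap)
    li <- which(y1[lo:j] < half)
    left <- if (length(li)) {
      a <- lo + max(li) - 1L  # last index below half before apex
      a + (half - y1[a]) / (y1[a + 1L] - y1[a])
    } else lo
    hi <- min(n, j + search_cap)
    ri <- which(y1[j:hi] < half)
    right <- if (length(ri)) {
      b <- j + min(ri) - 1L   # first index below half after apex
      b - (half - y1[b]) / (y1[b - 1L] - y1[b])
    } else hi
    ## sub-scan apex: quadratic interpolation on log intensities (exact
    ## for a sampled Gaussian pulse), parabola fallback near zero signal
    delta <- 0
    if (j > 1 && j < n) {
      y3 <- y1[(j - 1):(j + 1)]
      if (all(y3 > 0)) y3 <- log(y3)
      den <- y3[1] - 2 * y3[2] + y3[3]
      if (den < 0)
        delta <- max(-0.5, min(0.5, 0.5 * (y3[1] - y3[3]) / den))
    }
    apex[q] <- j + delta
    height[q] <- h
    hw[q] <- (right - left) / 2
    area[q] <- sum(y1[max(1L, floor(left)):min(n, ceiling(right))])
  }
  out <- data.frame(apex_scan = apex, height = height,
                    half_width_points = hw, area = area)
  out[out$half_width_points >= min_hw & out$height >= threshold, ,
      drop = FALSE]
}
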