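#' Internal size-standard specification
#'
#' @param sizes Fragment sizes in nucleotides, strictly increasing,
#'   within 35-500.
#' @param dye Dye channel carrying the ladder (default "ROX").
#' @return A list of class `msat_ladder`.
#' @export
ladder_spec <- function(sizes, dye = "ROX") {
  sizes <- as.numeric(sizes)
  stopifnot(length(sizes) >= 4, all(diff(sizes) > 0),
            min(sizes) >= 35, max(sizes) <= 500)
  structure(list(dye = dye, sizes = sizes), class = "msat_ladder")
}

#' The GeneScan 500 ROX ladder
#'
#' Canonical 16-fragment list of the GS500 internal size standard
#' (35-500 nt).  Override via [ladder_spec()] for other standards.
#'
#' @return An `msat_ladder`.
#' @export
gs500_ladder <- function() {
  ladder_spec(c(35, 50, 75, 100, 139, 150, 160, 200, 250, 300,
                340, 350, 400, 450, 490, 500))
}

## Least-squares fit of one reciprocal curve L = L0 + c/(m - m0) to all
## (scan, size) pairs.  For fixed m0 the model is linear in (L0, c); m0 is
## refined by nls from a closed-form 3-point start (exact on clean data).
fit_global_reciprocal <- function(scans, sizes) {
  n <- length(scans)
  stopifnot(n >= 3)
  idx <- c(1L, which.min(abs(scans - median(scans))), n)
  idx <- sort(unique(idx))
  if (length(idx) < 3) idx <- c(1L, max(2L, n %/% 2L), n)
  start <- fit_reciprocal3(scans[idx], sizes[idx])
  if (n == 3 || anyNA(start))
    return(start)
  fit <- tryCatch(
    nls(sizes ~ L0 + cc / (scans - m0),
        start = list(m0 = start[["m0"]], cc = start[["c"]],
                     L0 = start[["L0"]]),
        ## scaleOffset makes the convergence test sound for the
        ## zero-residual case (exact reciprocal-law data)
        control = stats::nls.control(maxiter = 200, warnOnly = TRUE,
                                     scaleOffset = 1)),
    error = function(e) NULL)
  if (is.null(fit)) return(start)
  cf <- coef(fit)
  c(m0 = unname(cf["m0"]), c = unname(cf["cc"]), L0 = unname(cf["L0"]))
}

reciprocal_rmse <- function(scans, sizes) {
  cf <- fit_global_reciprocal(scans, sizes)
  if (anyNA(cf)) return(Inf)
  pred <- cf[["L0"]] + cf[["c"]] / (scans - cf[["m0"]])
  sqrt(mean((pred - sizes)^2))
}

#' Match detected ROX peaks to the internal size standard
#'
#' Assigns the known ladder fragment sizes to a monotone subset of the
#' candidate ROX apexes.  When more candidates than fragments are present
#' (residual artifacts that survived spike rejection), the subset
#' minimizing the residual of a single reciprocal length-mobility fit is
#' chosen (exhaustively for up to 3 surplus candidates, by greedy
#' worst-candidate elimination beyond that).  A fit whose root mean square
#' residual exceeds `rmse_max` base pairs is rejected as a ladder failure
#' and the run is unusable.
#'
#' @param rox_peaks Data frame of detected peaks on the ladder channel
#'   (columns `apex_scan`, `height`).
#' @param ladder An `msat_ladder`.
#' @param strict If `TRUE` (default) fewer candidates than ladder
#'   fragments is an error.  If `FALSE` and exactly one fragment is
#'   missing, the best single-fragment-dropped fit is returned flagged as
#'   partial.
#' @param rmse_max Acceptance floor for the spacing fit, in bp.
#' @return A list of class `msat_ladder_fit`: matched `scans` and `sizes`,
#'   `rmse`, `partial` flag, and the usable interpolation interval
#'   (`interval_scan`, `interval_bp`) spanning the 2nd to (n-1)th matched
#'   standards (Local Southern needs two standards on each side).
#' @export
match_ladder <- function(rox_peaks, ladder, strict = TRUE, rmse_max = 2) {
  sizes <- ladder$sizes
  k <- length(sizes)
  if (is.null(rox_peaks) || nrow(rox_peaks) == 0)
    stop("ladder failure: no candidate ladder peaks detected", call. = FALSE)
  ord <- order(rox_peaks$apex_scan)
  scans <- rox_peaks$apex_scan[ord]
  heights <- if ("height" %in% names(rox_peaks)) rox_peaks$height[ord]
  else rep(1, length(scans))
  n <- length(scans)
  partial <- FALSE
  if (n < k) {
    if (strict || n < k - 1)
      stop(sprintf(paste0("ladder failure: %d candidate peaks for %d ladder",
                          " fragments"), n, k), call. = FALSE)
    ## one fragment lost: find which known size to drop
    fits <- lapply(seq_len(k), function(drop)
      reciprocal_rmse(scans, sizes[-drop]))
    drop <- which.min(unlist(fits))
    sizes <- sizes[-drop]
    partial <- TRUE
  } else if (n > k) {
    ## More candidates than fragments.  Ladder fragments run at similar
    ## signal, so far-surplus cases are first thinned by height; the last
    ## (up to 3) surplus candidates are resolved exhaustively by the
    ## spacing fit.
    while (length(scans) - k > 3) {
      d <- which.min(heights)
      scans <- scans[-d]; heights <- heights[-d]
    }
    surplus <- length(scans) - k
    combos <- utils::combn(length(scans), surplus)
    rms <- apply(combos, 2, function(d) reciprocal_rmse(scans[-d], sizes))
    scans <- scans[-combos[, which.min(rms), drop = TRUE]]
  }
  rmse <- reciprocal_rmse(scans, sizes)
  if (!is.finite(rmse) || rmse > rmse_max)
    stop(sprintf("ladder failure: spacing fit RMSE %.3f bp exceeds %.2f bp",
                 rmse, rmse_max), call. = FALSE)
  nk <- length(scans)
  structure(list(scans = scans, sizes = sizes, rmse = rmse,
                 partial = partial,
                 interval_scan = c(scans[2], scans[nk - 1]),
                 interval_bp = c(sizes[2], sizes[nk - 1])),
            class = "msat_ladder_fit")
}

#' @export
print.msat_ladder_fit <- function(x, ...) {
  cat(sprintf("<msat_ladder_fit: %d standards, %.0f-%.0f bp usable, RMSE %.3g bp%s>\n",
              length(x$scans), x$interval_bp[1], x$interval_bp[2], x$rmse,
              if (x$partial) ", PARTIAL" else ""))
  invisible(x)
}

## Exact reciprocal curve L = L0 + c/(m - m0) through three (scan, size)
## points; closed form.  Returns c(m0, c, L0), NA on degenerate input.
fit_reciprocal3 <- function(m, L) {
  stopifnot(length(m) == 3, length(L) == 3)
  A <- (L[1] - L[3]) * (m[3] - m[2])
  B <- (L[2] - L[3]) * (m[3] - m[1])
  den <- A - B
  if (!is.finite(den) || abs(den) < 1e-12 * max(abs(c(A, B, 1))))
    return(c(m0 = NA_real_, c = NA_real_, L0 = NA_real_))
  m0 <- (A * m[1] - B * m[2]) / den
  cc <- (L[1] - L[2]) * (m[1] - m0) * (m[2] - m0) / (m[2] - m[1])
  L0 <- L[1] - cc / (m[1] - m0)
  c(m0 = m0, c = cc, L0 = L0)
}

predict_reciprocal <- function(cf, scan) cf[["L0"]] + cf[["c"]] / (scan - cf[["m0"]])

#' Local Southern fragment sizing
#'
#' Sizes a fragment from the four nearest internal standards using the
#' reciprocal relationship between fragment length and mobility: with
#' standards p1 < p2 <= scan <= p3 < p4, a curve L = c/(m - m0) + L0 is
#' passed exactly through (p1, p2, p3) and through (p2, p3, p4), and the
#' mean of the two predicted sizes is returned.  A query equal to a
#' matched standard returns that standard's size exactly.  Queries with
#' fewer than two standards on either side are returned as `NA` (flagged
#' unsized downstream, never extrapolated).
#'
#' @param scan Numeric vector of apex scan positions.
#' @param fit An `msat_ladder_fit` from [match_ladder()].
#' @return Numeric vector of sizes in bp (`NA` where unsizable).
#' @export
local_southern_size <- function(scan, fit) {
  ms <- fit$scans; Ls <- fit$sizes
  n <- length(ms)
  vapply(scan, function(s) {
    hit <- which(abs(ms - s) < 1e-9)
    if (length(hit)) return(Ls[hit[1]])
    i <- findInterval(s, ms)   # standards 1..i are <= s
    if (i < 2 || i > n - 2) return(NA_real_)
    f1 <- fit_reciprocal3(ms[(i - 1):(i + 1)], Ls[(i - 1):(i + 1)])
    f2 <- fit_reciprocal3(ms[i:(i + 2)], Ls[i:(i + 2)])
    if (anyNA(f1) || anyNA(f2)) return(NA_real_)
    (predict_reciprocal(f1, s) + predict_reciprocal(f2, s)) / 2
  }, numeric(1))
}

#' Comparator sizing methods
#'
#' `global_southern` fits one reciprocal curve to all matched standards by
#' least squares; `cubic_ls` fits a single third-order polynomial
#' size(scan).  Both are provided for precision comparison against
#' [local_southern_size()]; queries outside the usable interval are
#' still predicted (the single global curve extends across all matched
#' standards) but flagged by [size_peaks()].
#'
#' @param scan Numeric vector of apex scans.
#' @param fit An `msat_ladder_fit`.
#' @param method `"global_southern"` or `"cubic_ls"`.
#' @return Numeric vector of sizes in bp.
#' @export
comparator_size <- function(scan, fit,
                            method = c("global_southern", "cubic_ls")) {
  method <- match.arg(method)
  if (method == "global_southern") {
    if (length(fit$scans) < 3)
      stop("global_southern needs >= 3 matched standards", call. = FALSE)
    cf <- fit_global_reciprocal(fit$scans, fit$sizes)
    if (anyNA(cf)) stop("degenerate global reciprocal fit", call. = FALSE)
    predict_reciprocal(cf, scan)
  } else {
    if (length(fit$scans) < 4)
      stop("cubic_ls needs >= 4 matched standards", call. = FALSE)
    d <- data.frame(m = fit$scans, L = fit$sizes)
    mod <- lm(L ~ poly(m, 3), data = d)
    unname(predict(mod, newdata = data.frame(m = scan)))
  }
}

#' Convert detected peaks to sized peaks
#'
#' Applies the chosen sizing method to every peak.  Peaks outside the
#' ladder interpolation interval (or on the ladder channel itself when
#' excluded upstream) are kept but flagged `sized = FALSE`; nothing is
#' silently dropped.
#'
#' @param peaks Peak data frame from [detect_peaks()].
#' @param fit An `msat_ladder_fit`.
#' @param method One of `"local_southern"`, `"global_southern"`,
#'   `"cubic_ls"`.
#' @return The peak data frame with `size_bp`, `method` and `sized`
#'   columns appended.
#' @export
size_peaks <- function(peaks, fit,
                       method = c("local_southern", "global_southern",
                                  "cubic_ls")) {
  method <- match.arg(method)
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) == 0) {
    peaks$size_bp <- numeric(0); peaks$method <- character(0)
    peaks$sized <- logical(0)
    return(peaks)
  }
  sz <- if (method == "local_southern")
    local_southern_size(peaks$apex_scan, fit)
  else comparator_size(peaks$apex_scan, fit, method)
  inside <- peaks$apex_scan >= fit$interval_scan[1] &
    peaks$apex_scan <= fit$interval_scan[2]
  peaks$size_bp <- sz
  peaks$method <- method
  peaks$sized <- inside & !is.na(sz)
  peaks
}
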