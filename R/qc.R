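#' Per-allele sizing coefficient of variation across replicate runs
#'
#' Groups allele size observations from a series of replicate profiles of
#' the same sample by (marker, bin) and computes the percent coefficient
#' of variation, %CV = 100 x sample SD / mean, per allele.  Alleles seen
#' in a single run have undefined %CV and are reported as `NA`, not zero.
#' Multiplying all sizes by a constant leaves %CV unchanged.
#'
#' @param profiles List of `msat_profile` objects (replicate runs).
#' @return Data frame `marker`, `bin`, `n`, `mean_bp`, `sd_bp`, `cv_pct`,
#'   with the cumulative %CV range over defined alleles in attribute
#'   `"cv_range"`.
#' @export
sizing_cv <- function(profiles) {
  obs <- do.call(rbind, lapply(profiles, function(p) {
    if (!nrow(p$calls)) return(NULL)
    data.frame(marker = p$calls$marker, bin = p$calls$bin,
               size_bp = p$calls$size_bp)
  }))
  if (is.null(obs) || !nrow(obs))
    stop("no allele observations in profiles", call. = FALSE)
  obs <- obs[!is.na(obs$bin), , drop = FALSE]
  sp <- split(obs, list(obs$marker, obs$bin), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    n <- nrow(d)
    mu <- mean(d$size_bp)
    s <- if (n >= 2) sd(d$size_bp) else NA_real_
    data.frame(marker = d$marker[1], bin = d$bin[1], n = n, mean_bp = mu,
               sd_bp = s, cv_pct = if (n >= 2) 100 * s / mu else NA_real_)
  }))
  out <- out[order(out$marker, out$bin), , drop = FALSE]
  rownames(out) <- NULL
  cv <- out$cv_pct[!is.na(out$cv_pct)]
  attr(out, "cv_range") <- if (length(cv)) range(cv) else c(NA_real_, NA_real_)
  out
}

## expected apparent bins for one genotype at one marker (always a pair;
## both alleles of the expected genotype are counted)
expected_pair <- function(genotype, marker, shift) {
  g <- genotype$alleles[genotype$alleles$marker == marker, ]
  if (!nrow(g)) return(NULL)
  round(c(g$a1, g$a2) + shift)
}

#' Percent deviation from expected genotypes
#'
#' Compares automated allele calls against ground-truth genotypes and
#' reports the percentage of miscalled alleles.  Each expected genotype
#' contributes two alleles per marker (a homozygote's single observed
#' call covers both).  For mononucleotide markers a deviation of up to
#' `mono_tolerance` nucleotides is accepted as normal (polymerase
#' slippage, not process error).  If a spurious allele is called at a
#' marker (an observed bin matching no expected allele), every expected
#' allele of that marker counts as miscalled -- the conservative
#' convention for nonspecific signals identified as alleles.
#'
#' The statistic is permutation-invariant over samples and additive over
#' day partitions: the all-days percentage is the allele-weighted mean of
#' the per-day percentages.
#'
#' @param observed List of `msat_profile` objects; each may carry a `day`
#'   element for the per-day breakdown.
#' @param expected List of `msat_genotype` objects; matched to profiles
#'   by `id`.
#' @param panel An `msat_panel` (identifies mononucleotide markers).
#' @param markers Optional subset of markers to assess (default: all
#'   markers present in the expected genotypes).
#' @param mono_tolerance Accepted deviation in nt for mononucleotide
#'   markers (default 1).
#' @param shift Apparent-size lattice shift of calls relative to template
#'   alleles (default +1, full adenylation).
#' @return A list of class `msat_deviation`: `total`, `miscalled`,
#'   `percent`, `per_day`, `per_marker`, `tolerance`.
#' @export
percent_deviation <- function(observed, expected, panel, markers = NULL,
                              mono_tolerance = 1, shift = 1) {
  exp_ids <- vapply(expected, `[[`, character(1), "id")
  obs_ids <- vapply(observed, `[[`, character(1), "id")
  missing <- setdiff(obs_ids, exp_ids)
  if (length(missing))
    stop("no expected genotype for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  mono <- panel$markers$name[panel$markers$repeat_unit == 1L]
  rows <- list()
  for (p in observed) {
    g <- expected[[match(p$id, exp_ids)]]
    mks <- markers %||% intersect(g$alleles$marker, unique(c(
      p$calls$marker, g$alleles$marker)))
    for (mk in mks) {
      exp_bins <- expected_pair(g, mk, shift)
      if (is.null(exp_bins)) next
      obs_bins <- p$calls$bin[p$calls$marker == mk]
      obs_bins <- obs_bins[!is.na(obs_bins)]
      tol <- if (mk %in% mono) mono_tolerance else 0
      matched <- vapply(exp_bins, function(e)
        any(abs(obs_bins - e) <= tol), logical(1))
      spurious <- length(obs_bins) &&
        any(vapply(obs_bins, function(o)
          all(abs(exp_bins - o) > tol), logical(1)))
      mis <- if (spurious) length(exp_bins) else sum(!matched)
      rows[[length(rows) + 1L]] <- data.frame(
        id = p$id, day = p$day %||% NA_character_, marker = mk,
        total = length(exp_bins), miscalled = mis)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("nothing to compare", call. = FALSE)
  tab$day[is.na(tab$day)] <- "(all)"
  agg <- function(key) {
    sp <- split(tab, tab[[key]])
    d <- do.call(rbind, lapply(sp, function(x)
      data.frame(key = x[[key]][1], total = sum(x$total),
                 miscalled = sum(x$miscalled))))
    names(d)[1] <- key
    d$percent <- 100 * d$miscalled / d$total
    rownames(d) <- NULL
    d
  }
  structure(list(total = sum(tab$total), miscalled = sum(tab$miscalled),
                 percent = 100 * sum(tab$miscalled) / sum(tab$total),
                 per_day = agg("day"), per_marker = agg("marker"),
                 tolerance = list(mono_tolerance = mono_tolerance,
                                  shift = shift)),
            class = "msat_deviation")
}

#' @export
print.msat_deviation <- function(x, ...) {
  cat(sprintf("<msat_deviation: %d of %d alleles miscalled (%.2f%%)>\n",
              x$miscalled, x$total, x$percent))
  invisible(x)
}

#' Control-sample chart over runs
#'
#' Tracks a known control sample across runs to separate process failure
#' from sample integrity: a run whose control profile deviates from the
#' control's reference genotype is flagged, and deviations of unknown
#' samples on that run are attributed to the process; on runs with a
#' concordant control, deviations are attributed to sample integrity.
#'
#' @param control_profiles List of `msat_profile` objects for the control
#'   sample, one per run (each should carry a `day`/run label in `$id`).
#' @param reference `msat_genotype` of the control sample.
#' @param panel An `msat_panel`.
#' @param mono_tolerance,shift As in [percent_deviation()].
#' @return Data frame `run`, `control_ok`, `attribution` ("sample" when
#'   the control passed, "process" otherwise).  With no control runs a
#'   warning is raised and a zero-row frame returned.
#' @export
control_chart <- function(control_profiles, reference, panel,
                          mono_tolerance = 1, shift = 1) {
  if (!length(control_profiles)) {
    warning("no control runs present; deviation attribution unavailable")
    return(data.frame(run = character(), control_ok = logical(),
                      attribution = character()))
  }
  rows <- lapply(control_profiles, function(p) {
    ref <- reference
    ref$id <- p$id
    dev <- percent_deviation(list(p), list(ref), panel,
                             mono_tolerance = mono_tolerance, shift = shift)
    ok <- dev$miscalled == 0
    data.frame(run = p$id, control_ok = ok,
               attribution = if (ok) "sample" else "process")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replicate control-sample study
#'
#' Simulates `n_runs` independent amplification + electrophoresis runs of
#' a fixed control genotype, genotypes each run with the full pipeline,
#' and summarises per-allele sizing reproducibility (%CV).
#'
#' @param panel An `msat_panel`.
#' @param group Multiplex group to run.
#' @param genotype Control genotype (default [control_genotype()]).
#' @param n_runs Number of replicate runs (default 23).
#' @param run Run conditions; default [run_conditions()] with 0.08 bp
#'   migration noise.
#' @param stutter Stutter model.
#' @param method Sizing method.
#' @param seed Seed; replicate r uses stream `seed + r`.
#' @return List with `profiles`, `cv` (from [sizing_cv()]), and
#'   `max_cv_pct`.
#' @export
replicate_control_study <- function(panel, group = 1,
                                    genotype = control_genotype(panel),
                                    n_runs = 23,
                                    run = run_conditions(),
                                    stutter = stutter_model(),
                                    method = "local_southern",
                                    seed = 1) {
  profiles <- lapply(seq_len(n_runs), function(r) {
    sim <- simulate_run(genotype, panel, group = group, stutter = stutter,
                        run = run, seed = seed + r)
    p <- genotype_run(sim$trace, panel, group = group, method = method,
                      id = sprintf("run%02d", r))
    p$day <- sprintf("day%02d", r)
    p
  })
  cv <- sizing_cv(profiles)
  list(profiles = profiles, cv = cv,
       max_cv_pct = max(cv$cv_pct, na.rm = TRUE))
}
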