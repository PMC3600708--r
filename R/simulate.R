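#' Ideal size-domain amplicon peaks for a genotype
#'
#' Expands each allele into its PCR product spectrum: a main peak plus a
#' geometric stutter ladder at one-repeat-unit steps below it, split
#' between the +A (size + 1) and non-adenylated (size + 0) forms
#' according to the adenylation fraction.  Stutter below `floor_frac` of
#' the main peak is truncated.  Per-allele amplification is unequal by a
#' lognormal factor.  Homozygous alleles contribute twice at the same
#' size (superposed on rendering).
#'
#' @param genotype An `msat_genotype`.
#' @param panel An `msat_panel`.
#' @param stutter An `msat_stutter` model.
#' @param group Restrict to one multiplex group (NULL = all markers).
#' @param height_range Range of the per-marker base peak height
#'   (fluorescence units), drawn uniformly.
#' @param allele_sdlog Lognormal sdlog of the per-allele amplification
#'   factor (0 = equal amplification).
#' @param seed Optional seed.
#' @return Data frame with columns `marker`, `dye`, `allele` (template
#'   size of the parent allele), `size` (apparent rendered size in bp),
#'   `height`, `kind` ("main" or "stutter").
#' @export
amplicon_peaks <- function(genotype, panel, stutter = stutter_model(),
                           group = NULL, height_range = c(1500, 3500),
                           allele_sdlog = 0.1, seed = NULL) {
  m <- panel$markers
  if (!is.null(group)) m <- m[m$group %in% group, , drop = FALSE]
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(m)), function(i) {
      g <- genotype$alleles[genotype$alleles$marker == m$name[i], ]
      if (!nrow(g)) return(NULL)
      u <- m$repeat_unit[i]
      rng <- if (u == 1L) stutter$mono_ratio_range else stutter$di_ratio_range
      base <- runif(1, height_range[1], height_range[2])
      per_allele <- lapply(c(g$a1, g$a2), function(a) {
        r <- runif(1, rng[1], rng[2])
        h0 <- base * rlnorm(1, 0, allele_sdlog)
        kmax <- max(0L, floor(log(stutter$floor_frac) / log(r)))
        k <- 0:kmax
        data.frame(marker = m$name[i], dye = m$dye[i], allele = a,
                   size = a - u * k, height = h0 * r^k,
                   kind = ifelse(k == 0, "main", "stutter"))
      })
      do.call(rbind, per_allele)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      return(data.frame(marker = character(), dye = character(),
                        allele = numeric(), size = numeric(),
                        height = numeric(), kind = character()))
    ## adenylation split: fraction a at size+1, (1-a) at size
    a <- stutter$adenylation
    parts <- list()
    if (a > 0) {
      up <- out; up$size <- up$size + 1; up$height <- up$height * a
      parts <- c(parts, list(up))
    }
    if (a < 1) {
      keep <- out; keep$height <- keep$height * (1 - a)
      parts <- c(parts, list(keep))
    }
    out <- do.call(rbind, parts)
    out <- out[out$height > 0, , drop = FALSE]
    rownames(out) <- NULL
    out[order(out$marker, out$size), ]
  })
}

#' Render ideal peaks into a multi-channel fluorescence trace
#'
#' Each peak becomes a Gaussian pulse centred at
#' `m(size + migration noise)` on the scan axis; the ROX channel carries
#' the internal size standard; the FAM channel additionally receives
#' `bleed` times the HEX signal (spectral overlap); one-scan spikes and
#' broad nonspecific pulses are injected at their Poisson rates; finally
#' a constant baseline and white noise are added.  The returned truth
#' table records every injected apex (markers, ladder, bleed images,
#' spikes, nonspecific products) for ground-truthed evaluation.
#'
#' @param peaks Ideal peak table from [amplicon_peaks()] (columns `dye`,
#'   `size`, `height`; extra columns are carried into the truth table).
#' @param mobility An `msat_mobility`.
#' @param run An `msat_run` ([run_conditions()]).
#' @param ladder An `msat_ladder` ([gs500_ladder()]); NULL renders no
#'   ladder.
#' @param avoid Optional data frame (`dye`, `min_bp`, `max_bp`) of size
#'   intervals nonspecific products must avoid (typically the same-dye
#'   marker windows of the group being rendered).
#' @param seed Optional seed.
#' @return List with `trace` (an `msat_trace` data frame: `scan`, `FAM`,
#'   `HEX`, `NED`, `ROX`) and `truth` (data frame of injected apexes:
#'   `channel`, `size`, `apex_scan`, `height`, `kind`, `marker`).
#' @export
render_trace <- function(peaks, mobility = mobility_model(),
                         run = run_conditions(), ladder = gs500_ladder(),
                         avoid = NULL, seed = NULL) {
  sizes_max <- max(c(if (!is.null(ladder)) ladder$sizes, peaks$size, 450))
  n_scans <- ceiling(mobility_scan(mobility, sizes_max + 5)) + 100L
  channels <- c("FAM", "HEX", "NED", "ROX")
  sig <- matrix(0, nrow = n_scans, ncol = 4L,
                dimnames = list(NULL, channels))
  sigma <- run$pulse_sigma
  truth <- list()

  add_pulse <- function(ch, mu, h, width = sigma) {
    lo <- max(1L, floor(mu - 6 * width))
    hi <- min(n_scans, ceiling(mu + 6 * width))
    if (lo > hi) return()
    x <- lo:hi
    sig[x, ch] <<- sig[x, ch] + h * exp(-(x - mu)^2 / (2 * width^2))
  }

  with_seed(seed %||% run$seed, {
    ## analyte fragments: migration noise is drawn once per fragment
    ## species (dye, size) -- identical-length fragments co-migrate, so
    ## e.g. the two allele copies of a homozygote stay coherent
    if (nrow(peaks)) {
      key <- paste(peaks$dye, peaks$size)
      species <- sort(unique(key))
      sjit <- rnorm(length(species), 0, run$migration_sd)
      jit <- sjit[match(key, species)]
      mus <- mobility_scan(mobility, peaks$size + jit)
      for (i in seq_len(nrow(peaks)))
        add_pulse(peaks$dye[i], mus[i], peaks$height[i])
      truth[["markers"]] <- data.frame(
        channel = peaks$dye, size = peaks$size, apex_scan = mus,
        height = peaks$height, kind = peaks$kind,
        marker = peaks$marker %||% NA_character_)
    }
    ## internal size standard
    if (!is.null(ladder)) {
      ljit <- rnorm(length(ladder$sizes), 0, run$ladder_sd)
      lmu <- mobility_scan(mobility, ladder$sizes + ljit)
      lh <- run$ladder_height * rlnorm(length(lmu), 0, 0.05)
      for (i in seq_along(lmu)) add_pulse(ladder$dye, lmu[i], lh[i])
      truth[["ladder"]] <- data.frame(
        channel = ladder$dye, size = ladder$sizes, apex_scan = lmu,
        height = lh, kind = "ladder", marker = NA_character_)
    }
    ## spectral bleed-through of HEX into FAM
    if (run$bleed > 0) {
      sig[, "FAM"] <- sig[, "FAM"] + run$bleed * sig[, "HEX"]
      hexed <- do.call(rbind, truth)
      if (!is.null(hexed)) {
        hexed <- hexed[hexed$channel == "HEX", , drop = FALSE]
        if (nrow(hexed)) {
          hexed$channel <- "FAM"
          hexed$height <- hexed$height * run$bleed
          hexed$kind <- "bleed"
          truth[["bleed"]] <- hexed
        }
      }
    }
    ## one-scan electrical spikes
    n_spikes <- rpois(1, run$spike_rate)
    if (n_spikes > 0) {
      sch <- sample(channels, n_spikes, replace = TRUE)
      sat <- sample.int(n_scans, n_spikes)
      sh <- runif(n_spikes, 200, 1200)
      for (i in seq_len(n_spikes)) sig[sat[i], sch[i]] <-
          sig[sat[i], sch[i]] + sh[i]
      truth[["spikes"]] <- data.frame(
        channel = sch, size = NA_real_, apex_scan = as.numeric(sat),
        height = sh, kind = "spike", marker = NA_character_)
    }
    ## broad nonspecific products
    n_ns <- rpois(1, run$nonspecific_rate)
    if (n_ns > 0) {
      rows <- lapply(seq_len(n_ns), function(i) {
        ch <- sample(c("FAM", "HEX", "NED"), 1)
        for (try in 1:50) {
          sz <- runif(1, 40, sizes_max - 20)
          blocked <- !is.null(avoid) &&
            any(avoid$dye == ch & sz >= avoid$min_bp & sz <= avoid$max_bp)
          if (!blocked) break
        }
        h <- run$nonspecific_height * runif(1, 0.4, 1.6)
        mu <- mobility_scan(mobility, sz + rnorm(1, 0, run$migration_sd))
        add_pulse(ch, mu, h, width = 2 * sigma)
        data.frame(channel = ch, size = sz, apex_scan = mu, height = h,
                   kind = "nonspecific", marker = NA_character_)
      })
      truth[["nonspecific"]] <- do.call(rbind, rows)
    }
    ## baseline + white noise
    if (run$baseline > 0 || run$noise_sd > 0)
      sig <- sig + run$baseline +
        matrix(rnorm(length(sig), 0, run$noise_sd), nrow = n_scans)
  })
  trace <- data.frame(scan = seq_len(n_scans), sig)
  class(trace) <- c("msat_trace", "data.frame")
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(trace = trace, truth = truth)
}

#' Simulate one multiplexed amplification and electrophoresis run
#'
#' Convenience wrapper: [amplicon_peaks()] for the requested group, then
#' [render_trace()] with the panel's ladder, steering nonspecific
#' products away from same-dye marker windows of the group.
#'
#' @inheritParams amplicon_peaks
#' @inheritParams render_trace
#' @param group Multiplex group to amplify (1 or 2).
#' @return As [render_trace()].
#' @export
simulate_run <- function(genotype, panel, group = 1,
                         stutter = stutter_model(),
                         run = run_conditions(),
                         mobility = mobility_model(), seed = NULL) {
  m <- panel$markers[panel$markers$group == group, ]
  avoid <- data.frame(dye = m$dye, min_bp = m$window_min,
                      max_bp = m$window_max)
  with_seed(seed, {
    ap <- amplicon_peaks(genotype, panel, stutter = stutter, group = group)
    render_trace(ap, mobility = mobility, run = run,
                 ladder = panel$ladder, avoid = avoid)
  })
}
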