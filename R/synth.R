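#' Default per-marker allele frequency tables
#'
#' Emulates the population structure the assay targets: dinucleotide
#' markers get a uniform ladder of alleles on the repeat lattice well
#' inside the marker window; the quasimonomorphic mononucleotide markers
#' Bat25 and Bat26 get a single modal allele with probability 0.96 (the
#' modal template alleles, 126 and 121 nt, give apparent adenylated sizes
#' of 127 and 122 nt, the sizes the assay reports for its control sample)
#' and two rare 1-nt neighbours.
#'
#' @param panel An `msat_panel`.
#' @return Named list of named numeric vectors: per marker,
#'   `probability` named by allele template size in bp.
#' @export
default_allele_freqs <- function(panel) {
  m <- panel$markers
  mono_modal <- c(BAT25 = 126, BAT26 = 121)
  freqs <- lapply(seq_len(nrow(m)), function(i) {
    if (m$repeat_unit[i] == 1L) {
      modal <- mono_modal[[m$name[i]]] %||%
        round((m$window_min[i] + m$window_max[i]) / 2)
      p <- c(0.02, 0.96, 0.02)
      names(p) <- c(modal - 1, modal, modal + 1)
      p
    } else {
      support <- seq(m$window_min[i] + 10, m$window_max[i] - 10, by = 2)
      p <- rep(1 / length(support), length(support))
      names(p) <- support
      p
    }
  })
  names(freqs) <- m$name
  freqs
}

new_genotype <- function(id, alleles) {
  structure(list(id = id, alleles = alleles), class = "msat_genotype")
}

#' @export
print.msat_genotype <- function(x, ...) {
  cat(sprintf("<msat_genotype '%s'>\n", x$id))
  print(x$alleles, row.names = FALSE)
  invisible(x)
}

#' Draw a random genotype from allele frequencies
#'
#' Two alleles per marker are drawn independently from the marker's
#' frequency table.  Allele sizes are template sizes in bp (the rendered
#' apparent size is shifted by adenylation, see [stutter_model()]).
#'
#' @param panel An `msat_panel`.
#' @param freqs Allele frequencies as from [default_allele_freqs()].
#' @param id Subject identifier.
#' @param seed Optional integer seed (identical seed, identical genotype).
#' @return An `msat_genotype`: `id` plus an `alleles` data frame with
#'   columns `marker`, `a1`, `a2` (a1 <= a2; equal = homozygous).
#' @export
sample_genotype <- function(panel, freqs = default_allele_freqs(panel),
                            id = "S1", seed = NULL) {
  if (!length(freqs)) stop("empty allele frequency table", call. = FALSE)
  bad <- vapply(freqs, function(p) length(p) == 0 ||
                  abs(sum(p) - 1) > 1e-6, logical(1))
  if (any(bad))
    stop("allele frequencies must be nonempty and sum to 1: ",
         paste(names(freqs)[bad], collapse = ", "), call. = FALSE)
  with_seed(seed, {
    draws <- lapply(names(freqs), function(nm) {
      p <- freqs[[nm]]
      sort(as.numeric(sample(names(p), 2, replace = TRUE, prob = p)))
    })
    alleles <- data.frame(marker = names(freqs),
                          a1 = vapply(draws, `[`, numeric(1), 1),
                          a2 = vapply(draws, `[`, numeric(1), 2))
    new_genotype(id, alleles)
  })
}

#' Fixed control genotype
#'
#' A deterministic reference genotype used for replicate process-control
#' studies (Bat25 and Bat26 at their modal template alleles; mid-window
#' heterozygotes at the dinucleotide markers).
#'
#' @param panel An `msat_panel`.
#' @param id Identifier (default "control").
#' @return An `msat_genotype`.
#' @export
control_genotype <- function(panel, id = "control") {
  a <- c(BAT25 = 126, BAT26 = 121, D3S3623 = 210, D5S346 = 104,
         D6S262 = 170, D7S481 = 185, D2S123 = 210, D3S1262 = 130,
         D9S171 = 110, D17S250 = 185, D18S61 = 155)
  b <- c(BAT25 = 126, BAT26 = 121, D3S3623 = 216, D5S346 = 110,
         D6S262 = 178, D7S481 = 193, D2S123 = 218, D3S1262 = 136,
         D9S171 = 114, D17S250 = 193, D18S61 = 161)
  mk <- panel$markers$name
  new_genotype(id, data.frame(marker = mk, a1 = unname(a[mk]),
                              a2 = unname(b[mk])))
}

#' Simulate a nuclear family
#'
#' Each child inherits exactly one allele per marker from each parent,
#' chosen uniformly.  With `twins = TRUE` the second child is an identical
#' copy of the first (monozygotic twins).
#'
#' @param parent1,parent2 `msat_genotype` objects on the same panel.
#' @param n_children Number of children (>= 2 when `twins = TRUE`).
#' @param twins Duplicate child 1's genotype as child 2.
#' @param seed Optional seed.
#' @return List with `parents` (list of 2) and `children` (list of
#'   `msat_genotype`).
#' @export
make_family <- function(parent1, parent2, n_children = 2, twins = FALSE,
                        seed = NULL) {
  stopifnot(identical(parent1$alleles$marker, parent2$alleles$marker))
  if (twins && n_children < 2) stop("twins need at least 2 children")
  with_seed(seed, {
    children <- lapply(seq_len(n_children), function(k) {
      from1 <- ifelse(runif(nrow(parent1$alleles)) < 0.5,
                      parent1$alleles$a1, parent1$alleles$a2)
      from2 <- ifelse(runif(nrow(parent2$alleles)) < 0.5,
                      parent2$alleles$a1, parent2$alleles$a2)
      new_genotype(sprintf("child%d", k),
                   data.frame(marker = parent1$alleles$marker,
                              a1 = pmin(from1, from2),
                              a2 = pmax(from1, from2)))
    })
    if (twins) {
      children[[2]]$alleles <- children[[1]]$alleles
    }
    list(parents = list(parent1, parent2), children = children)
  })
}

#' Introduce a microsatellite instability event
#'
#' Shifts one allele of one marker by `shift_bp` (expansion or
#' contraction of repeat units).  If the shifted allele leaves the marker
#' window the genotype is still returned, with an `out_of_window`
#' attribute naming the marker.
#'
#' @param genotype An `msat_genotype`.
#' @param marker Marker name.
#' @param shift_bp Signed shift in bp (0 = identity).
#' @param allele Which allele to shift (1 or 2).
#' @param panel Optional panel for the window check.
#' @return The modified `msat_genotype`.
#' @export
apply_msi <- function(genotype, marker, shift_bp, allele = 1, panel = NULL) {
  i <- match(marker, genotype$alleles$marker)
  if (is.na(i)) stop("marker not in genotype: ", marker, call. = FALSE)
  col <- if (allele == 1) "a1" else "a2"
  genotype$alleles[i, col] <- genotype$alleles[i, col] + shift_bp
  if (!is.null(panel)) {
    w <- panel$markers[panel$markers$name == marker, ]
    v <- genotype$alleles[i, col]
    if (nrow(w) && (v < w$window_min || v > w$window_max))
      attr(genotype, "out_of_window") <-
        c(attr(genotype, "out_of_window"), marker)
  }
  genotype
}

#' PCR stutter and adenylation model
#'
#' Polymerase slippage produces shadow peaks one repeat unit below the
#' allele, decaying geometrically: the k-th stutter has height ratio
#' `r^k` where the adjacent ratio `r` is drawn uniformly per allele from
#' the range for its repeat-unit length.  Non-templated +A addition
#' (promoted by the GTGTCTT primer tail) shifts a fraction
#' `adenylation` of product one nucleotide up; the default of 1 (full
#' adenylation) puts all apparent sizes on a +1-shifted lattice that the
#' bin definitions absorb.
#'
#' The mononucleotide upper bound (0.90) is set so that rendered
#' 1-nt-spaced stutter ladders, whose apex heights are slightly inflated
#' by overlap of neighbouring pulses, keep every secondary ratio below
#' the 0.95 mono cut-off: stable samples then reproducibly yield at most
#' two called alleles, as the assay was tuned to do.  These ranges are
#' simulator choices, not measured values.
#'
#' @param mono_ratio_range Adjacent stutter ratio range, repeat unit 1.
#' @param di_ratio_range Adjacent stutter ratio range, repeat unit 2.
#' @param adenylation Fraction of product carrying +A, in `[0, 1]`.
#' @param floor_frac Stutter peaks below this fraction of the main peak
#'   are truncated.
#' @return A list of class `msat_stutter`.
#' @export
stutter_model <- function(mono_ratio_range = c(0.85, 0.90),
                          di_ratio_range = c(0.30, 0.60),
                          adenylation = 1.0,
                          floor_frac = 0.01) {
  stopifnot(all(mono_ratio_range > 0), all(mono_ratio_range < 1),
            all(di_ratio_range > 0), all(di_ratio_range < 1),
            adenylation >= 0, adenylation <= 1, floor_frac > 0)
  structure(list(mono_ratio_range = sort(mono_ratio_range),
                 di_ratio_range = sort(di_ratio_range),
                 adenylation = adenylation, floor_frac = floor_frac),
            class = "msat_stutter")
}

#' Electrophoresis run conditions
#'
#' Noise model for trace rendering.  `migration_sd` is the per-fragment
#' migration noise in bp equivalents applied to analyte fragments;
#' `ladder_sd` is the (much smaller) residual jitter of the
#' co-electrophoresed internal standard, which defines the size axis so
#' common-mode migration variation cancels.  `bleed` is the HEX-into-FAM
#' spectral overlap coefficient.  Spikes are one-scan electrical
#' impulses; nonspecific products are broad low pulses placed outside
#' same-dye marker windows.
#'
#' @param migration_sd Migration noise SD per analyte fragment, bp.
#' @param ladder_sd Residual jitter of ladder fragments, bp.
#' @param bleed HEX->FAM bleed-through coefficient, in `[0, 1)`.
#' @param spike_rate Expected one-scan spikes per trace (Poisson).
#' @param nonspecific_rate Expected nonspecific products per trace.
#' @param nonspecific_height Height scale of nonspecific products.
#' @param baseline Constant baseline offset, fluorescence units.
#' @param noise_sd White noise SD, fluorescence units.
#' @param pulse_sigma Gaussian pulse width parameter in scan points
#'   (half-width at half height is 1.177 sigma, sized so genuine peaks
#'   clear the 4-point minimum half-width).
#' @param ladder_height Nominal ladder peak height.
#' @param seed Default seed carried by the run description.
#' @return A list of class `msat_run`.
#' @export
run_conditions <- function(migration_sd = 0.08, ladder_sd = 0.02,
                           bleed = 0.05, spike_rate = 2,
                           nonspecific_rate = 1.5,
                           nonspecific_height = 150,
                           baseline = 20, noise_sd = 5,
                           pulse_sigma = 4, ladder_height = 800,
                           seed = NULL) {
  stopifnot(migration_sd >= 0, ladder_sd >= 0, bleed >= 0, bleed < 1,
            spike_rate >= 0, nonspecific_rate >= 0, baseline >= 0,
            noise_sd >= 0, pulse_sigma > 0)
  structure(list(migration_sd = migration_sd, ladder_sd = ladder_sd,
                 bleed = bleed, spike_rate = spike_rate,
                 nonspecific_rate = nonspecific_rate,
                 nonspecific_height = nonspecific_height,
                 baseline = baseline, noise_sd = noise_sd,
                 pulse_sigma = pulse_sigma, ladder_height = ladder_height,
                 seed = seed),
            class = "msat_run")
}

#' Reciprocal length-mobility model
#'
#' Migration scan of a fragment of length L is `m(L) = m0 + c / (L - L0)`
#' (reciprocal relationship between fragment length and electrophoretic
#' mobility).  The defaults (`c < 0`, `L0 > 500`) give a strictly
#' increasing, invertible mapping on 35-500 nt with roughly 14 scans per
#' nucleotide at 120 nt, enough to resolve the 1-nt stutter combs of the
#' mononucleotide markers against the 4-point pulse width, comparable to
#' a capillary genetic analyzer.
#'
#' @param m0 Scan offset.
#' @param c Mobility constant.
#' @param L0 Size offset (outside `[35, 500]`).
#' @return A list of class `msat_mobility`.
#' @export
mobility_model <- function(m0 = -9500, c = -9e6, L0 = 900) {
  mob <- structure(list(m0 = m0, c = c, L0 = L0), class = "msat_mobility")
  s <- mobility_scan(mob, seq(35, 500, by = 5))
  if (any(diff(s) <= 0) || any(!is.finite(s)))
    stop("mobility model must be strictly increasing on [35, 500]",
         call. = FALSE)
  mob
}

#' @rdname mobility_model
#' @param mob An `msat_mobility`.
#' @param L Fragment lengths in nt.
#' @export
mobility_scan <- function(mob, L) mob$m0 + mob$c / (L - mob$L0)
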