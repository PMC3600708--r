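#' MSI classification thresholds
#'
#' Mononucleotide markers are quasimonomorphic; small deviations reflect
#' polymerase slippage, so only shifts of at least 3 bp (Bat25) or 4 bp
#' (Bat26) count as true somatic alterations, and a +/-1 nt deviation is
#' always normal.  Dinucleotide markers are unstable whenever a sample
#' allele bin is absent from the reference profile.  Overall status uses
#' the five-marker NCI panel: MSI-H with >= 2 unstable markers, MSI-L
#' with 1, MSS with 0.
#'
#' @param mono Named integer thresholds (bp) per mononucleotide marker.
#' @param mono_normal Deviation (nt) always considered normal.
#' @param nci_markers The reference five-marker panel used for overall
#'   status.
#' @param msi_high Minimum unstable NCI markers for MSI-H.
#' @return A list of class `msat_msi_thresholds`.
#' @export
msi_thresholds <- function(mono = c(BAT25 = 3L, BAT26 = 4L),
                           mono_normal = 1L,
                           nci_markers = c("BAT25", "BAT26", "D2S123",
                                           "D5S346", "D17S250"),
                           msi_high = 2L) {
  stopifnot(all(mono >= 1), mono_normal >= 0, msi_high >= 1)
  structure(list(mono = mono, mono_normal = mono_normal,
                 nci_markers = nci_markers, msi_high = msi_high),
            class = "msat_msi_thresholds")
}

#' Classify microsatellite instability against a reference profile
#'
#' Per-marker stability of a sample (e.g. tumor or clone) against a
#' reference profile (e.g. matched normal): a mononucleotide marker is
#' unstable iff some sample allele deviates from every reference allele
#' by at least its threshold (deviations within the normal tolerance
#' never count); a dinucleotide marker is unstable iff some sample bin is
#' absent from the reference.  Markers missing from the reference are
#' excluded and noted.  Overall status is derived from the NCI panel
#' markers present.
#'
#' @param sample,reference `msat_profile` objects on the same panel.
#' @param panel An `msat_panel`.
#' @param thresholds An `msat_msi_thresholds`.
#' @return List of class `msat_msi`: `per_marker` data frame (`marker`,
#'   `status`), `overall` ("MSS", "MSI-L" or "MSI-H"), `n_unstable`
#'   (among NCI markers), `excluded`.
#' @export
msi_classify <- function(sample, reference, panel,
                         thresholds = msi_thresholds()) {
  mono <- panel$markers$name[panel$markers$repeat_unit == 1L]
  mks <- unique(sample$calls$marker)
  excluded <- character()
  rows <- lapply(mks, function(mk) {
    sb <- sample$calls$bin[sample$calls$marker == mk]
    rb <- reference$calls$bin[reference$calls$marker == mk]
    sb <- sb[!is.na(sb)]; rb <- rb[!is.na(rb)]
    if (!length(rb)) {
      excluded <<- c(excluded, mk)
      return(NULL)
    }
    unstable <- if (mk %in% mono) {
      thr <- thresholds$mono[[mk]] %||% 3L
      dev <- vapply(sb, function(s) min(abs(s - rb)), numeric(1))
      any(dev >= thr & dev > thresholds$mono_normal)
    } else {
      any(!sb %in% rb)
    }
    data.frame(marker = mk, status = if (unstable) "unstable" else "stable")
  })
  per_marker <- do.call(rbind, rows)
  nci <- per_marker[per_marker$marker %in% thresholds$nci_markers, ,
                    drop = FALSE]
  n_unstable <- sum(nci$status == "unstable")
  overall <- if (n_unstable >= thresholds$msi_high) "MSI-H"
  else if (n_unstable >= 1) "MSI-L" else "MSS"
  structure(list(per_marker = per_marker, overall = overall,
                 n_unstable = n_unstable, excluded = excluded),
            class = "msat_msi")
}

#' @export
print.msat_msi <- function(x, ...) {
  cat(sprintf("<msat_msi: %s (%d unstable NCI markers)>\n", x$overall,
              x$n_unstable))
  print(x$per_marker, row.names = FALSE)
  if (length(x$excluded))
    cat("excluded (missing from reference):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Loss-of-heterozygosity allele ratio
#'
#' For a marker at which the normal sample is heterozygous, computes the
#' standard allele-ratio statistic R = (tumor h1/h2) / (normal h1/h2)
#' using bin-matched allele heights (alleles ordered by bin).  LOH is
#' called when R < `lower` or R > `upper` (strict inequalities; which
#' allele is lost determines the direction).  Swapping allele labels maps
#' R to 1/R and leaves the call unchanged.  Markers with a homozygous
#' normal, or with missing matched heights, are uninformative.
#'
#' @param tumor,normal `msat_profile` objects.
#' @param marker Marker name.
#' @param lower,upper Ratio bounds (defaults 0.5 and 2.0).
#' @return List of class `msat_loh`: `marker`, `ratio`, `informative`,
#'   `call` ("LOH", "retained" or "uninformative").
#' @export
loh_score <- function(tumor, normal, marker, lower = 0.5, upper = 2.0) {
  out <- function(ratio, call, informative = TRUE)
    structure(list(marker = marker, ratio = ratio,
                   informative = informative, call = call),
              class = "msat_loh")
  nc <- normal$calls[normal$calls$marker == marker & !is.na(normal$calls$bin), ]
  tc <- tumor$calls[tumor$calls$marker == marker & !is.na(tumor$calls$bin), ]
  nc <- nc[order(nc$bin), ]
  if (nrow(nc) != 2 || nc$bin[1] == nc$bin[2])
    return(out(NA_real_, "uninformative", FALSE))
  th <- tc$height[match(nc$bin, tc$bin)]
  if (anyNA(th) || anyNA(nc$height) || any(c(th, nc$height) <= 0))
    return(out(NA_real_, "uninformative", FALSE))
  ratio <- (th[1] / th[2]) / (nc$height[1] / nc$height[2])
  out(ratio, if (ratio < lower || ratio > upper) "LOH" else "retained")
}

#' @export
print.msat_loh <- function(x, ...) {
  cat(sprintf("<msat_loh %s: R = %s, %s>\n", x$marker,
              format(x$ratio, digits = 3), x$call))
  invisible(x)
}

#' Mendelian lineage and twin check
#'
#' For each child and marker, the child's allele pair is consistent iff
#' it can be partitioned with one allele from each parent (a single
#' called allele is treated as homozygous).  Where only one orientation
#' is possible the parent of origin of each allele is recorded.  Two
#' children with identical bins at every marker are flagged as possible
#' monozygotic twins.
#'
#' @param children,parents Lists of `msat_profile` objects (two parents).
#' @return List of class `msat_lineage`: `per_marker` data frame
#'   (`child`, `marker`, `consistent`, `origin_a1`, `origin_a2`),
#'   `all_consistent`, `twin_pairs` (data frame of child id pairs).
#' @export
lineage_check <- function(children, parents) {
  stopifnot(length(parents) == 2)
  bins_of <- function(p, mk) {
    b <- p$calls$bin[p$calls$marker == mk]
    b <- b[!is.na(b)]
    if (length(b) == 1) c(b, b) else sort(b)[1:2]
  }
  mks <- unique(parents[[1]]$calls$marker)
  rows <- list()
  for (ch in children) {
    for (mk in mks) {
      cb <- bins_of(ch, mk)
      p1 <- bins_of(parents[[1]], mk)
      p2 <- bins_of(parents[[2]], mk)
      if (anyNA(cb) || anyNA(p1) || anyNA(p2)) {
        rows[[length(rows) + 1L]] <- data.frame(
          child = ch$id, marker = mk, consistent = NA,
          origin_a1 = NA_character_, origin_a2 = NA_character_)
        next
      }
      o1 <- cb[1] %in% p1 && cb[2] %in% p2
      o2 <- cb[2] %in% p1 && cb[1] %in% p2
      origin <- c(NA_character_, NA_character_)
      if (xor(o1, o2)) {
        origin <- if (o1) c("parent1", "parent2") else c("parent2", "parent1")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        child = ch$id, marker = mk, consistent = o1 || o2,
        origin_a1 = origin[1], origin_a2 = origin[2])
    }
  }
  per_marker <- do.call(rbind, rows)
  ## twin flag: identical bins at every marker
  twin_pairs <- list()
  if (length(children) >= 2) {
    sig <- vapply(children, function(ch)
      paste(vapply(mks, function(mk)
        paste(bins_of(ch, mk), collapse = "/"), character(1)),
        collapse = ";"), character(1))
    for (i in seq_along(children)) for (j in seq_len(i - 1)) {
      if (identical(sig[i], sig[j]))
        twin_pairs[[length(twin_pairs) + 1L]] <- data.frame(
          child_a = children[[j]]$id, child_b = children[[i]]$id)
    }
  }
  twin_pairs <- if (length(twin_pairs)) do.call(rbind, twin_pairs)
  else data.frame(child_a = character(), child_b = character())
  structure(list(per_marker = per_marker,
                 all_consistent = all(per_marker$consistent %in% TRUE),
                 twin_pairs = twin_pairs),
            class = "msat_lineage")
}

#' @export
print.msat_lineage <- function(x, ...) {
  cat(sprintf("<msat_lineage: %s%s>\n",
              if (x$all_consistent) "all markers consistent"
              else "inconsistencies present",
              if (nrow(x$twin_pairs)) "; twin pair(s) flagged" else ""))
  invisible(x)
}
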