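# Shared fixtures.  Heavy simulations are cached in this environment so
# that property and acceptance tests reuse one study instead of
# re-simulating (testthat runs all files in one session).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

quiet_run <- function()
  run_conditions(migration_sd = 0, ladder_sd = 0, bleed = 0,
                 spike_rate = 0, nonspecific_rate = 0, baseline = 0,
                 noise_sd = 0)

# Minimal peak table for calling-level tests.
peak_df <- function(sizes, heights, channel = "FAM") {
  n <- length(sizes)
  data.frame(channel = rep(channel, n), apex_scan = seq_len(n),
             height = heights, half_width_points = rep(5, n),
             area = heights, size_bp = sizes,
             method = rep("local_southern", n), sized = rep(TRUE, n))
}

# Ladder fit constructed directly from known (scan, size) pairs, for
# sizing tests that bypass peak detection.
fit_from_pairs <- function(scans, sizes) {
  o <- order(scans)
  scans <- scans[o]; sizes <- sizes[o]
  n <- length(scans)
  structure(list(scans = scans, sizes = sizes, rmse = 0, partial = FALSE,
                 interval_scan = c(scans[2], scans[n - 1]),
                 interval_bp = range(sizes[c(2, n - 1)])),
            class = "msat_ladder_fit")
}

# Hand-built profile for QC/apps tests (same S3 shape as genotype_run()).
fake_profile <- function(id, calls, day = NULL, group = NA) {
  p <- structure(list(id = id, group = group, calls = calls,
                      flags = character(), method = "manual",
                      ladder_rmse = NA_real_),
                 class = "msat_profile")
  if (!is.null(day)) p$day <- day
  p
}

call_rows <- function(marker, bins, heights = NULL, sizes = NULL) {
  heights <- heights %||% rep(2000, length(bins))
  sizes <- sizes %||% bins
  data.frame(marker = marker, size_bp = sizes, bin = bins,
             height = heights, ratio = heights / max(heights),
             rank = seq_along(bins))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 100-sample end-to-end study at nominal noise, both multiplex groups;
# returns genotypes, called profiles and the per-run simulation truths.
study_100 <- function() cached("study100", {
  panel <- builtin_panel()
  freqs <- default_allele_freqs(panel)
  genotypes <- lapply(seq_len(100), function(i)
    sample_genotype(panel, freqs, id = sprintf("S%03d", i), seed = 5000 + i))
  profiles <- lapply(genotypes, function(g) {
    idx <- as.integer(sub("S", "", g$id))
    parts <- lapply(1:2, function(gr) {
      sim <- simulate_run(g, panel, group = gr,
                          seed = 10000L + idx * 10L + gr)
      genotype_run(sim$trace, panel, group = gr, id = g$id)
    })
    merged <- parts[[1]]
    merged$calls <- rbind(parts[[1]]$calls, parts[[2]]$calls)
    merged$flags <- c(parts[[1]]$flags, parts[[2]]$flags)
    merged$group <- 1:2
    merged
  })
  list(panel = panel, genotypes = genotypes, profiles = profiles)
})
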