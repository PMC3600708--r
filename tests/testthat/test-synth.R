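test_that("genotype sampling is seed-deterministic and respects degenerate
           frequencies", {
  panel <- builtin_panel()
  g1 <- sample_genotype(panel, id = "a", seed = 99)
  g2 <- sample_genotype(panel, id = "a", seed = 99)
  expect_identical(g1, g2)
  hom <- sample_genotype(panel, freqs = list(D9S171 = c("112" = 1)),
                         seed = 1)
  expect_equal(hom$alleles$a1, 112)
  expect_equal(hom$alleles$a2, 112)
  expect_error(sample_genotype(panel, freqs = list()), "empty")
  expect_error(sample_genotype(panel,
                               freqs = list(D9S171 = c("112" = 0.4))),
               "sum to 1")
})

test_that("heterozygosity of a two-allele marker at p = 0.5 matches the
           binomial expectation", {
  panel <- builtin_panel()
  freqs <- list(D9S171 = c("110" = 0.5, "112" = 0.5))
  het <- vapply(seq_len(1e4), function(i) {
    g <- sample_genotype(panel, freqs, seed = 20000 + i)
    g$alleles$a1 != g$alleles$a2
  }, logical(1))
  expect_equal(mean(het), 0.5, tolerance = 0.02)
})

test_that("Bat markers are drawn quasimonomorphic", {
  panel <- builtin_panel()
  freqs <- default_allele_freqs(panel)
  expect_gte(max(freqs$BAT25), 0.95)
  expect_gte(max(freqs$BAT26), 0.95)
  expect_equal(as.numeric(names(freqs$BAT25)[which.max(freqs$BAT25)]), 126)
  expect_equal(as.numeric(names(freqs$BAT26)[which.max(freqs$BAT26)]), 121)
})

test_that("children inherit one allele per marker from each parent; twins
           are identical", {
  panel <- builtin_panel()
  p1 <- sample_genotype(panel, id = "p1", seed = 41)
  p2 <- sample_genotype(panel, id = "p2", seed = 42)
  fam <- make_family(p1, p2, n_children = 4, seed = 43)
  for (ch in fam$children) {
    for (i in seq_len(nrow(ch$alleles))) {
      a <- unlist(ch$alleles[i, c("a1", "a2")])
      P1 <- unlist(p1$alleles[i, c("a1", "a2")])
      P2 <- unlist(p2$alleles[i, c("a1", "a2")])
      ok <- (a[1] %in% P1 && a[2] %in% P2) || (a[2] %in% P1 && a[1] %in% P2)
      expect_true(ok, info = paste(ch$id, ch$alleles$marker[i]))
    }
  }
  ## fully homozygous parents force identical heterozygous children
  homA <- p1; homA$alleles$a1 <- homA$alleles$a2 <- 100
  homB <- p2; homB$alleles$a1 <- homB$alleles$a2 <- 104
  fab <- make_family(homA, homB, n_children = 3, seed = 44)
  for (ch in fab$children) {
    expect_true(all(ch$alleles$a1 == 100), info = ch$id)
    expect_true(all(ch$alleles$a2 == 104), info = ch$id)
  }
  tw <- make_family(p1, p2, n_children = 2, twins = TRUE, seed = 45)
  expect_identical(tw$children[[1]]$alleles, tw$children[[2]]$alleles)
})

test_that("apply_msi shifts one allele, keeps the lattice and flags
           out-of-window results", {
  panel <- builtin_panel()
  g <- control_genotype(panel)
  expect_identical(apply_msi(g, "BAT26", 0)$alleles, g$alleles)
  ## apparent Bat26 at 122 contracting by 5 nt reads 117
  g122 <- g
  g122$alleles$a1[g122$alleles$marker == "BAT26"] <- 122
  shifted <- apply_msi(g122, "BAT26", -5)
  expect_equal(shifted$alleles$a1[shifted$alleles$marker == "BAT26"], 117)
  d <- apply_msi(g, "D2S123", -2, panel = panel)
  expect_equal(d$alleles$a1[d$alleles$marker == "D2S123"], 208)
  expect_equal(d$alleles$a1[d$alleles$marker == "D2S123"] %% 2,
               g$alleles$a1[g$alleles$marker == "D2S123"] %% 2)
  far <- apply_msi(g, "D9S171", -40, panel = panel)
  expect_equal(attr(far, "out_of_window"), "D9S171")
  expect_error(apply_msi(g, "NOPE", 2), "not in genotype")
})

test_that("amplicon peaks follow the geometric stutter law and the
           adenylation split", {
  panel <- builtin_panel()
  g <- control_genotype(panel)
  g$alleles <- data.frame(marker = "D18S61", a1 = 160, a2 = 170)
  ## fixed ratio 0.5, no adenylation, fixed height: 1000, 500, 250, 125...
  st <- stutter_model(di_ratio_range = c(0.5, 0.5), adenylation = 0,
                      floor_frac = 0.1)
  ap <- amplicon_peaks(g, panel, st, height_range = c(1000, 1000),
                       allele_sdlog = 0, seed = 1)
  a160 <- ap[ap$allele == 160, ]
  expect_equal(a160$size, c(154, 156, 158, 160))
  expect_equal(a160$height, c(125, 250, 500, 1000))
  expect_setequal(ap$kind[ap$size %in% c(160, 170)], "main")
  ## full adenylation: apparent size = template + 1
  ap1 <- amplicon_peaks(g, panel, stutter_model(di_ratio_range = c(0.5, 0.5),
                                                floor_frac = 0.6),
                        height_range = c(1000, 1000), allele_sdlog = 0,
                        seed = 1)
  expect_setequal(ap1$size[ap1$kind == "main"], c(161, 171))
  ## half adenylation splits each product into equal +0/+1 peaks
  ap05 <- amplicon_peaks(g, panel,
                         stutter_model(di_ratio_range = c(0.5, 0.5),
                                       adenylation = 0.5, floor_frac = 0.6),
                         height_range = c(1000, 1000), allele_sdlog = 0,
                         seed = 1)
  m160 <- ap05[ap05$allele == 160 & ap05$kind == "main", ]
  expect_setequal(m160$size, c(160, 161))
  expect_equal(m160$height, c(500, 500))
})

test_that("mobility is strictly increasing and rendering is
           seed-deterministic", {
  mob <- mobility_model()
  L <- seq(35, 500, by = 0.5)
  expect_true(all(diff(mobility_scan(mob, L)) > 0))
  expect_error(mobility_model(c = 9e6), "strictly increasing")
  panel <- builtin_panel()
  g <- control_genotype(panel)
  s1 <- simulate_run(g, panel, group = 2, seed = 77)
  s2 <- simulate_run(g, panel, group = 2, seed = 77)
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_run(g, panel, group = 2, seed = 78)
  expect_false(identical(s1$trace, s3$trace))
})

test_that("bleed-through copies HEX signal into FAM at the bleed
           coefficient; zero bleed leaves FAM clean", {
  pk <- data.frame(marker = "X", dye = "HEX", allele = 170, size = 170,
                   height = 2000, kind = "main")
  run0 <- quiet_run()
  run0$bleed <- 0.1
  sim <- render_trace(pk, run = run0, ladder = NULL, seed = 5)
  expect_equal(max(sim$trace$FAM), 200, tolerance = 0.01)
  expect_equal(which.max(sim$trace$FAM), which.max(sim$trace$HEX))
  expect_true(any(sim$truth$kind == "bleed" & sim$truth$channel == "FAM"))
  simz <- render_trace(pk, run = quiet_run(), ladder = NULL, seed = 5)
  expect_equal(max(simz$trace$FAM), 0)
})

test_that("a ladder-only render carries exactly the ladder's fragments on
           ROX, recovered to better than 0.05 bp at zero migration noise", {
  panel <- builtin_panel()
  g <- control_genotype(panel)
  sim <- simulate_run(g, panel, group = 1, run = quiet_run(), seed = 55)
  pk <- detect_peaks(sim$trace, panel$params, group = 1)
  rox <- pk[pk$channel == "ROX", ]
  expect_equal(nrow(rox), 16)
  fit <- match_ladder(rox, panel$ladder)
  sized <- size_peaks(pk[pk$channel != "ROX", ], fit)
  truth <- sim$truth[sim$truth$kind %in% c("main", "stutter") &
                       sim$truth$height >= 100, ]
  for (i in seq_len(nrow(truth))) {
    hit <- sized[sized$channel == truth$channel[i] & sized$sized &
                   abs(sized$size_bp - truth$size[i]) < 0.5, ]
    expect_gte(nrow(hit), 1)
    expect_lt(min(abs(hit$size_bp - truth$size[i])), 0.05)
  }
})
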