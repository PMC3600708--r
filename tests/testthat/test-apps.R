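test_that("a sample classified against itself is MSS with every marker
           stable", {
  panel <- builtin_panel()
  prof <- profile_from_truth(sample_genotype(panel, seed = 71), panel)
  res <- msi_classify(prof, prof, panel)
  expect_equal(res$overall, "MSS")
  expect_equal(res$n_unstable, 0)
  expect_true(all(res$per_marker$status == "stable"))
})

test_that("mono thresholds separate slippage from somatic alteration", {
  panel <- builtin_panel()
  ref <- profile_from_truth(control_genotype(panel), panel)
  shift_bin <- function(p, marker, by) {
    i <- which(p$calls$marker == marker)[1]
    p$calls$bin[i] <- p$calls$bin[i] + by
    p$calls$size_bp[i] <- p$calls$size_bp[i] + by
    p
  }
  ## +1 nt on Bat25 is normal
  res1 <- msi_classify(shift_bin(ref, "BAT25", 1), ref, panel)
  expect_equal(res1$per_marker$status[res1$per_marker$marker == "BAT25"],
               "stable")
  ## -4 nt on Bat26 crosses its >= 4 bp threshold
  res2 <- msi_classify(shift_bin(ref, "BAT26", -4), ref, panel)
  expect_equal(res2$per_marker$status[res2$per_marker$marker == "BAT26"],
               "unstable")
  expect_equal(res2$overall, "MSI-L")
  ## +2 on Bat25 stays under its 3 bp threshold
  res3 <- msi_classify(shift_bin(ref, "BAT25", 2), ref, panel)
  expect_equal(res3$per_marker$status[res3$per_marker$marker == "BAT25"],
               "stable")
})

test_that("novel dinucleotide bins are unstable and two NCI markers give
           MSI-H", {
  panel <- builtin_panel()
  ref <- profile_from_truth(control_genotype(panel), panel)
  samp <- ref
  i <- which(samp$calls$marker == "D2S123" & samp$calls$rank == 1)
  samp$calls$bin[i] <- samp$calls$bin[i] - 6
  j <- which(samp$calls$marker == "BAT26")[1]
  samp$calls$bin[j] <- samp$calls$bin[j] - 5
  res <- msi_classify(samp, ref, panel)
  pm <- res$per_marker
  expect_equal(pm$status[pm$marker == "D2S123"], "unstable")
  expect_equal(pm$status[pm$marker == "BAT26"], "unstable")
  expect_equal(res$n_unstable, 2)
  expect_equal(res$overall, "MSI-H")
  ## non-NCI dinucleotide instability does not drive the overall status
  samp2 <- ref
  k <- which(samp2$calls$marker == "D18S61" & samp2$calls$rank == 1)
  samp2$calls$bin[k] <- samp2$calls$bin[k] + 4
  expect_equal(msi_classify(samp2, ref, panel)$overall, "MSS")
})

test_that("markers missing from the reference are excluded and noted", {
  panel <- builtin_panel()
  ref <- profile_from_truth(control_genotype(panel), panel)
  ref$calls <- ref$calls[ref$calls$marker != "D17S250", ]
  samp <- profile_from_truth(control_genotype(panel), panel)
  res <- msi_classify(samp, ref, panel)
  expect_true("D17S250" %in% res$excluded)
  expect_false("D17S250" %in% res$per_marker$marker)
})

loh_profiles <- function(t_h1, t_h2, n_h1 = 1000, n_h2 = 1000,
                         n_bins = c(211, 219)) {
  normal <- fake_profile("N", call_rows("D2S123", n_bins,
                                        heights = c(n_h1, n_h2)))
  tumor <- fake_profile("T", call_rows("D2S123", c(211, 219),
                                       heights = c(t_h1, t_h2)))
  list(tumor = tumor, normal = normal)
}

test_that("LOH ratio statistic and strict bounds behave as specified", {
  p <- loh_profiles(1000, 1000)
  res <- loh_score(p$tumor, p$normal, "D2S123")
  expect_equal(res$ratio, 1)
  expect_equal(res$call, "retained")
  ## allele 2 halved: R = 2.0 exactly -> boundary, not called
  p2 <- loh_profiles(1000, 500)
  expect_equal(loh_score(p2$tumor, p2$normal, "D2S123")$ratio, 2)
  expect_equal(loh_score(p2$tumor, p2$normal, "D2S123")$call, "retained")
  p3 <- loh_profiles(1000, 480)
  expect_equal(loh_score(p3$tumor, p3$normal, "D2S123")$call, "LOH")
  ## homozygous normal is uninformative
  p4 <- loh_profiles(1000, 900, n_bins = c(211, 211))
  res4 <- loh_score(p4$tumor, p4$normal, "D2S123")
  expect_equal(res4$call, "uninformative")
  expect_false(res4$informative)
})

test_that("LOH is reciprocal-symmetric under allele relabelling", {
  set.seed(12)
  for (i in 1:20) {
    h <- runif(4, 300, 3000)
    a <- loh_profiles(h[1], h[2], h[3], h[4])
    r <- loh_score(a$tumor, a$normal, "D2S123")
    ## swap the two alleles in both profiles (reverse bin order)
    swap <- function(p) {
      p$calls <- p$calls[2:1, ]
      p$calls$bin <- c(205, 213)  # relabel keeping order
      p
    }
    b <- list(tumor = swap(a$tumor), normal = swap(a$normal))
    r2 <- loh_score(b$tumor, b$normal, "D2S123")
    expect_equal(r2$ratio, 1 / r$ratio, tolerance = 1e-12)
    expect_equal(r2$call, r$call)
  }
})

test_that("families from make_family always pass the lineage check and
           twins are flagged", {
  panel <- builtin_panel()
  for (s in 1:5) {
    p1 <- sample_genotype(panel, id = "p1", seed = 300 + s)
    p2 <- sample_genotype(panel, id = "p2", seed = 400 + s)
    fam <- make_family(p1, p2, n_children = 3, seed = 500 + s)
    profs <- lapply(c(fam$parents, fam$children), profile_from_truth,
                    panel = panel)
    res <- lineage_check(profs[3:5], profs[1:2])
    expect_true(res$all_consistent, info = paste("family seed", s))
  }
  p1 <- sample_genotype(panel, id = "p1", seed = 310)
  p2 <- sample_genotype(panel, id = "p2", seed = 410)
  tw <- make_family(p1, p2, n_children = 2, twins = TRUE, seed = 510)
  profs <- lapply(c(tw$parents, tw$children), profile_from_truth,
                  panel = panel)
  res <- lineage_check(profs[3:4], profs[1:2])
  expect_true(res$all_consistent)
  expect_equal(nrow(res$twin_pairs), 1)
  expect_setequal(unlist(res$twin_pairs[1, ]), c("child1", "child2"))
})

test_that("a foreign allele breaks consistency at exactly that marker", {
  panel <- builtin_panel()
  p1 <- sample_genotype(panel, id = "p1", seed = 320)
  p2 <- sample_genotype(panel, id = "p2", seed = 420)
  fam <- make_family(p1, p2, n_children = 1, seed = 520)
  child <- fam$children[[1]]
  ## give the child an allele neither parent carries
  i <- which(child$alleles$marker == "D9S171")
  child$alleles$a1[i] <- max(p1$alleles$a1[i], p1$alleles$a2[i],
                             p2$alleles$a1[i], p2$alleles$a2[i]) + 4
  profs <- lapply(list(p1, p2, child), profile_from_truth, panel = panel)
  res <- lineage_check(profs[3], profs[1:2])
  pm <- res$per_marker
  expect_false(pm$consistent[pm$marker == "D9S171"])
  expect_true(all(pm$consistent[pm$marker != "D9S171"]))
  expect_false(res$all_consistent)
})

test_that("parent of origin is recorded when unambiguous", {
  panel <- builtin_panel()
  p1 <- control_genotype(panel, id = "p1")
  p2 <- control_genotype(panel, id = "p2")
  ## make parents fully distinct at D2S123: p1 {210,212}, p2 {230,232}
  fix <- function(g, a, b) {
    i <- g$alleles$marker == "D2S123"
    g$alleles$a1[i] <- a; g$alleles$a2[i] <- b
    g
  }
  p1 <- fix(p1, 210, 212); p2 <- fix(p2, 230, 232)
  fam <- make_family(p1, p2, n_children = 1, seed = 530)
  profs <- lapply(c(list(p1, p2), fam$children), profile_from_truth,
                  panel = panel)
  res <- lineage_check(profs[3], profs[1:2])
  row <- res$per_marker[res$per_marker$marker == "D2S123", ]
  expect_true(row$consistent)
  expect_setequal(c(row$origin_a1, row$origin_a2), c("parent1", "parent2"))
})
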