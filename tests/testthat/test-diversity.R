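test_that("hypergeometric rarefaction matches closed forms and the exhaustive oracle", {
  # counts {A:6, B:2}, g = 4: AR = 1 + (1 - C(6,4)/C(8,4)) = 1.785714...
  gt <- bind_rows(
    gt_row("s1", "p1", "population", list(L1 = c(1, 1))),
    gt_row("s2", "p1", "population", list(L1 = c(1, 1))),
    gt_row("s3", "p1", "population", list(L1 = c(1, 1))),
    gt_row("s4", "p1", "population", list(L1 = c(2, 2))))
  ar <- allelic_richness(gt, by = "population", g = 4)
  expect_equal(ar$AR, 1 + (1 - 15 / 70), tolerance = 1e-12)
  expect_equal(ar$AR, enum_rarefaction(c(6, 2), 4), tolerance = 1e-12)

  # monomorphic locus contributes exactly 1; g = N gives the observed count
  gt_mono <- bind_rows(gt_row("s1", "p1", "population", list(L1 = c(5, 5))),
                       gt_row("s2", "p1", "population", list(L1 = c(5, 5))))
  expect_equal(allelic_richness(gt_mono, by = "population", g = 2)$AR, 1)
  expect_equal(allelic_richness(gt, by = "population", g = 8)$AR, 2)

  # errors: depth exceeding copies, named locus
  expect_error(allelic_richness(gt, by = "population", g = 10), "L1")
})

test_that("rarefaction equals exhaustive enumeration on random fixtures", {
  for (s in 1:30) {
    gt <- random_gt(s, n_samples = 5, n_loci = 2, k = 4)
    counts <- allele_frequencies(gt, by = "population")
    ar <- tryCatch(allelic_richness(gt, by = "population", g = "auto"),
                   error = function(e) NULL)
    if (is.null(ar)) next
    per_locus <- attr(ar, "per_locus")
    for (r in seq_len(nrow(per_locus))) {
      loc <- as.character(per_locus$locus[r])
      sub <- filter(counts, locus == loc)
      n_i <- round(sub$freq * sub$n_copies)
      expect_equal(per_locus$AR_locus[r],
                   enum_rarefaction(n_i, per_locus$g[r]), tolerance = 1e-9)
    }
  }
})

test_that("rarefied richness is monotone in depth", {
  gt <- random_gt(99, n_samples = 8, n_loci = 3, k = 5, missing_rate = 0)
  ars <- sapply(c(2, 4, 8, 16), function(g)
    allelic_richness(gt, by = "population", g = g)$AR)
  expect_true(all(diff(ars) >= -1e-12))
})

test_that("indices are invariant to sample order and within-call allele order", {
  gt <- random_gt(7, n_samples = 8, n_loci = 3, k = 4)
  swap <- gt
  swap[, c("L01_1", "L01_2")] <- swap[, c("L01_2", "L01_1")]
  swap <- arrange(swap, desc(sample_id))
  a <- diversity_summary(gt, by = "population")
  b <- diversity_summary(swap, by = "population")
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("private alleles are per-locus set differences summed", {
  gt <- bind_rows(
    gt_row("s1", "p1", "population", list(L1 = c(1, 2), L2 = c(1, 1))),
    gt_row("s2", "p1", "population", list(L1 = c(3, 3), L2 = c(2, 2))),
    gt_row("t1", "p1", "seed", list(L1 = c(2, 3), L2 = c(2, 3)), bunch = "B"),
    gt_row("t2", "p1", "seed", list(L1 = c(4, 4), L2 = c(3, 4)), bunch = "B"))
  # L1: pop {1,2,3} vs seed {2,3,4} -> (1,1); L2: {1,2} vs {2,3,4} -> (1,2)
  pa <- private_alleles(gt, by = "role")
  expect_equal(pa$n_private[pa$role == "population"], 2)
  expect_equal(pa$n_private[pa$role == "seed"], 3)

  # identical groups share everything
  same <- mutate(gt[1:2, ], role = c("population", "population"))
  both <- bind_rows(same, mutate(same, role = "seed",
                                 bunch = "B", sample_id = c("x1", "x2")))
  pa2 <- private_alleles(both, by = "role")
  expect_equal(pa2$n_private, c(0, 0))
})

test_that("MLG counting uses unordered pairs and missing-as-state", {
  gt <- bind_rows(
    gt_row("s1", "p1", "population", list(L1 = c(1, 2))),
    gt_row("s2", "p1", "population", list(L1 = c(2, 1))),
    gt_row("s3", "p1", "population", list(L1 = c(1, 1))),
    gt_row("s4", "p1", "population", list(L1 = c(NA, NA))))
  res <- count_mlg(gt)
  expect_equal(res$MLG, 3) # (1,2)==(2,1); (1,1); missing distinct
  asn <- attr(res, "assignments")
  expect_equal(asn$mlg[1], asn$mlg[2])

  # wildcard mode lets the missing call match anything
  res_w <- count_mlg(gt, missing = "wildcard")
  expect_equal(res_w$MLG, 2)

  # three identical samples are one MLG
  clones <- bind_rows(lapply(1:3, function(i)
    gt_row(paste0("c", i), "p1", "population", list(L1 = c(1, 2)))))
  expect_equal(count_mlg(clones)$MLG, 1)
})

test_that("genotypic diversity indices match direct formula evaluation", {
  gd <- genotypic_diversity(c(2, 1, 1))
  expect_equal(gd$Hprime, 1.039721, tolerance = 1e-6)
  expect_equal(gd$lambda, 0.625)
  # direct evaluation: ((1/0.375) - 1)/(exp(H') - 1), exp(H') = 2 sqrt(2)
  expect_equal(gd$E5, (1 / 0.375 - 1) / (2 * sqrt(2) - 1), tolerance = 1e-9)

  # uniform: H' = ln k, lambda = 1 - 1/k, E5 = 1
  gd_u <- genotypic_diversity(rep(3, 7))
  expect_equal(gd_u$Hprime, log(7))
  expect_equal(gd_u$lambda, 1 - 1 / 7)
  expect_equal(gd_u$E5, 1)

  # degenerate single MLG
  gd_1 <- genotypic_diversity(5)
  expect_equal(unlist(gd_1), c(Hprime = 0, lambda = 0, E5 = 1))
  expect_error(genotypic_diversity(numeric(0)), "empty")
})

test_that("heterozygosity and Fis follow the unbiased Nei formulas", {
  gt <- bind_rows(
    gt_row("s1", "p1", "population", list(L1 = c(1, 2))),
    gt_row("s2", "p1", "population", list(L1 = c(1, 2))))
  het <- heterozygosity(gt, by = "population")
  expect_equal(het$Ho, 1)
  expect_equal(het$Hexp, (4 / 3) * 0.5, tolerance = 1e-12)
  expect_equal(heterozygosity(gt, by = "population", unbiased = FALSE)$Hexp,
               0.5)
  fis <- inbreeding_coefficient(gt, by = "population")
  expect_equal(fis$Fis, -0.5, tolerance = 1e-12)

  # all homozygous: Ho = Hexp = 0, Fis undefined
  hom <- bind_rows(gt_row("s1", "p1", "population", list(L1 = c(1, 1))),
                   gt_row("s2", "p1", "population", list(L1 = c(1, 1))))
  het0 <- heterozygosity(hom, by = "population")
  expect_equal(c(het0$Ho, het0$Hexp), c(0, 0))
  expect_warning(fis0 <- inbreeding_coefficient(hom, by = "population"),
                 "undefined")
  expect_true(is.na(fis0$Fis))

  # complete inbreeding: Ho = 0 with polymorphism -> Fis = 1
  inb <- bind_rows(gt_row("s1", "p1", "population", list(L1 = c(1, 1))),
                   gt_row("s2", "p1", "population", list(L1 = c(2, 2))))
  expect_equal(inbreeding_coefficient(inb, by = "population")$Fis, 1)

  # bounds on random data
  for (s in 1:5) {
    h <- heterozygosity(random_gt(s, 8, 3), by = "population")
    expect_true(h$Ho >= 0 && h$Ho <= 1 && h$Hexp >= 0 && h$Hexp < 1)
  }
})

test_that("capture proportion reproduces the published regional ratios", {
  expect_equal(capture_proportion(37, 73, digits = 0), 51)
  expect_equal(capture_proportion(224, 242, digits = 0), 93)
  expect_equal(capture_proportion(50, 50), 100)
  expect_error(capture_proportion(10, 0), "zero")
})

test_that("Welch t test matches hand evaluation and is antisymmetric", {
  res <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  swapped <- welch_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  # degenerate equal constants: t = 0, p = 1
  expect_equal(welch_t_test(c(2, 2), c(2, 2))[, c("t", "p")],
               tibble(t = 0, p = 1))
})

test_that("allele frequency spectrum flags rare alleles", {
  gt <- bind_rows(lapply(1:13, function(i)
    gt_row(paste0("s", i), "p1", "population",
           list(L1 = if (i == 1) c(1, 2) else c(1, 1)))))
  sp <- allele_frequency_spectrum(gt, by = "population",
                                  rare_threshold = 0.05)
  expect_equal(sort(sp$freq), c(1 / 26, 25 / 26))
  expect_equal(attr(sp, "rare_counts")$n_rare, 1)
})

test_that("diversity summary reproduces the component indices per group", {
  gt <- sim_dataset_example()
  ds <- diversity_summary(gt, by = "role")
  expect_equal(ds$N, as.integer(table(gt$role)[c("population", "seed")]),
               ignore_attr = TRUE)
  ar <- allelic_richness(gt, by = "role")
  expect_equal(ds$AR, ar$AR)
  expect_equal(ds$MLG, count_mlg(gt, by = "role")$MLG)
  expect_true(all(ds$MLG <= ds$N))
  expect_true(all(ds$lambda >= 0 & ds$lambda < 1))
  expect_true(all(ds$E5 > 0 & ds$E5 <= 1))
  pa <- private_alleles(gt, by = "role")
  expect_equal(ds$PA, pa$n_private)
})
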