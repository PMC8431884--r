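test_that("mismatch distances count allele differences per locus", {
  gt <- bind_rows(
    gt_row("s1", "p1", "population", list(L1 = c(1, 2), L2 = c(1, 1))),
    gt_row("s2", "p1", "population", list(L1 = c(2, 1), L2 = c(1, 2))),
    gt_row("s3", "p1", "population", list(L1 = c(3, 3), L2 = c(3, 3))))
  d <- individual_distances(gt)
  expect_equal(d["s1", "s2"], 0 + 1)  # same unordered pair; one shared
  expect_equal(d["s1", "s3"], 2 + 2)  # no alleles shared at either locus
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_true(isSymmetric(unname(d)))

  # pairwise deletion rescales by loci compared
  gt$L2_1[2] <- NA; gt$L2_2[2] <- NA
  d2 <- individual_distances(gt)
  expect_equal(d2["s1", "s2"], 0 * 2 / 1) # only L1 compared, rescaled x2
  expect_equal(d2["s2", "s3"], 2 * 2 / 1)
})

test_that("AMOVA reproduces the degenerate partitions", {
  # two internally-clonal populations that differ: all variance among
  clone <- function(pop, ids, g1, g2) bind_rows(lapply(ids, function(i)
    gt_row(paste0(pop, i), pop, "population", list(L1 = g1, L2 = g2))))
  gt <- bind_rows(clone("pa", 1:4, c(1, 1), c(5, 5)),
                  clone("pb", 1:4, c(2, 2), c(6, 6)))
  res <- amova(gt)
  expect_equal(res$phi, 1)
  expect_equal(res$percent_within, 0)

  # one population split under two labels: no structure
  gt2 <- random_gt(3, n_samples = 12, n_loci = 4, k = 3, missing_rate = 0)
  gt2$population <- rep(c("x", "y"), each = 6)
  res2 <- amova(gt2)
  expect_lt(res2$phi, 0.15)
  expect_gt(res2$percent_within, 85)

  expect_error(amova(gt[c(1, 5), ]), "single sample")
})

test_that("AMOVA components equal the definitional sums-of-squares oracle", {
  for (s in 1:6) {
    gt <- random_gt(s, n_samples = 10, n_loci = 4, k = 4, missing_rate = 0.1)
    gt$population <- rep(c("g1", "g2"), each = 5)
    res <- amova(gt)
    d2 <- individual_distances(gt)^2
    oracle <- amova_oracle(d2, gt$population)
    expect_equal(res$ssd[["among"]], oracle$ssd_among, tolerance = 1e-9)
    expect_equal(res$ssd[["within"]], oracle$ssd_within, tolerance = 1e-9)
    expect_equal(unname(res$sigma2), unname(oracle$sigma2), tolerance = 1e-9)
    expect_equal(res$phi, oracle$phi, tolerance = 1e-9)
  }
})

test_that("AMOVA permutation p is plus-one corrected and maximal structure is extreme", {
  clone <- function(pop, n, g1) bind_rows(lapply(seq_len(n), function(i)
    gt_row(paste0(pop, i), pop, "population", list(L1 = g1))))
  gt <- bind_rows(clone("pa", 6, c(1, 1)), clone("pb", 10, c(2, 2)))
  res <- amova_permutation_test(gt, n_permutations = 199, seed = 5)
  expect_equal(res$p, 1 / 200) # no permuted partition re-separates the clones
  expect_gt(res$p, 0)

  phi_perm <- attr(res, "phi_perm")
  expect_equal(length(phi_perm), 199)
  expect_true(all(phi_perm <= res$phi + 1e-12))
})

test_that("phi rises with the simulated differentiation parameter", {
  mean_phi <- sapply(c(0.05, 0.3), function(th) {
    mean(sapply(1:5, function(s) {
      cfg <- sim_config(n_loci = 8, alleles_per_locus = 6, theta = th,
                        n_populations = 4, n_adults_per_pop = 10,
                        seeds_per_bunch = 1, missing_rate = 0, rng_seed = s)
      amova(simulate_dataset(cfg)$data)$phi
    }))
  })
  expect_gt(mean_phi[2], mean_phi[1])
})

test_that("Nei distance matches direct formula evaluation and its invariances", {
  one_pop <- function(pop, geno) bind_rows(
    gt_row(paste0(pop, 1), pop, "population", list(L1 = geno[[1]])),
    gt_row(paste0(pop, 2), pop, "population", list(L1 = geno[[2]])))
  # X = (0.5, 0.5), Y = (1, 0): I = 0.707..., D = 0.3465736
  gt <- bind_rows(one_pop("px", list(c(1, 1), c(2, 2))),
                  one_pop("py", list(c(1, 1), c(1, 1))))
  d <- nei_distance(gt, by = "population")
  expect_equal(as.numeric(d), -log(0.5 / sqrt(0.5)), tolerance = 1e-9)

  # identical profiles -> 0; disjoint -> Inf, flagged
  gt_same <- bind_rows(one_pop("px", list(c(1, 2), c(1, 2))),
                       one_pop("py", list(c(1, 2), c(1, 2))))
  expect_equal(as.numeric(nei_distance(gt_same, by = "population")), 0)
  gt_dis <- bind_rows(one_pop("px", list(c(1, 1), c(1, 1))),
                      one_pop("py", list(c(2, 2), c(2, 2))))
  d_inf <- nei_distance(gt_dis, by = "population")
  expect_true(is.infinite(as.numeric(d_inf)))
  expect_true(attr(d_inf, "has_infinite"))

  # invariance to allele relabelling
  gt_re <- gt
  for (col in c("L1_1", "L1_2")) gt_re[[col]] <- gt_re[[col]] * 7L + 3L
  expect_equal(as.numeric(nei_distance(gt_re, by = "population")),
               as.numeric(d), tolerance = 1e-12)
})

test_that("complete-linkage clustering merges in the documented order", {
  m <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- hierarchical_clustering(m)
  expect_equal(hc$height, c(1, 5))
  expect_equal(sort(hc$labels[-hc$merge[1, ]]), c("A", "B"))
  nwk <- as_newick(hc)
  expect_match(nwk, "^\\(")
  expect_match(nwk, "C")

  # label permutation leaves merge heights unchanged
  p <- c(3, 1, 2)
  hc2 <- hierarchical_clustering(m[p, p])
  expect_equal(hc2$height, hc$height)

  expect_error(hierarchical_clustering(matrix(c(0, Inf, Inf, 0), 2)),
               "infinite|cap")
})

test_that("Mantel test detects perfect affine relation and respects invariances", {
  set.seed(1)
  m <- as.matrix(dist(cbind(runif(6), runif(6))))
  dimnames(m) <- list(letters[1:6], letters[1:6])
  res <- mantel_test(m, 2 * m + 3, n_permutations = 99, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 100)

  # relabelling both matrices identically leaves r unchanged
  b <- as.matrix(dist(cbind(runif(6), runif(6))))
  dimnames(b) <- dimnames(m)
  r0 <- mantel_test(m, b, n_permutations = 19, seed = 2)$r
  p <- sample(6)
  r1 <- mantel_test(m[p, p], b[p, p], n_permutations = 19, seed = 2)$r
  expect_equal(r1, r0, tolerance = 1e-12)

  expect_error(mantel_test(m[1:2, 1:2], m[1:2, 1:2]), "3 labels")
})

test_that("Mantel agrees with the independent vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(9)
  a <- dist(cbind(runif(7), runif(7)))
  b <- dist(cbind(runif(7), runif(7)))
  ours <- mantel_test(a, b, n_permutations = 999, seed = 3)
  ref <- vegan::mantel(a, b, permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.06)
})

test_that("Mantel detects the simulator's spatial gradient", {
  hits <- sapply(1:20, function(s) {
    cfg <- sim_preset("maclayi_like", n_loci = 10, n_adults_per_pop = 10,
                      seeds_per_bunch = 2, n_populations = 6,
                      missing_rate = 0)
    gt <- simulate_dataset(cfg, seed = s)$data
    pops <- pool_genotypes(gt, "population")
    res <- mantel_test(geo_distance(pops, by = "population"),
                       nei_distance(pops, by = "population"),
                       n_permutations = 199, seed = s)
    res$p <= 0.05
  })
  expect_gte(mean(hits), 0.8)
})
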