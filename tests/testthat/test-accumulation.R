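test_that("incidence matrices record presence per unit", {
  gt <- gt_tiny()
  inc <- build_incidence(gt, unit = "population")
  expect_equal(inc$units, c("p1", "p2"))
  # L1: p1 has {101,103}, p2 has {103,105}; L2: p1 {200,202}, p2 {200,202}
  f <- colSums(inc$presence) / nrow(inc$presence)
  key <- paste(inc$alleles$locus, inc$alleles$allele)
  expect_equal(unname(f[match(c("L1 101", "L1 103", "L1 105"), key)]),
               c(0.5, 1, 0.5))

  # presence semantics: duplicating a sample changes nothing
  dup <- bind_rows(gt, mutate(gt[1, ], sample_id = "a1bis"))
  expect_equal(build_incidence(dup, unit = "population")$presence,
               inc$presence)

  # no seeds -> bunch incidence errors
  expect_error(build_incidence(filter(gt, role == "population"),
                               unit = "bunch"), "no samples")
  # seed units need a single bunch unless specified
  expect_error(build_incidence(gt, unit = "seed"), "bunch")
  inc_s <- build_incidence(gt, unit = "seed", bunch = "B1")
  expect_equal(inc_s$units, "s1")
})

test_that("richness extrapolators match hand-evaluated closed forms", {
  # 5 units; one allele in exactly 1 unit, four alleles in all 5
  inc <- incidence_from_sets(list(u1 = c(1, 2, 3, 4, 9),
                                  u2 = 1:4, u3 = 1:4, u4 = 1:4, u5 = 1:4))
  boot <- extrapolate_total_richness(inc, "bootstrap")
  expect_equal(boot$S_hat, 5 + 0.8^5, tolerance = 1e-12)
  expect_equal(boot$S_obs, 5)

  # chao2 with S_obs = 5, q1 = 2, q2 = 1 -> 5 + 4/2 = 7
  inc2 <- incidence_from_sets(list(u1 = c(1, 2, 3, 4), u2 = c(1, 2, 3, 5),
                                   u3 = c(1, 2), u4 = c(1, 2)))
  ch <- extrapolate_total_richness(inc2, "chao2")
  expect_equal(c(ch$S_obs, ch$q1, ch$q2), c(5, 2, 1))
  expect_equal(ch$S_hat, 7)

  # jackknife1: S_obs + q1 (n-1)/n
  j <- extrapolate_total_richness(inc2, "jackknife1")
  expect_equal(j$S_hat, 5 + 2 * 3 / 4)

  # nothing unseen: all estimators collapse to S_obs
  full <- incidence_from_sets(list(u1 = 1:6, u2 = 1:6, u3 = 1:6))
  for (est in c("bootstrap", "chao2", "jackknife1")) {
    expect_equal(extrapolate_total_richness(full, est)$S_hat, 6)
  }

  # consistency: S_obs <= S_hat on random incidence matrices
  for (s in 1:10) {
    sets <- withr::with_seed(s, lapply(1:5, function(i)
      sample.int(12, sample(3:8, 1))))
    inc_r <- incidence_from_sets(sets)
    for (est in c("bootstrap", "chao2", "jackknife1")) {
      res <- extrapolate_total_richness(inc_r, est)
      expect_gte(res$S_hat, res$S_obs)
    }
  }
})

test_that("estimators agree with the independent vegan implementation", {
  skip_if_not_installed("vegan")
  for (s in 1:5) {
    sets <- withr::with_seed(100 + s, lapply(1:6, function(i)
      sample.int(15, sample(4:10, 1))))
    inc <- incidence_from_sets(sets)
    sp <- vegan::specpool(as.data.frame(inc$presence * 1))
    expect_equal(extrapolate_total_richness(inc, "bootstrap")$S_hat,
                 sp$boot, tolerance = 1e-9)
    expect_equal(extrapolate_total_richness(inc, "jackknife1")$S_hat,
                 sp$jack1, tolerance = 1e-9)
  }
})

test_that("exact accumulation equals the average over all orderings", {
  # two units {A,B}, {B,C}: E[S_1] = 2, E[S_2] = 3
  inc <- incidence_from_sets(list(u1 = c(1, 2), u2 = c(2, 3)))
  cv <- accumulation_curve(inc, method = "exact")
  expect_equal(cv$mean, c(2, 3))

  # n <= 6 random fixtures against full n! enumeration
  for (s in 1:8) {
    n <- withr::with_seed(s, sample(3:6, 1))
    sets <- withr::with_seed(s * 13, lapply(seq_len(n), function(i)
      sample.int(10, sample(2:6, 1))))
    inc_r <- incidence_from_sets(sets)
    cv_r <- accumulation_curve(inc_r, method = "exact")
    expect_equal(cv_r$mean, enum_accumulation(inc_r$presence),
                 tolerance = 1e-9)
  }
})

test_that("random accumulation agrees with the exact mean within 3 SE", {
  sets <- withr::with_seed(42, lapply(1:4, function(i)
    sample.int(12, sample(4:9, 1))))
  inc <- incidence_from_sets(sets)
  exact <- accumulation_curve(inc, method = "exact")
  rand <- accumulation_curve(inc, method = "random", n_resamples = 999,
                             seed = 7)
  se <- rand$sd / sqrt(999)
  dev <- abs(rand$mean - exact$mean)
  expect_true(all(dev <= pmax(3 * se, 1e-9)))
  # identical orderings all end at the union
  expect_equal(rand$sd[4], 0)
  expect_equal(rand$mean[4], exact$mean[4])
})

test_that("flat communities accumulate nothing and curves stay below the observed cap", {
  inc <- incidence_from_sets(list(u1 = 1:4, u2 = 1:4, u3 = 1:4))
  cv <- accumulation_curve(inc, method = "random", n_resamples = 99, seed = 1)
  expect_equal(cv$mean, rep(4, 3))
  expect_equal(cv$sd, rep(0, 3))
  # normalised curve never exceeds 100 * S_obs / S_hat
  for (s in 1:5) {
    sets <- withr::with_seed(s, lapply(1:5, function(i)
      sample.int(10, sample(2:7, 1))))
    inc_r <- incidence_from_sets(sets)
    cv_r <- accumulation_curve(inc_r, method = "exact")
    cap <- 100 * attr(cv_r, "S_obs") / attr(cv_r, "S_hat")
    expect_true(all(cv_r$pct <= cap + 1e-9))
    expect_true(all(diff(cv_r$mean) >= -1e-9))
  }
})

test_that("threshold search returns the smallest sufficient unit count", {
  # 5 disjoint units of 2 alleles each, external total 10: mean = 2k,
  # pct = 20k -> 70% first reached at k = 4
  inc <- incidence_from_sets(list(u1 = 1:2, u2 = 3:4, u3 = 5:6,
                                  u4 = 7:8, u5 = 9:10))
  cv <- accumulation_curve(inc, method = "exact", total = 10)
  thr <- units_to_threshold(cv, targets = c(70, 90))
  expect_equal(thr$k, c(4, 5))
  expect_equal(thr$source, c("observed", "observed"))

  # 100% target with S_hat > S_obs cannot be reached from data
  cv2 <- accumulation_curve(inc, method = "exact", total = 12)
  thr2 <- units_to_threshold(cv2, targets = 100, extrapolate = FALSE)
  expect_equal(thr2$source, "not_reached")
  expect_true(is.na(thr2$k))

  # monotonicity of thresholds in the target
  thr3 <- units_to_threshold(cv, targets = c(10, 40, 75, 95))
  expect_true(all(diff(thr3$k) >= 0))
  expect_error(units_to_threshold(cv, targets = 120), "targets")

  # saturating-fit extrapolation is flagged
  sets <- lapply(1:5, function(i) unique(c(1:6, 6 + i)))
  cv4 <- accumulation_curve(incidence_from_sets(sets), method = "exact",
                            total = 20)
  thr4 <- units_to_threshold(cv4, targets = 90)
  expect_true(thr4$source %in% c("extrapolated", "not_reached"))
  if (thr4$source == "extrapolated") expect_gt(thr4$k, 5)
})

test_that("allele membership tables match hand enumeration", {
  gt <- gt_tiny()
  m <- allele_membership(gt, by = "role")
  pw <- attr(m, "pairwise")
  # population alleles: L1 {101,103,105}, L2 {200,202}
  # seed alleles: L1 {101,103}, L2 {200,202}
  expect_equal(pw$shared, 4)
  expect_equal(pw$only_a + pw$only_b, 1)
  expect_equal(attr(m, "shared_by_all"), 4)

  # nested group has zero unique alleles
  sets <- list(inner = filter(gt, sample_id == "s1"),
               outer = gt)
  m2 <- allele_membership(sets)
  pw2 <- attr(m2, "pairwise")
  expect_equal(pw2$only_a, 0)
  expect_error(allele_membership(list(a = gt)), "two")
})
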