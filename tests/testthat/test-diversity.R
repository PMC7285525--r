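test_that("alpha diversity matches hand-computed values", {
  rel <- rbind(uniform = rep(0.25, 4), single = c(1, 0, 0, 0))
  a <- alpha_diversity(rel)
  expect_equal(a$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(a$pielou_simpson[1], 1, tolerance = 1e-12)
  expect_equal(a$pielou_shannon[1], 1, tolerance = 1e-12)
  expect_equal(a$richness[2], 1)
  expect_equal(a$shannon[2], 0)
  expect_true(is.na(a$pielou_shannon[2])) # undefined for one taxon
  # default evenness column is the Simpson-based variant
  expect_identical(a$pielou, a$pielou_simpson)
})

test_that("Shannon agrees with vegan on random compositions", {
  set.seed(12)
  rel <- t(apply(matrix(rgamma(50, 1), 10, 5), 1, function(x) x / sum(x)))
  colnames(rel) <- paste0("t", 1:5)
  a <- alpha_diversity(rel)
  expect_equal(a$shannon, unname(vegan::diversity(rel, "shannon")),
               tolerance = 1e-12)
  expect_equal(1 / (a$pielou_simpson * a$richness),
               unname(rowSums(rel^2)), tolerance = 1e-12)
})

test_that("Bray-Curtis matches its defining formula and axioms", {
  set.seed(13)
  rel <- t(apply(matrix(rgamma(60, 1), 10, 6), 1, function(x) x / sum(x)))
  d <- bray_curtis(rel)
  # direct formula on a few pairs
  for (p in list(c(1, 2), c(3, 7), c(9, 10))) {
    want <- sum(abs(rel[p[1], ] - rel[p[2], ])) /
      sum(rel[p[1], ] + rel[p[2], ])
    expect_equal(d[p[1], p[2]], want, tolerance = 1e-12)
  }
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 10))
  expect_true(all(d >= 0 & d <= 1))
  same <- rbind(rel[1, ], rel[1, ])
  expect_equal(bray_curtis(same)[1, 2], 0)
  disjoint <- rbind(c(1, 0, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0))
  expect_equal(bray_curtis(disjoint)[1, 2], 1)
})

test_that("ANOSIM: extreme separation gives R = 1 and p at its floor", {
  set.seed(14)
  g1 <- matrix(runif(30, 0, 0.1), 5)
  g2 <- matrix(runif(30, 0.9, 1), 5)
  rel <- rbind(g1, g2)
  rel <- rel / rowSums(rel)
  d <- bray_curtis(rbind(g1, g2))
  lab <- rep(c("a", "b"), each = 5)
  r <- anosim(d, lab, n_perm = 99, seed = 7)
  expect_equal(r$statistic, 1, tolerance = 1e-9)
  expect_gte(r$p.value, 1 / (1 + 99))
  # invariance to relabeling group names
  r2 <- anosim(d, rep(c("ctrl", "case"), each = 5), n_perm = 99, seed = 7)
  expect_equal(r2$statistic, r$statistic)
  expect_error(anosim(d, rep("a", 10)), "two groups")
})

test_that("permutation p-values are reproducible and bounded", {
  set.seed(15)
  rel <- matrix(runif(80), 16, 5)
  d <- bray_curtis(rel / rowSums(rel))
  lab <- rep(c("x", "y"), 8)
  a1 <- anosim(d, lab, n_perm = 199, seed = 3)
  a2 <- anosim(d, lab, n_perm = 199, seed = 3)
  expect_identical(a1$p.value, a2$p.value)
  expect_gte(a1$p.value, 1 / 200)
  expect_lte(a1$p.value, 1)
  p1 <- permanova(d, lab, n_perm = 199, seed = 3)
  p2 <- permanova(d, lab, n_perm = 199, seed = 3)
  expect_identical(p1$p.value, p2$p.value)
  expect_identical(p1$statistic,
                   permanova(d, rep(c("u", "v"), 8), n_perm = 199,
                             seed = 3)$statistic)
})

test_that("PERMANOVA detects clean group separation", {
  set.seed(16)
  g1 <- matrix(rep(c(0.8, 0.2, 0, 0), each = 8), 8) + runif(32, 0, 0.01)
  g2 <- matrix(rep(c(0, 0, 0.3, 0.7), each = 8), 8) + runif(32, 0, 0.01)
  d <- bray_curtis(rbind(g1, g2))
  r <- permanova(d, rep(c("a", "b"), each = 8), n_perm = 99, seed = 1)
  expect_lte(r$p.value, 0.02)
})
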