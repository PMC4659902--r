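test_that("Bray-Curtis matches the direct formula and its bounds", {
  tab <- otu_table(matrix(c(6L, 2L, 2L, 2L), 2,
                          dimnames = list(c("a", "b"), c("x", "y"))))
  d <- bray_curtis(tab)
  expect_equal(d["x", "y"], 4 / 12)
  expect_equal(diag(d), c(x = 0, y = 0))
  disj <- otu_table(matrix(c(1L, 0L, 0L, 1L), 2,
                           dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(bray_curtis(disj)["x", "y"], 1)
  same <- otu_table(matrix(c(3L, 1L, 3L, 1L), 2,
                           dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(bray_curtis(same)["x", "y"], 0)
  zero <- otu_table(matrix(c(1L, 0L, 0L, 0L), 2,
                           dimnames = list(c("a", "b"), c("x", "y"))))
  expect_error(bray_curtis(zero), "all-zero sample")
  b <- small_bundle()
  d2 <- bray_curtis(rarefy(b$table, 1000, seed = 1))
  expect_true(isSymmetric(unname(d2)))
  expect_true(all(d2 >= 0 & d2 <= 1))
})

test_that("weighted-normalized UniFrac matches branch-sum oracles", {
  # two samples on disjoint tips of a 2-tip star: complete separation
  tr <- ape::read.tree(text = "(A:1,B:1):0;")
  tab <- otu_table(matrix(c(10L, 0L, 0L, 5L), 2,
                          dimnames = list(c("A", "B"), c("x", "y"))))
  expect_equal(weighted_normalized_unifrac(tab, tr)["x", "y"], 1)
  # identical relative abundances: zero
  tab0 <- otu_table(matrix(c(10L, 20L, 1L, 2L), 2,
                           dimnames = list(c("A", "B"), c("x", "y"))))
  expect_equal(weighted_normalized_unifrac(tab0, tr)["x", "y"], 0)
  # caterpillar ((A:1,B:1):1,C:2), x all on A, y all on C: hand-summed 1.0
  tr3 <- caterpillar_tree()
  tab3 <- otu_table(matrix(c(7L, 0L, 0L, 0L, 0L, 3L), 3,
                           dimnames = list(c("A", "B", "C"), c("x", "y"))))
  expect_equal(weighted_normalized_unifrac(tab3, tr3)["x", "y"], 1)
  # partial overlap case checked against phyloseq
  b <- small_bundle()
  rar <- rarefy(b$table, 1000, seed = 2)
  mine <- weighted_normalized_unifrac(rar, b$tree)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(unclass(rar), taxa_are_rows = TRUE),
    phyloseq::phy_tree(b$tree))
  ref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  expect_equal(unname(mine), unname(ref[rownames(mine), colnames(mine)]),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(mine >= 0 & mine <= 1))
  # missing tip is a join error naming the OTU
  tab_bad <- otu_table(matrix(c(1L, 1L), 2, 1,
                              dimnames = list(c("A", "Zmissing"), "x")))
  expect_error(weighted_normalized_unifrac(
    otu_table(matrix(c(1L, 1L, 1L, 2L), 2,
                     dimnames = list(c("A", "Zmissing"), c("x", "y")))), tr),
    "Zmissing")
})

test_that("ANOSIM gives R = 1 under perfect separation and matches vegan", {
  # construct distances where all between-group exceed all within-group
  m <- matrix(0.9, 6, 6)
  m[1:3, 1:3] <- 0.1
  m[4:6, 4:6] <- 0.1
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- setNames(rep(c("a", "b"), each = 3), rownames(m))
  res <- anosim(m, g, n_permutations = 999, seed = 1)
  expect_equal(res$statistic, 1)
  expect_lt(res$p_value, 0.2)
  # statistic agrees with vegan on real community distances
  b <- small_bundle()
  rar <- rarefy(b$table, 1000, seed = 3)
  d <- bray_curtis(rar)
  reach <- setNames(as.character(b$frames$reach), b$frames$sample_id)
  keep <- colnames(rar)[reach[colnames(rar)] != "reservoir"]
  mine <- anosim(d[keep, keep], reach[keep], n_permutations = 999, seed = 5)
  ref <- vegan::anosim(stats::as.dist(d[keep, keep]), factor(reach[keep]),
                       permutations = 999)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_gte(mine$p_value, 1 / 1000)
  expect_error(anosim(m, setNames(c("a", rep("b", 5)), rownames(m)), 99, 1),
               "singleton")
})

test_that("ANOSIM permutation p is close to exhaustive enumeration", {
  set.seed(4)
  m <- as.matrix(stats::dist(matrix(rnorm(12), 6, 2)))
  dimnames(m) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- setNames(rep(c("a", "b"), each = 3), rownames(m))
  # brute-force oracle: every one of the 6! label orderings
  lt <- which(lower.tri(m))
  pi_ <- row(m)[lt]; pj <- col(m)[lt]
  r <- rank(m[lt]); M <- length(r)
  stat_for <- function(lab) {
    within <- lab[pi_] == lab[pj]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  perms <- combinat_perms(6)
  all_R <- apply(perms, 1, function(ix) stat_for(unname(g)[ix]))
  obs <- stat_for(unname(g))
  p_exact <- mean(all_R >= obs - 1e-12)
  res <- anosim(m, g, n_permutations = 9999, seed = 2)
  expect_equal(res$statistic, obs)
  expect_lt(abs(res$p_value - p_exact), 0.02)
})

test_that("ANOSIM R is near zero for random labels and rank-invariant", {
  set.seed(9)
  m <- as.matrix(stats::dist(matrix(rnorm(20), 10, 2)))
  dimnames(m) <- list(paste0("s", 1:10), paste0("s", 1:10))
  # rank invariance: squaring distances preserves R exactly
  g <- setNames(rep(c("a", "b"), each = 5), rownames(m))
  expect_equal(anosim(m, g, 99, 1)$statistic,
               anosim(m^2, g, 99, 1)$statistic)
  # permutation-null expectation of R is zero
  stats <- sapply(1:200, function(s) {
    set.seed(s + 1000)
    gl <- setNames(sample(rep(c("a", "b"), each = 5)), rownames(m))
    anosim(m, gl, n_permutations = 1, seed = 1)$statistic
  })
  expect_lt(abs(mean(stats)), 3 * stats::sd(stats) / sqrt(length(stats)))
})
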