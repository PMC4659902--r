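test_that("rarefaction hits exact depth, drops shallow samples, is seeded", {
  b <- small_bundle()
  rar <- rarefy(b$table, 500, seed = 7)
  expect_true(all(colSums(rar) == 500))
  expect_identical(attr(rar, "dropped_samples"), character(0))
  # rarefying at a sample's own total is the identity on that sample
  tot <- colSums(b$table)[1]
  one <- b$table[, 1]
  rar1 <- rarefy(one, tot, seed = 1)
  expect_equal(unclass(rar1), unclass(one), ignore_attr = "dropped_samples")
  # shallow samples are dropped and reported
  shallow <- otu_table(matrix(c(999L, 0L, 600L, 400L), nrow = 2,
                              dimnames = list(c("a", "b"), c("s1", "s2"))))
  rar2 <- rarefy(shallow, 1000, seed = 1)
  expect_identical(colnames(rar2), "s2")
  expect_identical(attr(rar2, "dropped_samples"), "s1")
  expect_error(rarefy(shallow, 5000, seed = 1), "all samples dropped")
  expect_error(rarefy(shallow, 0, seed = 1), "positive integer")
  # determinism
  expect_identical(unclass(rarefy(b$table, 500, seed = 3)),
                   unclass(rarefy(b$table, 500, seed = 3)))
})

test_that("rarefaction matches the hypergeometric expectation", {
  x <- otu_table(matrix(c(50L, 30L, 20L), 3, 1,
                        dimnames = list(c("a", "b", "c"), "s")))
  draws <- sapply(1:1000, function(s) unclass(rarefy(x, 10, seed = s))[, 1])
  expected <- 10 * c(50, 30, 20) / 100
  se <- sqrt(apply(draws, 1, var) / 1000)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * se + 1e-9))
})

test_that("Shannon index matches closed forms and is permutation-invariant", {
  expect_equal(shannon(c(5, 5, 5, 5)), log(4))
  expect_equal(shannon(7), 0)
  expect_equal(shannon(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(shannon(c(2, 1, 1)), 1.0397, tolerance = 1e-4)
  expect_equal(shannon(c(1, 2, 3, 9)), shannon(c(9, 3, 2, 1)))
  expect_equal(shannon(c(4, 4), base = "2"), 1)
  expect_error(shannon(c(0, 0)), "all-zero")
  # agreement with vegan across random vectors
  set.seed(1)
  for (i in 1:5) {
    v <- rpois(20, 5)
    v[1] <- v[1] + 1
    expect_equal(shannon(v), unname(vegan::diversity(v)))
  }
})

test_that("MPD matches hand-computed patristic means and picante", {
  expect_equal(mpd(paste0("OTU", 1:3), star_tree(3)), 2)
  expect_equal(mpd(paste0("OTU", 1:5), star_tree(5)), 2)
  tr2 <- ape::read.tree(text = "(A:1.5,B:2):0;")
  expect_equal(mpd(c("A", "B"), tr2), 3.5)
  expect_equal(mpd(c("A", "B", "C"), caterpillar_tree()), 10 / 3)
  expect_true(is.na(mpd("A", caterpillar_tree())))
  expect_error(mpd(c("A", "Z"), caterpillar_tree()), "Z")
  # unweighted mode is abundance-invariant; equal weights equal unweighted
  b <- small_bundle()
  taxa <- rownames(b$table)[1:10]
  expect_equal(mpd(taxa, b$tree),
               mpd(taxa, b$tree, weighted = TRUE, abundances = rep(3, 10)))
  # picante agreement (presence-based)
  comm <- matrix(1, 1, 10, dimnames = list("c", taxa))
  expect_equal(mpd(taxa, b$tree),
               unname(picante::mpd(comm,
                                   ape::cophenetic.phylo(b$tree)[taxa, taxa])))
  # weighted mode against explicit pair enumeration
  ab <- c(5, 1, 2)
  d <- ape::cophenetic.phylo(caterpillar_tree())[c("A", "B", "C"),
                                                 c("A", "B", "C")]
  w <- ab / sum(ab)
  num <- w[1] * w[2] * d[1, 2] + w[1] * w[3] * d[1, 3] + w[2] * w[3] * d[2, 3]
  den <- w[1] * w[2] + w[1] * w[3] + w[2] * w[3]
  expect_equal(mpd(c("A", "B", "C"), caterpillar_tree(), weighted = TRUE,
                   abundances = ab), num / den)
})

test_that("collector curve is monotone and exhausts observed richness", {
  b <- small_bundle()
  cc <- collector_curve(b$table, grain = 500, reps = 5, seed = 2)
  expect_true(all(diff(cc$mean_otus) >= 0))
  expect_equal(cc$mean_otus[nrow(cc)], sum(rowSums(b$table) > 0))
  # single-OTU table: constant at 1 from the first grain onwards
  one <- otu_table(matrix(c(40L, 60L), 1, 2,
                          dimnames = list("a", c("s1", "s2"))))
  cc1 <- collector_curve(one, grain = 10, reps = 3, seed = 1)
  expect_true(all(cc1$mean_otus == 1))
})

test_that("reach contrasts report signed ratios and ANOVA p-values", {
  frames <- frames_for(up = c("u1", "u2"), dw = c("d1", "d2"))
  rec <- data.frame(sample_id = c("u1", "u2", "d1", "d2"),
                    scope = "all", n_sequences = 100,
                    richness = c(5, 3, 1, 3), shannon = c(4, 4, 2, 2),
                    mpd = NA_real_)
  rc <- reach_contrast(rec, frames, "shannon")
  expect_equal(rc$signed_ratio, 2)
  expect_equal(rc$mean_upstream, 4)
  # mirrored direction gives the negative fold change
  rec2 <- rec
  rec2$shannon <- c(2, 2, 4, 4)
  expect_equal(reach_contrast(rec2, frames, "shannon")$signed_ratio, -2)
  # identical groups: F = 0 boundary, p = 1, ratio +1
  rec3 <- rec
  rec3$shannon <- c(3, 3, 3, 3)
  rc3 <- reach_contrast(rec3, frames, "shannon")
  expect_equal(rc3$signed_ratio, 1)
  expect_equal(rc3$anova_p, 1)
  # generic case agrees with stats::anova on the two-group design
  rc4 <- reach_contrast(rec, frames, "richness")
  fit <- stats::anova(stats::lm(c(5, 3, 1, 3) ~ factor(c(1, 1, 2, 2))))
  expect_equal(rc4$anova_p, fit[["Pr(>F)"]][1])
  expect_error(reach_contrast(rec[1:3, ], frames, "shannon"),
               "at least two")
})

test_that("alpha records respect their internal bounds", {
  b <- small_bundle()
  rar <- rarefy(b$table, 1000, seed = 1)
  alpha <- alpha_diversity(rar, tree = b$tree)
  expect_true(all(alpha$richness <= alpha$n_sequences))
  expect_true(all(alpha$shannon >= 0))
  expect_true(all(alpha$shannon <= log(alpha$richness) + 1e-12))
  expect_true(all(is.na(alpha$mpd) | alpha$mpd > 0))
})
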