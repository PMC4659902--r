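simple_tax <- function(ids, class = "K") {
  data.frame(otu_id = ids, domain = "Bacteria", phylum = "P", class = class,
             order = paste0(class, "_o1"), family = NA_character_,
             genus = NA_character_, stringsAsFactors = FALSE)
}

test_that("class abundance is the per-sample sum over member OTUs", {
  counts <- rbind(a = c(1L, 2L, 3L), b = c(0L, 1L, 0L), c = c(9L, 9L, 9L))
  colnames(counts) <- paste0("s", 1:3)
  tab <- otu_table(counts)
  tax <- rbind(simple_tax(c("a", "b"), "K1"), simple_tax("c", "K2"))
  expect_equal(class_abundance(tab, tax, focal = "K1"),
               c(s1 = 1, s2 = 3, s3 = 3))
  expect_equal(class_abundance(tab, tax, focal = "K2"), c(s1 = 9, s2 = 9, s3 = 9))
  # conservation: class sums partition the column totals
  expect_equal(class_abundance(tab, tax, focal = "K1") +
                 class_abundance(tab, tax, focal = "K2"),
               colSums(tab))
  expect_error(class_abundance(tab, tax, focal = "Nope"), "no OTU")
})

test_that("dominant flagging is strict and scale-free", {
  # grand total 10000: 11 counts (0.11%) dominant, 10 (0.10%) not
  counts <- matrix(c(11L, 10L, 9979L), 3, 1,
                   dimnames = list(c("just_over", "at", "rest"), "s"))
  tab <- otu_table(counts)
  expect_identical(sort(flag_dominant_otus(tab)), c("just_over", "rest"))
  doubled <- otu_table(counts * 2L)
  expect_identical(flag_dominant_otus(doubled), flag_dominant_otus(tab))
})

test_that("partition verdicts follow sign, Bonferroni and alpha", {
  set.seed(2)
  n <- 32
  # two OTUs tracking a strong shared signal plus a constant OTU
  sig <- round(exp(rnorm(n, 3, 1)))
  a <- as.integer(sig + rpois(n, 2))
  b <- as.integer(sig + rpois(n, 2))
  flat <- rep(5L, n)
  counts <- rbind(a = a, b = b, flat = flat)
  colnames(counts) <- paste0("s", seq_len(n))
  tab <- otu_table(counts)
  tax <- simple_tax(rownames(counts))
  part <- partition_class(tab, tax, "K")
  v <- setNames(as.character(part$records$verdict), part$records$otu_id)
  expect_identical(v[["a"]], "positive")
  expect_identical(v[["b"]], "positive")
  expect_identical(v[["flat"]], "untestable")
  expect_equal(part$family_size, 2)
  # p_adjusted = min(1, p_raw * family)
  rec <- part$records[part$records$verdict != "untestable", ]
  expect_equal(rec$p_adjusted, pmin(1, rec$p_raw * 2))
  # raw p matches cor.test's two-sided t transform
  ct <- stats::cor.test(a, colSums(counts))
  expect_equal(rec$p_raw[rec$otu_id == "a"], ct$p.value)
  expect_equal(rec$pearson_r[rec$otu_id == "a"], unname(ct$estimate))
})

test_that("an exact-mirror OTU is negative under leave-one-out", {
  set.seed(3)
  n <- 32
  sig <- round(exp(rnorm(n, 3, 1)))
  a <- as.integer(sig + rpois(n, 2))
  b <- as.integer(sig + rpois(n, 2))
  # class total is constant: the mirror cancels the other members exactly
  mirror <- as.integer(max(a + b) + 10 - (a + b))
  counts <- rbind(a = a, b = b, mirror = mirror)
  colnames(counts) <- paste0("s", seq_len(n))
  tab <- otu_table(counts)
  tax <- simple_tax(rownames(counts))
  # with the focal OTU included, the constant class sum is a loud error
  expect_error(partition_class(tab, tax, "K"), "zero variance")
  part <- partition_class(tab, tax, "K", self_inclusion = FALSE)
  v <- setNames(as.character(part$records$verdict), part$records$otu_id)
  expect_identical(v[["mirror"]], "negative")
  expect_equal(part$records$pearson_r[part$records$otu_id == "mirror"], -1)
})

test_that("single-OTU class self-correlates positively; errors are loud", {
  counts <- matrix(c(1L, 5L, 2L, 9L), 1, dimnames = list("a", paste0("s", 1:4)))
  tab <- otu_table(counts)
  part <- partition_class(tab, simple_tax("a"), "K")
  expect_identical(as.character(part$records$verdict), "positive")
  expect_equal(part$records$pearson_r, 1)
  expect_error(partition_class(tab[, 1:3], simple_tax("a"), "K"),
               "at least 4")
  flat <- otu_table(matrix(3L, 1, 4, dimnames = list("a", paste0("s", 1:4))))
  expect_error(partition_class(flat, simple_tax("a"), "K"), "zero variance")
})

test_that("partition is exhaustive and Bonferroni is monotone in family", {
  b <- simulate_dataset(recovery_config(0.5), seed = 5)
  part_w <- partition_class(b$table, b$taxonomy, "Betaproteobacteria")
  expect_true(all(!is.na(part_w$records$verdict)))
  expect_equal(nrow(part_w$records),
               sum(b$taxonomy$class == "Betaproteobacteria"))
  part_g <- partition_class(b$table, b$taxonomy, "Betaproteobacteria",
                            family = "global", family_size = 1000)
  w <- as.character(part_w$records$verdict)
  g <- as.character(part_g$records$verdict)
  # enlarging the family can only demote significant verdicts
  expect_true(all(g[w == "nonsignificant"] == "nonsignificant"))
  expect_true(all(g %in% c(w, "nonsignificant")))
  expect_true(all(w[g == "positive"] == "positive"))
})

test_that("positive_fraction reproduces worked-example arithmetic", {
  fx <- partition_from_counts("Gammaproteobacteria", 2, 43, 48, 473)
  pf <- positive_fraction(fx$partition, fx$table)
  expect_equal(round(pf$otu_percent), 4)
  expect_equal(round(pf$sequence_percent), 9)
  # all-positive partition gives (100, 100)
  allpos <- partition_from_counts("K", 3, 0, 30, 0)
  pf2 <- positive_fraction(allpos$partition, allpos$table)
  expect_equal(pf2$otu_percent, 100)
  expect_equal(pf2$sequence_percent, 100)
})

test_that("subgroup summaries capture diversity contrasts and dominants", {
  b <- simulate_dataset(recovery_config(0.25), seed = 3)
  part <- partition_class(b$table, b$taxonomy, "Betaproteobacteria")
  dom <- flag_dominant_otus(b$table)
  sm <- subgroup_summary(part, b$table, b$tree, dom)
  expect_identical(sm$group, c("positive", "noncorrelated"))
  # percent-dominant of the two groups sums to 100 when dominants exist
  if (!anyNA(sm$pct_dominant)) expect_equal(sum(sm$pct_dominant), 100)
  expect_true(all(sm$n_otus > 0))
  expect_true(all(is.finite(sm$shannon)))
  # one-OTU subgroup: Shannon 0, MPD missing
  fx <- partition_from_counts("K", 1, 2, 10, 20)
  sm1 <- subgroup_summary(fx$partition, fx$table, tree = NULL,
                          dominant_set = character())
  expect_equal(sm1$shannon[sm1$group == "positive"], 0)
  expect_true(is.na(sm1$mpd[sm1$group == "positive"]))
})

test_that("subgroup taxonomy rows are percentages summing to 100", {
  b <- simulate_dataset(recovery_config(0.5), seed = 7)
  part <- partition_class(b$table, b$taxonomy, "Betaproteobacteria")
  comp <- subgroup_taxonomy(part, b$table, b$taxonomy)
  sums <- tapply(comp$percent, comp$group, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # single-order group collapses to one 100% row
  fx <- partition_from_counts("K", 2, 0, 10, 0)
  tax <- simple_tax(fx$partition$records$otu_id)
  one <- subgroup_taxonomy(fx$partition, fx$table, tax)
  expect_equal(nrow(one), 1)
  expect_equal(one$percent, 100)
  # empty group yields no rows, not an error
  emptyfx <- partition_from_counts("K", 0, 2, 0, 20)
  comp2 <- subgroup_taxonomy(emptyfx$partition, emptyfx$table,
                             simple_tax(emptyfx$partition$records$otu_id))
  expect_true(all(comp2$group != "positive"))
})

test_that("planted anti-responders can cancel the class-level signal", {
  # with anti-responder mass rivalling the coherent mass, the class
  # abundance vector flattens and coherent OTUs lose their correlation
  hits <- sapply(1:8, function(s) {
    b <- simulate_dataset(recovery_config(0.4, anti = 0.4), seed = 100 + s)
    part <- partition_class(b$table, b$taxonomy, "Betaproteobacteria")
    rec <- merge(part$records, b$truth, by = "otu_id")
    mean(rec$verdict[rec$label == "coherent_with_class"] == "positive")
  })
  full <- sapply(1:8, function(s) {
    b <- simulate_dataset(recovery_config(0.4, anti = 0), seed = 100 + s)
    part <- partition_class(b$table, b$taxonomy, "Betaproteobacteria")
    rec <- merge(part$records, b$truth, by = "otu_id")
    mean(rec$verdict[rec$label == "coherent_with_class"] == "positive")
  })
  expect_lt(median(hits), median(full))
})

test_that("score_recovery matches its closed-form cases", {
  fx <- partition_from_counts("K", 2, 2, 20, 20)
  truth <- data.frame(otu_id = fx$partition$records$otu_id, class = "K",
                      label = c("coherent_with_class", "coherent_with_class",
                                "null_responder", "null_responder"),
                      stringsAsFactors = FALSE)
  sc <- score_recovery(fx$partition, truth)
  expect_equal(unname(sc), c(1, 1, 0))
  # all-nonsignificant partition with planted f = 0.5
  fx0 <- partition_from_counts("K", 0, 4, 0, 40)
  truth0 <- truth
  truth0$otu_id <- fx0$partition$records$otu_id
  sc0 <- score_recovery(fx0$partition, truth0)
  expect_equal(unname(sc0[c("sensitivity", "fraction_error")]), c(0, 0.5))
})
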