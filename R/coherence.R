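#' Per-sample abundance of a taxon at a given rank
#'
#' Sums counts over all OTUs assigned to the focal label (e.g., a class),
#' preserving sample order.
#'
#' @param table An [otu_table].
#' @param taxonomy Taxonomy data frame (see [read_taxonomy]).
#' @param rank Rank column to match (default `"class"`).
#' @param focal Label at that rank.
#' @return Named numeric vector, one entry per sample.
#' @export
class_abundance <- function(table, taxonomy, rank = "class", focal) {
  stopifnot(inherits(table, "otu_table"))
  if (!rank %in% names(taxonomy)) stop("unknown rank: ", rank, call. = FALSE)
  otus <- taxonomy$otu_id[!is.na(taxonomy[[rank]]) & taxonomy[[rank]] == focal]
  if (length(otus) == 0)
    stop("no OTU carries label '", focal, "' at rank ", rank, call. = FALSE)
  check_ids(otus, rownames(table), "OTU table")
  colSums(unclass(table)[otus, , drop = FALSE])
}

#' Flag dominant OTUs
#'
#' An OTU is "dominant" when its pooled count across all samples strictly
#' exceeds `threshold_fraction` of the grand total (default 0.1% of the
#' pooled sequences); below or at the threshold it is "moderately
#' abundant". Meant for the non-rarefied table.
#'
#' @param table An [otu_table].
#' @param threshold_fraction Strict fraction threshold (default 0.001).
#' @return Character vector of dominant OTU ids.
#' @export
flag_dominant_otus <- function(table, threshold_fraction = 0.001) {
  stopifnot(inherits(table, "otu_table"))
  pooled <- rowSums(table)
  rownames(table)[pooled > threshold_fraction * sum(pooled)]
}

#' Partition a class's OTUs by correlation with class abundance
#'
#' The core coherence statistic: for every OTU in the focal class, the
#' two-sided Pearson correlation between the OTU's per-sample counts and
#' the per-sample summed abundance of its parent class (all campaigns
#' pooled, non-rarefied counts). P-values use the t transform with n - 2
#' degrees of freedom and are Bonferroni-adjusted; each OTU receives one
#' verdict: `positive` (r > 0, adjusted p < alpha), `negative` (r < 0,
#' adjusted p < alpha), `nonsignificant`, or `untestable` (zero-variance
#' count vector).
#'
#' @param table An [otu_table] with at least 4 samples.
#' @param taxonomy Taxonomy data frame.
#' @param class_label Focal class.
#' @param alpha Significance level after adjustment (default 0.05).
#' @param family `"within_class"` (default): Bonferroni family = number of
#'   testable OTUs in the focal class; `"global"`: a caller-supplied
#'   `family_size` (e.g., testable OTUs across all classes).
#' @param family_size Required when `family = "global"`.
#' @param self_inclusion Keep the focal OTU inside the class sum it is
#'   correlated against (default TRUE; the class abundance is simply the
#'   sum of all its members). With FALSE, each OTU is correlated against
#'   the class sum minus itself, removing the self-correlation term that
#'   inflates positives in tiny classes.
#' @return An object of class `coherence_partition`: list with `class`,
#'   `records` (data frame otu_id, pearson_r, p_raw, p_adjusted, verdict),
#'   `family_size`, `alpha`, `n_samples`, `self_inclusion`.
#' @export
partition_class <- function(table, taxonomy, class_label, alpha = 0.05,
                            family = c("within_class", "global"),
                            family_size = NULL, self_inclusion = TRUE) {
  family <- match.arg(family)
  stopifnot(inherits(table, "otu_table"))
  n <- ncol(table)
  if (n < 4)
    stop("need at least 4 samples to test correlations", call. = FALSE)
  otus <- taxonomy$otu_id[!is.na(taxonomy$class) &
                            taxonomy$class == class_label]
  if (length(otus) == 0)
    stop("class '", class_label, "' has no OTUs", call. = FALSE)
  check_ids(otus, rownames(table), "OTU table")
  sub <- unclass(table)[otus, , drop = FALSE]
  classvec <- colSums(sub)
  # under leave-one-out the per-OTU reference vectors can still vary even
  # when the full class sum is constant, so only reject here when the
  # focal OTU is included in its class sum
  if (self_inclusion && stats::var(classvec) == 0)
    stop("class abundance vector for '", class_label,
         "' has zero variance; correlations are undefined", call. = FALSE)
  r <- p <- rep(NA_real_, length(otus))
  for (i in seq_along(otus)) {
    x <- sub[i, ]
    y <- if (self_inclusion) classvec else classvec - x
    if (stats::var(x) == 0 || stats::var(y) == 0) next
    ri <- stats::cor(x, y)
    r[i] <- ri
    p[i] <- if (abs(ri) >= 1) 0 else
      2 * stats::pt(-abs(ri) * sqrt((n - 2) / (1 - ri^2)), df = n - 2)
  }
  testable <- !is.na(r)
  fam <- switch(family,
    within_class = sum(testable),
    global = {
      if (is.null(family_size))
        stop("family = 'global' requires family_size", call. = FALSE)
      family_size
    })
  p_adj <- pmin(1, p * fam)
  verdict <- rep("untestable", length(otus))
  verdict[testable] <- ifelse(p_adj[testable] < alpha,
                              ifelse(r[testable] > 0, "positive", "negative"),
                              "nonsignificant")
  structure(list(
    class = class_label,
    records = data.frame(otu_id = otus, pearson_r = r, p_raw = p,
                         p_adjusted = p_adj,
                         verdict = factor(verdict,
                                          levels = c("positive", "negative",
                                                     "nonsignificant",
                                                     "untestable")),
                         stringsAsFactors = FALSE),
    family_size = fam, alpha = alpha, n_samples = n,
    self_inclusion = self_inclusion),
    class = "coherence_partition")
}

#' @export
print.coherence_partition <- function(x, ...) {
  tab <- table(x$records$verdict)
  cat("Coherence partition for class ", x$class, " (n = ", x$n_samples,
      " samples, alpha = ", x$alpha, ", family = ", x$family_size, "):\n",
      sep = "")
  print(tab)
  invisible(x)
}

#' Fraction of a class represented by its positively correlated OTUs
#'
#' The two headline fractions: the percent of testable OTUs whose verdict
#' is positive, and the percent of the class's pooled sequences carried by
#' those OTUs (sequence denominator = all partitioned OTUs of the class,
#' untestable included).
#'
#' @param partition A `coherence_partition`.
#' @param table The [otu_table] the partition was computed on.
#' @return List with `otu_percent` and `sequence_percent` (both on the
#'   0-100 scale, unrounded).
#' @export
positive_fraction <- function(partition, table) {
  rec <- partition$records
  if (nrow(rec) == 0) stop("empty partition", call. = FALSE)
  testable <- rec$verdict != "untestable"
  if (!any(testable))
    stop("no testable OTU in class ", partition$class, call. = FALSE)
  pos <- rec$verdict == "positive"
  pooled <- rowSums(unclass(table)[rec$otu_id, , drop = FALSE])
  list(otu_percent = 100 * sum(pos) / sum(testable),
       sequence_percent = 100 * sum(pooled[pos]) / sum(pooled))
}

#' Summaries of the positive and non-correlated subgroups of a class
#'
#' For each of the two subgroups — OTUs positively correlated with class
#' abundance, and OTUs not significantly correlated — reports the pooled
#' sequence count, OTU count, the share of the class's dominant OTUs the
#' subgroup contains, the Shannon index of the pooled per-OTU count
#' vector, and the presence-based MPD of the subgroup's OTU set.
#'
#' @param partition A `coherence_partition`.
#' @param table The [otu_table] the partition was computed on.
#' @param tree Rooted `phylo` covering the class's OTUs (optional; MPD is
#'   NA without it).
#' @param dominant_set Character vector from [flag_dominant_otus].
#' @param shannon_mode `"pooled"` (default): Shannon of the pooled count
#'   vector; `"per_sample_mean"`: mean of per-sample Shannon over samples
#'   where the subgroup has sequences.
#' @return Data frame with rows `positive` and `noncorrelated`.
#' @export
subgroup_summary <- function(partition, table, tree = NULL, dominant_set,
                             shannon_mode = c("pooled", "per_sample_mean")) {
  shannon_mode <- match.arg(shannon_mode)
  rec <- partition$records
  groups <- list(positive = rec$otu_id[rec$verdict == "positive"],
                 noncorrelated = rec$otu_id[rec$verdict == "nonsignificant"])
  dom_in_class <- intersect(dominant_set, unlist(groups))
  rows <- lapply(names(groups), function(gn) {
    ids <- groups[[gn]]
    sub <- unclass(table)[ids, , drop = FALSE]
    pooled <- rowSums(sub)
    sh <- if (length(ids) == 0 || sum(pooled) == 0) NA_real_
      else if (shannon_mode == "pooled") shannon(pooled)
      else {
        per <- apply(sub, 2, function(z) if (sum(z) > 0) shannon(z) else NA_real_)
        mean(per, na.rm = TRUE)
      }
    data.frame(
      group = gn,
      n_sequences = sum(pooled),
      n_otus = length(ids),
      pct_dominant = if (length(dom_in_class) == 0) NA_real_ else
        100 * length(intersect(ids, dom_in_class)) / length(dom_in_class),
      shannon = sh,
      mpd = if (is.null(tree) || length(ids) < 2) NA_real_ else mpd(ids, tree),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(class = partition$class, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Taxonomic composition of the coherence subgroups
#'
#' Percent of each subgroup's sequences contributed by each taxonomic
#' order (or another rank); OTUs unassigned at that rank are grouped as
#' `"unclassified"`. Percentages sum to 100 within each non-empty group.
#'
#' @param partition A `coherence_partition`.
#' @param table The [otu_table] the partition was computed on.
#' @param taxonomy Taxonomy data frame.
#' @param rank Rank for the composition (default `"order"`).
#' @return Data frame with columns `class`, `group`, `taxon`, `percent`;
#'   empty groups yield no rows.
#' @export
subgroup_taxonomy <- function(partition, table, taxonomy, rank = "order") {
  rec <- partition$records
  groups <- list(positive = rec$otu_id[rec$verdict == "positive"],
                 noncorrelated = rec$otu_id[rec$verdict == "nonsignificant"])
  out <- list()
  for (gn in names(groups)) {
    ids <- groups[[gn]]
    if (length(ids) == 0) next
    pooled <- rowSums(unclass(table)[ids, , drop = FALSE])
    if (sum(pooled) == 0) next
    tax <- taxonomy[[rank]][match(ids, taxonomy$otu_id)]
    tax[is.na(tax)] <- "unclassified"
    agg <- tapply(pooled, tax, sum)
    out[[length(out) + 1]] <- data.frame(
      class = partition$class, group = gn, taxon = names(agg),
      percent = 100 * as.numeric(agg) / sum(pooled),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(class = character(), group = character(),
                      taxon = character(), percent = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Coherence partitions for every class with enough OTUs
#'
#' Convenience loop over all class labels present in the taxonomy (or a
#' supplied subset), returning one `coherence_partition` per class; under
#' `family = "global"` the Bonferroni family is the total number of
#' testable OTUs across all analyzed classes.
#'
#' @inheritParams partition_class
#' @param classes Character vector of class labels (default: all classes
#'   in the taxonomy with at least `min_otus` OTUs present in the table).
#' @param min_otus Minimum class size to analyze (default 2).
#' @return Named list of `coherence_partition` objects.
#' @export
partition_all_classes <- function(table, taxonomy, classes = NULL,
                                  alpha = 0.05,
                                  family = c("within_class", "global"),
                                  self_inclusion = TRUE, min_otus = 2) {
  family <- match.arg(family)
  if (is.null(classes)) {
    cls <- taxonomy$class[taxonomy$otu_id %in% rownames(table)]
    tab <- table(cls[!is.na(cls)])
    classes <- names(tab)[tab >= min_otus]
  }
  parts <- lapply(classes, function(k)
    partition_class(table, taxonomy, k, alpha = alpha,
                    family = "within_class", self_inclusion = self_inclusion))
  names(parts) <- classes
  if (family == "global") {
    fam <- sum(vapply(parts, function(p)
      sum(p$records$verdict != "untestable"), numeric(1)))
    parts <- lapply(classes, function(k)
      partition_class(table, taxonomy, k, alpha = alpha, family = "global",
                      family_size = fam, self_inclusion = self_inclusion))
    names(parts) <- classes
  }
  parts
}
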