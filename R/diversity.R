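#' Rarefy an OTU table to even sequencing depth
#'
#' Subsamples each sample's sequence pool without replacement
#' (hypergeometric) so that every retained sample sums exactly to `depth`.
#' Samples whose total falls below `depth` are dropped and reported in the
#' `"dropped_samples"` attribute, mirroring the usual practice of excluding
#' under-sequenced samples rather than padding them.
#'
#' @param table An [otu_table].
#' @param depth Target number of sequences per sample (positive integer).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A rarefied [otu_table] whose columns each sum to `depth`, with
#'   attribute `dropped_samples` naming any excluded samples.
#' @export
rarefy <- function(table, depth, seed) {
  stopifnot(inherits(table, "otu_table"))
  if (length(depth) != 1 || !is.finite(depth) || depth < 1 ||
      depth != round(depth))
    stop("depth must be a positive integer", call. = FALSE)
  totals <- colSums(table)
  keep <- totals >= depth
  dropped <- colnames(table)[!keep]
  if (!any(keep))
    stop("no sample reaches depth ", depth,
         "; all samples dropped: ", paste(dropped, collapse = ", "),
         call. = FALSE)
  sub <- table[, keep]
  set.seed(as.integer(seed))
  # vegan warns when the smallest nonzero count exceeds 1 (a heuristic for
  # non-count data); our inputs are validated integer counts
  rar <- withCallingHandlers(
    t(vegan::rrarefy(t(unclass(sub)), sample = depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  out <- otu_table(rar, otu_ids = rownames(sub), sample_ids = colnames(sub))
  attr(out, "dropped_samples") <- dropped
  out
}

#' Shannon diversity index
#'
#' H = -sum p_i log p_i over the positive entries of a count vector,
#' p_i = count_i / total. Natural log by default (nats); base 2 available.
#'
#' @param counts Non-negative numeric vector with at least one positive
#'   entry.
#' @param base `"e"` (default, nats) or `"2"` (bits).
#' @return The Shannon index (0 for a single-taxon vector).
#' @export
shannon <- function(counts, base = c("e", "2")) {
  base <- match.arg(base)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative with no missing values", call. = FALSE)
  if (sum(counts) == 0)
    stop("Shannon index is undefined for an all-zero vector", call. = FALSE)
  p <- counts[counts > 0] / sum(counts)
  h <- -sum(p * log(p))
  if (base == "2") h <- h / log(2)
  h
}

#' Mean pairwise phylogenetic distance (MPD)
#'
#' Mean of the patristic distances over all unordered pairs of distinct
#' taxa present in a community. The default is presence-based; with
#' `weighted = TRUE` each pair is weighted by the product of the taxa's
#' relative abundances.
#'
#' @param present_taxa Character vector of tip labels present in the
#'   community (must all be tips of `tree`).
#' @param tree A rooted ape `phylo` with branch lengths.
#' @param weighted If `TRUE`, abundance-weight pairs; requires `abundances`.
#' @param abundances Numeric vector of abundances aligned with
#'   `present_taxa` (only used when `weighted = TRUE`).
#' @return The MPD, or `NA_real_` when fewer than two taxa are present.
#' @export
mpd <- function(present_taxa, tree, weighted = FALSE, abundances = NULL) {
  present_taxa <- as.character(present_taxa)
  check_ids(present_taxa, tree$tip.label, "tree tips")
  if (length(present_taxa) < 2) return(NA_real_)
  d <- ape::cophenetic.phylo(tree)[present_taxa, present_taxa]
  if (!weighted) return(mean(d[lower.tri(d)]))
  if (is.null(abundances) || length(abundances) != length(present_taxa))
    stop("weighted MPD needs abundances aligned with present_taxa",
         call. = FALSE)
  w <- abundances / sum(abundances)
  ww <- outer(w, w)
  lt <- lower.tri(d)
  sum(d[lt] * ww[lt]) / sum(ww[lt])
}

#' Per-sample alpha diversity records
#'
#' For each sample: number of sequences, observed richness, Shannon index,
#' and (when a tree is supplied) presence-based MPD of the OTUs detected in
#' that sample. A `scope` label records whether the table is the whole
#' community, one class, or one coherence subgroup.
#'
#' @param table An [otu_table].
#' @param tree Optional rooted `phylo` covering the table's OTUs; when
#'   absent, `mpd` is NA.
#' @param scope Label stored with each record (default `"all"`).
#' @param weighted_mpd Abundance-weight the MPD (default presence-based).
#' @return Data frame with columns `sample_id`, `scope`, `n_sequences`,
#'   `richness`, `shannon`, `mpd`.
#' @export
alpha_diversity <- function(table, tree = NULL, scope = "all",
                            weighted_mpd = FALSE) {
  stopifnot(inherits(table, "otu_table"))
  res <- lapply(colnames(table), function(s) {
    x <- table[, s][, 1]
    pos <- x > 0
    data.frame(
      sample_id = s, scope = scope, n_sequences = sum(x),
      richness = sum(pos),
      shannon = if (sum(x) > 0) shannon(x) else NA_real_,
      mpd = if (is.null(tree) || sum(pos) < 2) NA_real_ else
        mpd(rownames(table)[pos], tree, weighted = weighted_mpd,
            abundances = x[pos]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' OTU accumulation (collector) curve
#'
#' Pools all sequences across samples, draws them in random order, and
#' records the mean cumulative number of distinct OTUs observed at every
#' `grain` sequences, averaged over `reps` shuffles. The final point equals
#' the total observed richness.
#'
#' @param table An [otu_table].
#' @param grain Step size in sequences (positive integer, at most the
#'   pooled total).
#' @param reps Number of random orderings to average (default 10).
#' @param seed Integer seed.
#' @return Data frame with columns `n_sequences`, `mean_otus`.
#' @export
collector_curve <- function(table, grain, reps = 10, seed = 1) {
  stopifnot(inherits(table, "otu_table"))
  pooled <- rowSums(table)
  total <- sum(pooled)
  if (grain < 1 || grain != round(grain) || grain > total)
    stop("grain must be a positive integer no larger than the pooled total",
         call. = FALSE)
  points <- unique(c(seq(grain, total, by = grain), total))
  set.seed(as.integer(seed))
  curves <- vapply(seq_len(reps), function(r) {
    perm <- sample(rep.int(seq_along(pooled), pooled))
    firstpos <- sort(which(!duplicated(perm)))
    findInterval(points, firstpos)
  }, numeric(length(points)))
  data.frame(n_sequences = points,
             mean_otus = rowMeans(matrix(curves, nrow = length(points))))
}

#' Upstream vs. downstream contrast for an alpha-diversity metric
#'
#' Compares mean metric values between upstream and downstream samples
#' (reservoir excluded) with a one-way ANOVA, and reports a signed
#' fold-change: `up/down` when the upstream mean is at least the downstream
#' mean, `-(down/up)` otherwise, so positive values mean "higher upstream".
#' A log2 ratio is also emitted.
#'
#' @param records Data frame from [alpha_diversity].
#' @param frames Validated sample metadata (see [read_metadata]).
#' @param metric Name of the record column to contrast
#'   (`"n_sequences"`, `"richness"`, `"shannon"`, or `"mpd"`).
#' @return One-row data frame: `metric`, `mean_upstream`, `mean_downstream`,
#'   `signed_ratio`, `log2_ratio`, `anova_p`.
#' @export
reach_contrast <- function(records, frames, metric) {
  if (!metric %in% names(records))
    stop("unknown metric: ", metric, call. = FALSE)
  check_ids(records$sample_id, frames$sample_id, "sample metadata")
  reach <- frames$reach[match(records$sample_id, frames$sample_id)]
  ok <- reach %in% c("upstream", "downstream") & !is.na(records[[metric]])
  v <- records[[metric]][ok]
  g <- droplevels(factor(reach[ok], levels = c("upstream", "downstream")))
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need at least two upstream and two downstream samples", call. = FALSE)
  mu <- tapply(v, g, mean)
  up <- mu[["upstream"]]; dw <- mu[["downstream"]]
  ratio <- if (up >= dw) up / dw else -(dw / up)
  # one-way ANOVA with explicit handling of the degenerate zero-variance cases
  gm <- mean(v)
  ssb <- sum(tapply(v, g, function(z) length(z) * (mean(z) - gm)^2))
  ssw <- sum(tapply(v, g, function(z) sum((z - mean(z))^2)))
  df1 <- nlevels(g) - 1L
  df2 <- length(v) - nlevels(g)
  p <- if (ssb <= .Machine$double.eps * sum(v^2)) 1 else
    if (ssw == 0) 0 else
      stats::pf((ssb / df1) / (ssw / df2), df1, df2, lower.tail = FALSE)
  data.frame(metric = metric, mean_upstream = up, mean_downstream = dw,
             signed_ratio = ratio, log2_ratio = log2(up / dw), anova_p = p,
             stringsAsFactors = FALSE)
}
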