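#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i) over OTUs; computed on the
#' counts as supplied (the pipeline applies it to the rarefied table so
#' that samples are directly comparable).
#'
#' @param table An [otu_table] with at least two samples and no all-zero
#'   sample columns.
#' @return A square symmetric matrix keyed by sample ids with zero
#'   diagonal and entries in \[0, 1\]; attribute `metric` is
#'   `"bray_curtis"`.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  if (ncol(table) < 2) stop("need at least two samples", call. = FALSE)
  zero <- colSums(table) == 0
  if (any(zero))
    stop("Bray-Curtis is undefined for all-zero sample(s): ",
         paste(colnames(table)[zero], collapse = ", "), call. = FALSE)
  d <- as.matrix(vegan::vegdist(t(unclass(table)), method = "bray"))
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Weighted-normalized UniFrac distance between samples
#'
#' For each pair of samples, branch lengths are weighted by the absolute
#' difference in the fraction of each sample's sequences descending from
#' the branch, and normalized by the abundance-weighted total branch
#' length: d = sum_b l_b |p_b(x) - p_b(y)| / sum_b l_b (p_b(x) + p_b(y)).
#' Tree tips absent from the table contribute zero abundance.
#'
#' @param table An [otu_table]; every OTU with a nonzero row must be a tip
#'   of `tree`.
#' @param tree Rooted ape `phylo` with branch lengths.
#' @return Square symmetric matrix in \[0, 1\] with attribute
#'   `metric = "weighted_normalized_unifrac"`.
#' @export
weighted_normalized_unifrac <- function(table, tree) {
  stopifnot(inherits(table, "otu_table"))
  if (ncol(table) < 2) stop("need at least two samples", call. = FALSE)
  zero <- colSums(table) == 0
  if (any(zero))
    stop("UniFrac is undefined for all-zero sample(s): ",
         paste(colnames(table)[zero], collapse = ", "), call. = FALSE)
  present <- rownames(table)[rowSums(table) > 0]
  check_ids(present, tree$tip.label, "tree tips")
  rel <- sweep(unclass(table), 2, colSums(table), "/")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  # per-sample abundance fraction descending from each node, by postorder
  ab <- matrix(0, ntip + nnode, ncol(table))
  hit <- intersect(tree$tip.label, rownames(rel))
  ab[match(hit, tree$tip.label), ] <- rel[hit, , drop = FALSE]
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge)))
    ab[tr$edge[k, 1], ] <- ab[tr$edge[k, 1], ] + ab[tr$edge[k, 2], ]
  p <- ab[tr$edge[, 2], , drop = FALSE]    # branch-descendant fraction
  l <- tr$edge.length
  n <- ncol(table)
  d <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- sum(l * abs(p[, i] - p[, j]))
    den <- sum(l * (p[, i] + p[, j]))
    d[i, j] <- d[j, i] <- if (den == 0) 0 else num / den
  }
  attr(d, "metric") <- "weighted_normalized_unifrac"
  d
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities: R = (mean between-group rank - mean
#' within-group rank) / (M/2), M = n(n-1)/2, computed on the ranks of all
#' pairwise distances. Significance by random permutation of group labels,
#' with the +1 correction so p is never zero.
#'
#' @param dist Square symmetric distance matrix with sample ids as
#'   dimnames (as returned by [bray_curtis] or
#'   [weighted_normalized_unifrac]).
#' @param grouping Named character vector or factor mapping sample id to
#'   group label (names must cover the distance matrix), or an unnamed
#'   vector aligned with the matrix order.
#' @param n_permutations Number of label permutations (default 9999).
#' @param seed Integer seed; identical seeds give identical p-values.
#' @return An object of class `anosim_result`: list with `statistic`
#'   (R in \[-1, 1\]), `p_value`, `n_permutations`, `seed`, `grouping`.
#' @export
anosim <- function(dist, grouping, n_permutations = 9999, seed = 1) {
  m <- as.matrix(dist)
  n <- nrow(m)
  ids <- rownames(m)
  if (!is.null(names(grouping))) {
    check_ids(ids, names(grouping), "grouping")
    g <- as.character(grouping[ids])
  } else {
    if (length(grouping) != n)
      stop("unnamed grouping must align with the distance matrix",
           call. = FALSE)
    g <- as.character(grouping)
  }
  tab <- table(g)
  if (length(tab) < 2)
    stop("ANOSIM needs at least two groups", call. = FALSE)
  if (any(tab < 2))
    stop("singleton group(s): ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  lt <- which(lower.tri(m))
  pi_ <- row(m)[lt]; pj <- col(m)[lt]
  r <- rank(m[lt])
  M <- length(r)
  stat_for <- function(lab) {
    within <- lab[pi_] == lab[pj]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  observed <- stat_for(g)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_permutations),
                 function(i) stat_for(sample(g)), numeric(1))
  p <- (sum(perm >= observed) + 1) / (n_permutations + 1)
  structure(list(statistic = observed, p_value = p,
                 n_permutations = n_permutations, seed = seed,
                 grouping = g),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat("ANOSIM: R =", format(x$statistic, digits = 4),
      ", p =", format(x$p_value, digits = 4),
      "(", x$n_permutations, "permutations, seed", x$seed, ")\n")
  invisible(x)
}
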