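#' Assign each OTU its origin reach under unidirectional flow
#'
#' Each OTU is assigned to the farthest-upstream river reach (or site,
#' under site resolution) where it is detected at all, pooling every
#' campaign, on the assumption that water — and the cells it carries —
#' moves only downstream. Meant for the non-rarefied table so that rare
#' detections count.
#'
#' @param table An [otu_table] (non-rarefied; all campaigns pooled).
#' @param frames Validated sample metadata.
#' @param resolution `"reach"` (default) or `"site"`; under site
#'   resolution the earliest-flow-order site of first detection is also
#'   reported.
#' @return Data frame with columns `otu_id`, `origin` (factor upstream /
#'   reservoir / downstream) and, under site resolution, `origin_site`.
#'   OTUs with zero total are excluded and listed in attribute
#'   `excluded_otus`.
#' @export
assign_origin <- function(table, frames, resolution = c("reach", "site")) {
  resolution <- match.arg(resolution)
  stopifnot(inherits(table, "otu_table"))
  check_ids(colnames(table), frames$sample_id, "sample metadata")
  idx <- match(colnames(table), frames$sample_id)
  reach <- frames$reach[idx]
  fo <- frames$flow_order[idx]
  totals <- rowSums(table)
  excluded <- rownames(table)[totals == 0]
  keep <- rownames(table)[totals > 0]
  det <- unclass(table)[keep, , drop = FALSE] > 0
  if (resolution == "reach") {
    ord <- as.integer(reach)                      # upstream < reservoir < downstream
    origin <- apply(det, 1, function(z) min(ord[z]))
    out <- data.frame(otu_id = keep,
                      origin = factor(REACH_LEVELS[origin],
                                      levels = REACH_LEVELS),
                      stringsAsFactors = FALSE)
  } else {
    first <- apply(det, 1, function(z) which(z)[which.min(fo[z])])
    out <- data.frame(otu_id = keep,
                      origin = factor(as.character(reach[first]),
                                      levels = REACH_LEVELS),
                      origin_site = frames$site_id[idx][first],
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "excluded_otus") <- excluded
  out
}

#' Assign each OTU the reach where it is most abundant
#'
#' An OTU is upstream-, reservoir-, or downstream-dominant when its summed
#' sequence abundance in that reach strictly exceeds both other reaches;
#' any tie for the maximum yields `"no_change"`. Reach sums pool all sites
#' and campaigns. A per-site-mean variant divides each reach sum by its
#' site count to offset the unequal 6/1/5 design.
#'
#' @param table An [otu_table] (non-rarefied; all campaigns pooled).
#' @param frames Validated sample metadata.
#' @param per_site_mean Compare per-site means instead of raw reach sums.
#' @return Data frame with columns `otu_id`, `dominance` (factor
#'   upstream_dominant / reservoir_dominant / downstream_dominant /
#'   no_change); zero-total OTUs excluded and listed in attribute
#'   `excluded_otus`.
#' @export
assign_dominance <- function(table, frames, per_site_mean = FALSE) {
  stopifnot(inherits(table, "otu_table"))
  check_ids(colnames(table), frames$sample_id, "sample metadata")
  reach <- frames$reach[match(colnames(table), frames$sample_id)]
  totals <- rowSums(table)
  excluded <- rownames(table)[totals == 0]
  keep <- totals > 0
  sums <- matrix(vapply(REACH_LEVELS, function(rc)
    rowSums(unclass(table)[keep, reach == rc, drop = FALSE]),
    numeric(sum(keep))), ncol = length(REACH_LEVELS),
    dimnames = list(NULL, REACH_LEVELS))
  if (per_site_mean) {
    nsites <- vapply(REACH_LEVELS, function(rc)
      length(unique(frames$site_id[frames$reach == rc])), numeric(1))
    sums <- sweep(sums, 2, pmax(nsites, 1), "/")
  }
  labels <- c("upstream_dominant", "reservoir_dominant", "downstream_dominant")
  lab <- apply(sums, 1, function(z) {
    top <- which(z == max(z))
    if (length(top) > 1) "no_change" else labels[top]
  })
  out <- data.frame(otu_id = rownames(table)[keep],
                    dominance = factor(lab, levels = c(labels, "no_change")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded_otus") <- excluded
  out
}

#' Per-class reach-level fractions of sequences by OTU category
#'
#' For each bacterial class and each focal reach, the fraction of that
#' reach's class sequences carried by OTUs of each origin (or dominance)
#' category. Sites within a reach are pooled by summation within each
#' campaign; the per-campaign fractions are then averaged over campaigns.
#' A class with zero sequences in a reach for every campaign yields
#' missing fractions, not zeros.
#'
#' @param table An [otu_table] (non-rarefied).
#' @param frames Validated sample metadata.
#' @param taxonomy Taxonomy data frame (see [read_taxonomy]); every
#'   included OTU needs a class label.
#' @param categories Data frame from [assign_origin] or
#'   [assign_dominance].
#' @param by `"origin"` or `"dominance"` — which category column to use.
#' @return Data frame with columns `class`, `reach`, `category`,
#'   `fraction`; fractions within a (class, reach) cell sum to 1 (or are
#'   all NA).
#' @export
summarize_reach_fractions <- function(table, frames, taxonomy, categories,
                                      by = c("origin", "dominance")) {
  by <- match.arg(by)
  stopifnot(inherits(table, "otu_table"))
  if (!by %in% names(categories))
    stop("categories lack a '", by, "' column", call. = FALSE)
  otus <- categories$otu_id
  check_ids(otus, rownames(table), "OTU table")
  check_ids(otus, taxonomy$otu_id, "taxonomy")
  cls <- taxonomy$class[match(otus, taxonomy$otu_id)]
  if (anyNA(cls))
    stop("class label missing for OTU(s): ",
         paste(utils::head(otus[is.na(cls)], 5), collapse = ", "),
         call. = FALSE)
  cat_lev <- levels(categories[[by]])
  catv <- as.character(categories[[by]])
  idx <- match(colnames(table), frames$sample_id)
  reach <- frames$reach[idx]
  campaign <- frames$campaign[idx]
  out <- list()
  for (k in unique(cls)) {
    rows <- otus[cls == k]
    kcat <- catv[cls == k]
    sub <- unclass(table)[rows, , drop = FALSE]
    for (rc in REACH_LEVELS) {
      # per-campaign fractions, then average over campaigns with sequences
      fr <- sapply(unique(campaign), function(cp) {
        cols <- which(reach == rc & campaign == cp)
        if (length(cols) == 0) return(rep(NA_real_, length(cat_lev)))
        pooled <- rowSums(sub[, cols, drop = FALSE])
        tot <- sum(pooled)
        if (tot == 0) return(rep(NA_real_, length(cat_lev)))
        vapply(cat_lev, function(cc) sum(pooled[kcat == cc]) / tot, numeric(1))
      })
      fr <- matrix(fr, nrow = length(cat_lev))
      mean_fr <- rowMeans(fr, na.rm = TRUE)
      mean_fr[is.nan(mean_fr)] <- NA_real_
      out[[length(out) + 1]] <- data.frame(
        class = k, reach = rc, category = cat_lev, fraction = mean_fr,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
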