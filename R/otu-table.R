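#' Construct a validated OTU count table
#'
#' An `otu_table` is the single substrate of every analysis stage: a
#' non-negative integer matrix of sequence counts with OTUs as rows and
#' samples as columns, carrying unique identifiers on both axes.
#'
#' @param counts Numeric matrix of counts (rows = OTUs, columns = samples).
#'   All entries must be non-negative integers (integer-valued doubles are
#'   accepted and coerced).
#' @param otu_ids Character vector of unique OTU identifiers; defaults to
#'   `rownames(counts)`.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `colnames(counts)`.
#'
#' @return An object of class `otu_table`: an integer matrix with OTU row
#'   names and sample column names.
#' @examples
#' tab <- otu_table(matrix(c(1, 0, 2, 5, 0, 3), nrow = 3, byrow = TRUE,
#'                  dimnames = list(paste0("OTU", 1:3), c("s1", "s2"))))
#' n_otus(tab)
#' @export
otu_table <- function(counts, otu_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(otu_ids) || is.null(sample_ids))
    stop("both OTU and sample identifiers are required", call. = FALSE)
  otu_ids <- as.character(otu_ids)
  sample_ids <- as.character(sample_ids)
  if (length(otu_ids) != nrow(counts))
    stop("length of otu_ids (", length(otu_ids), ") does not match row count (",
         nrow(counts), ")", call. = FALSE)
  if (length(sample_ids) != ncol(counts))
    stop("length of sample_ids (", length(sample_ids),
         ") does not match column count (", ncol(counts), ")", call. = FALSE)
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU identifiers: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values", call. = FALSE)
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("counts must be non-negative integers; first offending cell: row ",
         otu_ids[bad[1, 1]], ", column ", sample_ids[bad[1, 2]],
         " (value ", counts[bad[1, , drop = FALSE]], ")", call. = FALSE)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(otu_ids, sample_ids)
  structure(counts, class = c("otu_table", "matrix", "array"))
}

#' @rdname otu_table
#' @param x An `otu_table`.
#' @export
n_otus <- function(x) nrow(x)

#' @rdname otu_table
#' @export
n_samples <- function(x) ncol(x)

#' @rdname otu_table
#' @export
otu_ids <- function(x) rownames(x)

#' @rdname otu_table
#' @export
sample_ids <- function(x) colnames(x)

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table: ", nrow(x), " OTUs x ", ncol(x), " samples; ",
      format(sum(as.numeric(x)), big.mark = ","), " sequences\n", sep = "")
  invisible(x)
}

#' Subset an OTU table, keeping class and validity
#'
#' @param x An `otu_table`.
#' @param i,j Row (OTU) and column (sample) indices or names.
#' @param ... Ignored.
#' @param drop Ignored; dimensions are always kept.
#' @return An `otu_table`.
#' @export
`[.otu_table` <- function(x, i, j, ..., drop = FALSE) {
  m <- unclass(x)
  m <- m[i, j, drop = FALSE]
  structure(m, class = c("otu_table", "matrix", "array"))
}

# internal: error listing identifiers missing from a join target
check_ids <- function(needed, available, what) {
  missing <- setdiff(needed, available)
  if (length(missing) > 0)
    stop("identifiers missing from ", what, ": ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) paste0(" (and ", length(missing) - 10, " more)"),
         call. = FALSE)
  invisible(TRUE)
}
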