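#' Read an OTU count table from disk
#'
#' Reads the classic tab-separated OTU-by-sample dialect (first column OTU
#' identifier, header row of sample identifiers, integer cells; a leading
#' `#OTU ID` header as written by QIIME-era tools is accepted alongside a
#' bare header) or a BIOM file.
#'
#' @param path Path to the file.
#' @param format `"classic_tsv"` (default) or `"biom"`. BIOM reading uses
#'   the biomformat package.
#' @return A validated [otu_table] with row/column order as in the file.
#' @export
read_otu_table <- function(path, format = c("classic_tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the biomformat package", call. = FALSE)
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(otu_table(m))
  }
  first <- readLines(path, n = 1L)
  header <- strsplit(sub("^#OTU ID", "otu_id", first), "\t", fixed = TRUE)[[1]]
  raw <- utils::read.delim(path, header = FALSE, skip = 1L, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "")
  if (ncol(raw) != length(header))
    stop("header has ", length(header), " fields but data rows have ",
         ncol(raw), call. = FALSE)
  ids <- raw[[1]]
  samples <- header[-1]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("malformed count at OTU '", ids[bad[1, 1]], "', sample '",
         samples[bad[1, 2]], "': '", cells[bad[1, , drop = FALSE]],
         "' is not a non-negative integer", call. = FALSE)
  otu_table(num, otu_ids = ids, sample_ids = samples)
}

#' Write an OTU count table to disk
#'
#' Classic tab-separated dialect with a `#OTU ID` header; the exact inverse
#' of [read_otu_table] so that write-then-read is the identity.
#'
#' @param x An [otu_table].
#' @param path Output path.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("#OTU ID", colnames(x)), collapse = "\t"), con)
  utils::write.table(unclass(x), con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}

REACH_LEVELS <- c("upstream", "reservoir", "downstream")

#' Read or validate per-sample metadata
#'
#' Sample metadata define the spatial/temporal design: each sample belongs
#' to a site, a reach (upstream, reservoir, or downstream of the dam
#' system), a strictly increasing along-flow site order, and a sampling
#' campaign. `read_metadata()` reads a tab-separated file with columns
#' `sample_id`, `site_id`, `reach`, `flow_order`, `campaign`;
#' `validate_sample_frames()` checks an in-memory data frame of the same
#' shape.
#'
#' @param path Path to a tab-separated metadata file with a header row.
#' @return A data frame with the five required columns; `reach` is a factor
#'   with levels upstream < reservoir < downstream.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_sample_frames(df)
}

#' @rdname read_metadata
#' @param frames Data frame with columns `sample_id`, `site_id`, `reach`,
#'   `flow_order`, `campaign`.
#' @export
validate_sample_frames <- function(frames) {
  required <- c("sample_id", "site_id", "reach", "flow_order", "campaign")
  missing <- setdiff(required, names(frames))
  if (length(missing) > 0)
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  frames <- as.data.frame(frames)[required]
  for (col in c("sample_id", "site_id", "reach", "campaign")) {
    v <- as.character(frames[[col]])
    if (anyNA(v) || any(!nzchar(trimws(v))))
      stop("metadata column '", col, "' has empty or missing entries",
           call. = FALSE)
    frames[[col]] <- v
  }
  fo <- suppressWarnings(as.numeric(frames$flow_order))
  if (anyNA(fo) || any(fo != round(fo)))
    stop("flow_order must be integer for every sample", call. = FALSE)
  frames$flow_order <- as.integer(fo)
  if (!all(frames$reach %in% REACH_LEVELS))
    stop("reach must be one of: ", paste(REACH_LEVELS, collapse = ", "),
         "; offending values: ",
         paste(unique(setdiff(frames$reach, REACH_LEVELS)), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(frames$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(frames$sample_id[duplicated(frames$sample_id)]),
               collapse = ", "), call. = FALSE)
  key <- paste(frames$site_id, frames$campaign, sep = "\r")
  if (anyDuplicated(key))
    stop("each (site_id, campaign) pair may appear at most once", call. = FALSE)
  up <- frames$flow_order[frames$reach == "upstream"]
  rs <- frames$flow_order[frames$reach == "reservoir"]
  dw <- frames$flow_order[frames$reach == "downstream"]
  if (length(rs) > 0 && ((length(up) > 0 && max(up) >= min(rs)) ||
                         (length(dw) > 0 && min(dw) <= max(rs))))
    stop("flow_order must strictly increase from upstream through reservoir ",
         "to downstream reaches", call. = FALSE)
  if (length(rs) == 0 && length(up) > 0 && length(dw) > 0 &&
      max(up) >= min(dw))
    stop("upstream flow_order must be below every downstream flow_order",
         call. = FALSE)
  frames$reach <- factor(frames$reach, levels = REACH_LEVELS)
  rownames(frames) <- NULL
  frames
}

#' Read or build an OTU taxonomy map
#'
#' Lineages are semicolon-delimited strings ordered domain, phylum, class,
#' order, family, genus; entries may be unassigned below some rank.
#' Greengenes-style rank prefixes (`k__`, `c__`, ...) are tolerated and
#' stripped.
#'
#' @param path Path to a two-column tab-separated file (`otu_id`, lineage),
#'   with or without a header row.
#' @return A data frame with columns `otu_id`, `domain`, `phylum`, `class`,
#'   `order`, `family`, `genus` (NA where unassigned).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "")
  if (ncol(df) < 2)
    stop("taxonomy file must have two tab-separated columns", call. = FALSE)
  if (tolower(df[1, 1]) %in% c("otu_id", "#otu id", "otu"))
    df <- df[-1, , drop = FALSE]
  taxonomy_from_lineages(df[[1]], df[[2]])
}

#' @rdname read_taxonomy
#' @param ids Character vector of OTU identifiers.
#' @param lineages Character vector of semicolon-delimited lineage strings.
#' @export
taxonomy_from_lineages <- function(ids, lineages) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate otu_id in taxonomy: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  parts <- strsplit(as.character(lineages), ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[a-zA-Z]__", "", p)
    p[!nzchar(p)] <- NA_character_
    length(p) <- 6L
    p
  }, character(6)))
  out <- data.frame(otu_id = ids, mat, stringsAsFactors = FALSE)
  names(out) <- c("otu_id", ranks)
  out
}

#' Read a rooted phylogenetic tree
#'
#' Newick input via ape; validates that the tree is rooted, tip labels are
#' unique, and every branch length is finite and non-negative.
#'
#' @param path Path to a Newick file.
#' @return An ape `phylo` object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick tree: ", path, call. = FALSE)
  validate_tree(tree)
}

# internal: shared tree validity checks
validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("tree tip labels are not unique", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("every branch length must be finite and non-negative", call. = FALSE)
  if (!ape::is.rooted(tree))
    stop("tree must be rooted", call. = FALSE)
  tree
}

#' Read an environmental variable matrix
#'
#' Tab-separated, first column `sample_id`, remaining columns real-valued
#' environmental variables (temperature, conductivity, nutrients, ...).
#'
#' @param path Path to the file.
#' @return Numeric matrix, samples as rows (named), variables as columns.
#' @export
read_env <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample_id in environmental table", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m))
    stop("environmental variables must be numeric with no missing values",
         call. = FALSE)
  rownames(m) <- ids
  m
}

#' Write a result table as tab-separated UTF-8
#'
#' All pipeline outputs are tab-separated with a header row; this is the
#' single writer they share.
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
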