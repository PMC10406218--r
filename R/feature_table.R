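#' Construct a feature table
#'
#' A feature table holds non-negative integer counts of microbial features
#' (ASVs or OTUs) per sample. Samples are rows, features are columns;
#' dimnames carry the sample and feature identifiers.
#'
#' @param counts Numeric matrix of non-negative integer counts
#'   (samples x features).
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `rownames(counts)`.
#' @param feature_ids Character vector of unique feature identifiers; defaults
#'   to `colnames(counts)`.
#' @return An object of class `feature_table`: an integer matrix with
#'   samples as rows and features as columns.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'             dimnames = list(c("S1A1", "S1B1"), c("ASV1", "ASV2")))
#' feature_table(m)
#' @export
feature_table <- function(counts, sample_ids = rownames(counts),
                          feature_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(feature_ids))
    stop("sample and feature identifiers are required")
  if (length(sample_ids) != nrow(counts) ||
      length(feature_ids) != ncol(counts))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature identifiers: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, feature_ids)
  class(counts) <- c("feature_table", "matrix", "array")
  counts
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples x %d features, %s total reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Write a feature table as TSV
#'
#' Features are written as rows and samples as columns (the layout of
#' classic QIIME-style tables), with a header row of sample identifiers and
#' a leading `feature_id` column.
#'
#' @param table A [feature_table].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(feature_id = colnames(table), t(unclass(table)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from TSV
#'
#' Reads the dialect written by [write_feature_table()] (features as rows,
#' samples as columns, first column `feature_id` or `#OTU ID`), or its
#' transpose (first column `sample_id`); the orientation is auto-detected
#' from the header. Round-trips bit-exactly with [write_feature_table()].
#'
#' @param path Path to a TSV file.
#' @return A [feature_table].
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("feature table file has no data rows: ", path)
  # classic BIOM-TSV tables carry a comment line before the "#OTU ID" header
  if (grepl("^# ", lines[1L]) && length(lines) > 2L &&
      grepl("^#OTU ID\t", lines[2L]))
    lines <- lines[-1L]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    stop("ragged row at line ", which(widths != widths[1L])[1L], " in ", path)
  header <- cells[[1L]]
  body <- cells[-1L]
  ids <- vapply(body, `[[`, character(1), 1L)
  vals <- lapply(body, function(r) r[-1L])
  num <- suppressWarnings(
    matrix(as.numeric(unlist(vals)), nrow = length(body), byrow = TRUE))
  bad <- which(apply(num, 1L, anyNA))
  if (length(bad))
    stop("non-numeric count at line ", bad[1L] + 1L, " in ", path)
  if (any(num != round(num)))
    stop("non-integer count in ", path)
  if (any(num < 0))
    stop("negative count in ", path)
  by_sample_rows <- identical(header[1L], "sample_id")
  if (by_sample_rows) {
    feature_table(num, sample_ids = ids, feature_ids = header[-1L])
  } else {
    feature_table(t(num), sample_ids = header[-1L], feature_ids = ids)
  }
}

#' Rare-feature filter cutoff
#'
#' The minimum total read count a feature must reach to survive the
#' rare-feature filter: `fraction` times the table's grand total. Features
#' strictly below the cutoff are removed by [filter_rare_features()].
#'
#' @param grand_total Total reads across all samples and features.
#' @param fraction Proportion of total reads; the conventional value is
#'   0.005\% (`5e-5`).
#' @return The cutoff as a double.
#' @examples
#' rare_cutoff(48389, 5e-5)  # 2.41945
#' @export
rare_cutoff <- function(grand_total, fraction = 5e-5) {
  stopifnot(grand_total >= 0, fraction >= 0, fraction < 1)
  fraction * grand_total
}

#' Remove rare features from a table
#'
#' Features whose total count across all samples is strictly less than
#' `fraction` of the grand total of the input table are removed. The sample
#' set and the retained counts are unchanged. The grand total is always that
#' of the input table, so re-filtering an already filtered table with the
#' same *cutoff* removes nothing; note that re-applying the *fraction* to a
#' filtered table's own (smaller) grand total could remove more features,
#' which is why the fraction is applied exactly once in the pipeline.
#'
#' @param table A [feature_table].
#' @param fraction Proportion of the grand total, in `[0, 1)`. Default
#'   0.005\%.
#' @return A new, filtered [feature_table]; the cutoff used is attached as
#'   attribute `"cutoff"`.
#' @export
filter_rare_features <- function(table, fraction = 5e-5) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table) == 0L || ncol(table) == 0L)
    stop("cannot filter an empty feature table")
  stopifnot(fraction >= 0, fraction < 1)
  totals <- colSums(unclass(table))
  cutoff <- rare_cutoff(sum(totals), fraction)
  keep <- totals >= cutoff
  out <- feature_table(unclass(table)[, keep, drop = FALSE],
                       sample_ids = rownames(table),
                       feature_ids = colnames(table)[keep])
  attr(out, "cutoff") <- cutoff
  out
}

#' Presence/absence matrix
#'
#' @param table A [feature_table].
#' @return A binary integer matrix (samples x features); entry 1 iff the
#'   count is positive.
#' @export
presence_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  m <- (unclass(table) > 0L) * 1L
  dimnames(m) <- dimnames(table)
  m
}

#' Aggregate features into coarser groups
#'
#' Sums counts of features mapped to the same group, emulating a
#' coarser clustering level (e.g. an OTU-like table from an ASV-like one).
#'
#' @param table A [feature_table].
#' @param groups Character vector naming the group of each feature, in
#'   feature order (or named by feature id).
#' @return A [feature_table] with one column per group.
#' @export
aggregate_features <- function(table, groups) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.null(names(groups))) groups <- groups[colnames(table)]
  if (length(groups) != ncol(table) || anyNA(groups))
    stop("'groups' must name a group for every feature")
  g <- factor(groups, levels = unique(groups))
  agg <- sapply(split(seq_len(ncol(table)), g), function(j)
    rowSums(unclass(table)[, j, drop = FALSE]))
  feature_table(agg, sample_ids = rownames(table),
                feature_ids = levels(g))
}

#' Write sample metadata as TSV
#'
#' @param meta Sample metadata data frame (columns `sample_id`, `twin_pair`,
#'   `individual`, `time_point`, `month_offset`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path Path to a TSV written by [write_sample_metadata()].
#' @return A data frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "twin_pair", "individual", "time_point",
              "month_offset")
  missing <- setdiff(needed, names(meta))
  if (length(missing))
    stop("metadata is missing columns: ", paste(missing, collapse = ", "))
  validate_metadata(meta)
  meta
}

validate_metadata <- function(meta) {
  key <- paste(meta$twin_pair, meta$individual, meta$time_point)
  if (anyDuplicated(key))
    stop("duplicate (twin_pair, individual, time_point) in metadata")
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  invisible(meta)
}
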