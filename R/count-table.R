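#' OTU count table with aligned sample metadata
#'
#' The central data structure of the package: a samples x OTUs matrix of
#' non-negative integer read counts, with optional per-sample metadata
#' describing the library-preparation design (source sample, number of pooled
#' PCR replicates, sequencing platform, site/region grouping).
#'
#' @param counts Numeric matrix (samples in rows, OTUs in columns) of
#'   non-negative integers. Row and column names are required and must be
#'   unique; they become the sample and OTU identifiers.
#' @param metadata Optional `data.frame` with one row per sample and columns
#'   `sample_id`, `source_id`, `pool_size`, `platform`, `group` and
#'   optionally `replicate_index`. Rows are matched to `counts` by
#'   `sample_id` and reordered to follow it.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer-valued matrix) and `metadata` (`data.frame` or `NULL`).
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 3L), nrow = 2,
#'             dimnames = list(c("a", "b"), c("OTU1", "OTU2")))
#' count_table(m)
#' @export
count_table <- function(counts, metadata = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0) {
      stop("counts must have sample (row) names", call. = FALSE)
    }
    rownames(counts) <- character(0)
  }
  if (is.null(colnames(counts))) {
    if (ncol(counts) > 0) {
      stop("counts must have OTU (column) names", call. = FALSE)
    }
    colnames(counts) <- character(0)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate OTU identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  check_counts(as.vector(counts), "count matrix entries")
  storage.mode(counts) <- "double"
  if (!is.null(metadata)) metadata <- validate_metadata(metadata, rownames(counts))
  structure(list(counts = counts, metadata = metadata), class = "count_table")
}

validate_metadata <- function(metadata, sample_ids) {
  required <- c("sample_id", "source_id", "pool_size", "platform", "group")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  absent <- setdiff(sample_ids, metadata$sample_id)
  if (length(absent)) {
    stop("sample(s) missing from metadata: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(metadata$sample_id, sample_ids)
  if (length(extra)) {
    warning(length(extra), " metadata row(s) without a matching sample ignored",
            call. = FALSE)
  }
  metadata <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
  pool <- suppressWarnings(as.numeric(metadata$pool_size))
  if (anyNA(pool) || any(pool < 1) || any(abs(pool - round(pool)) > 1e-8)) {
    stop("pool_size must be an integer >= 1 for every sample", call. = FALSE)
  }
  metadata$pool_size <- as.integer(round(pool))
  if (is.null(metadata$replicate_index)) {
    metadata$replicate_index <- 0L
  } else {
    metadata$replicate_index <- as.integer(metadata$replicate_index)
    if (anyNA(metadata$replicate_index) || any(metadata$replicate_index < 0)) {
      stop("replicate_index must be an integer >= 0", call. = FALSE)
    }
  }
  metadata$source_id <- as.character(metadata$source_id)
  metadata$platform <- as.character(metadata$platform)
  metadata$group <- as.character(metadata$group)
  rownames(metadata) <- NULL
  metadata
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> ", nrow(x$counts), " samples x ", ncol(x$counts),
      " OTUs; total reads ", format(sum(x$counts), big.mark = ","), "\n",
      sep = "")
  if (!is.null(x$metadata)) {
    cat("  platforms: ", paste(unique(x$metadata$platform), collapse = ", "),
        "; groups: ", paste(unique(x$metadata$group), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Sample identifiers of a count table
#' @param table A `count_table`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(table) rownames(table$counts)

#' OTU identifiers of a count table
#' @param table A `count_table`.
#' @return Character vector of OTU ids.
#' @export
otu_ids <- function(table) colnames(table$counts)

# Subset a count table to a set of samples (by id or logical/positional
# index), keeping metadata aligned. OTU columns are retained as-is.
ct_subset <- function(table, samples) {
  counts <- table$counts[samples, , drop = FALSE]
  meta <- table$metadata
  if (!is.null(meta)) meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  structure(list(counts = counts, metadata = meta), class = "count_table")
}

# Relabel samples (e.g. collapse platform-suffixed library ids to their
# underlying source sample for cross-platform matrix comparisons).
ct_relabel <- function(table, new_ids) {
  stopifnot(length(new_ids) == nrow(table$counts))
  rownames(table$counts) <- new_ids
  if (!is.null(table$metadata)) table$metadata$sample_id <- new_ids
  table
}
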