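#' Read an OTU count table from a tab-separated file
#'
#' Reads a TSV matrix of read counts with identifiers in the first row and
#' column. Both orientations used in the wild are supported via an explicit
#' flag rather than guessed. Cells must be non-negative integers; missing or
#' fractional cells are an error (silent zero-filling hides upstream
#' corruption). A first header cell of `#OTU_ID` is accepted.
#'
#' @param path Path to the file.
#' @param orientation `"samples-as-rows"` (default) or `"otus-as-rows"`,
#'   describing the file layout. The returned table always has samples as
#'   rows.
#' @param format `"tsv"` (default) or `"biom-json"` for the dense BIOM JSON
#'   dialect (requires the `biomformat` package).
#' @return A [count_table] without metadata (see [attach_metadata]).
#' @export
read_count_table <- function(path,
                             orientation = c("samples-as-rows", "otus-as-rows"),
                             format = c("tsv", "biom-json")) {
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  if (format == "biom-json") return(read_count_table_biom(path, orientation))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          quote = "", comment.char = "", row.names = NULL,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("malformed table: no columns in ", path, call. = FALSE)
  row_ids <- as.character(df[[1]])
  col_ids <- header[-1]
  if (anyDuplicated(row_ids)) {
    stop("duplicate row identifiers in ", path, ": ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(col_ids)) {
    stop("duplicate column identifiers in ", path, call. = FALSE)
  }
  body <- as.matrix(df[, -1, drop = FALSE])
  if (any(is.na(body)) || any(body == "")) {
    stop("missing cells in ", path, "; counts must be explicit", call. = FALSE)
  }
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 ncol = ncol(body)))
  if (anyNA(num)) stop("non-numeric cell(s) in ", path, call. = FALSE)
  dimnames(num) <- list(row_ids, col_ids)
  if (orientation == "otus-as-rows") num <- t(num)
  count_table(num)
}

read_count_table_biom <- function(path, orientation) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("reading BIOM files requires the 'biomformat' package", call. = FALSE)
  }
  b <- biomformat::read_biom(path)
  m <- as.matrix(biomformat::biom_data(b))  # OTUs x samples
  count_table(t(m))
}

#' Write an OTU count table to a tab-separated file
#'
#' Writes samples as rows, with a `sample_id` header cell, preserving
#' identifiers verbatim. `read_count_table()` of the result reproduces the
#' input table exactly.
#'
#' @param table A [count_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  counts <- table$counts
  header <- paste(c("sample_id", colnames(counts)), collapse = "\t")
  rows <- character(nrow(counts))
  if (nrow(counts)) {
    body <- format(counts, scientific = FALSE, trim = TRUE)
    rows <- paste(rownames(counts),
                  apply(body, 1L, paste, collapse = "\t"),
                  sep = if (ncol(counts)) "\t" else "")
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open ", path, " for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Attach sample metadata to a count table
#'
#' Joins a TSV metadata file (required columns `sample_id`, `source_id`,
#' `pool_size`, `platform`, `group`; optional `replicate_index`) to a count
#' table by `sample_id`. Every sample in the table must appear in the
#' metadata; extra metadata rows are ignored with a warning.
#'
#' @param table A [count_table].
#' @param metadata_path Path to the metadata TSV, or a `data.frame` already
#'   in memory.
#' @return The table with validated, aligned metadata.
#' @export
attach_metadata <- function(table, metadata_path) {
  stopifnot(inherits(table, "count_table"))
  meta <- if (is.data.frame(metadata_path)) {
    metadata_path
  } else {
    utils::read.delim(metadata_path, sep = "\t", header = TRUE,
                      check.names = FALSE, quote = "", comment.char = "",
                      stringsAsFactors = FALSE)
  }
  table$metadata <- validate_metadata(meta, rownames(table$counts))
  table
}

#' Write sample metadata to a tab-separated file
#' @param table A [count_table] with metadata.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  if (is.null(table$metadata)) stop("table has no metadata", call. = FALSE)
  write_tsv(table$metadata, path)
}
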