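# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a label path
#'
#' Stages of a pipeline (community draw, each PCR, each sequencing library,
#' each rarefaction draw) receive independent, stable seeds derived from one
#' master seed plus a string path, so any stage can be re-run in isolation.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric labels identifying the stage.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate `expr` under `seed` (restoring RNG state afterwards); if seed is
# NULL, evaluate with the ambient RNG.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# Validate that x is a non-negative integral count vector.
check_counts <- function(x, what = "counts") {
  if (!is.numeric(x) || anyNA(x)) {
    stop(what, " must be numeric with no missing values", call. = FALSE)
  }
  if (any(x < 0)) stop(what, " must be non-negative", call. = FALSE)
  if (any(abs(x - round(x)) > 1e-8)) {
    stop(what, " must be whole numbers (read counts)", call. = FALSE)
  }
  invisible(x)
}

# Column-bind named count vectors into a samples x OTUs matrix over the
# union of names, zero-filling absences (used when assembling simulations,
# where an OTU unobserved in a library genuinely has zero reads).
bind_count_rows <- function(vectors, sample_ids) {
  all_ids <- unique(unlist(lapply(vectors, names), use.names = FALSE))
  m <- matrix(0, nrow = length(vectors), ncol = length(all_ids),
              dimnames = list(sample_ids, all_ids))
  for (i in seq_along(vectors)) {
    v <- vectors[[i]]
    m[i, names(v)] <- as.numeric(v)
  }
  m
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
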