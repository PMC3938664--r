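#' Bray-Curtis dissimilarity between two count vectors
#'
#' Abundance-weighted dissimilarity `sum(|x - y|) / sum(x + y)`; 0 for
#' identical samples, 1 for samples with disjoint taxa.
#'
#' @param x,y Count vectors of equal length (not both all-zero).
#' @return Value in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  check_pair(x, y)
  sum(abs(x - y)) / sum(x + y)
}

#' Binary Jaccard dissimilarity between two count vectors
#'
#' `1 - |A intersect B| / |A union B|` on the presence sets; insensitive to
#' abundance.
#'
#' @param x,y Count vectors of equal length (not both all-zero).
#' @return Value in `[0, 1]`.
#' @export
jaccard_binary <- function(x, y) {
  check_pair(x, y)
  px <- x > 0
  py <- y > 0
  1 - sum(px & py) / sum(px | py)
}

#' Beta-sim presence-based turnover
#'
#' `min(b, c) / (min(b, c) + a)` where `a` is the number of shared taxa and
#' `b`, `c` the numbers unique to each sample. Discounts richness
#' differences: a community nested inside a richer one scores 0.
#'
#' @param x,y Count vectors of equal length, each with at least one present
#'   taxon.
#' @return Value in `[0, 1]`.
#' @export
beta_sim <- function(x, y) {
  check_pair(x, y)
  px <- x > 0
  py <- y > 0
  if (!any(px) || !any(py)) {
    stop("beta_sim requires at least one present taxon in each sample",
         call. = FALSE)
  }
  a <- sum(px & py)
  b <- sum(px & !py)
  cc <- sum(!px & py)
  m <- min(b, cc)
  if (m + a == 0) return(0)
  m / (m + a)
}

check_pair <- function(x, y) {
  check_counts(x, "x")
  check_counts(y, "y")
  if (length(x) != length(y)) {
    stop("count vectors must have equal length", call. = FALSE)
  }
  if (sum(x) == 0 && sum(y) == 0) {
    stop("dissimilarity undefined for two all-zero samples", call. = FALSE)
  }
  invisible(NULL)
}

beta_metric_funs <- list(
  bray_curtis = bray_curtis,
  jaccard = jaccard_binary,
  beta_sim = beta_sim
)

resolve_metric <- function(metric) {
  metric <- match.arg(metric, c("bray_curtis", "jaccard", "beta_sim"))
  beta_metric_funs[[metric]]
}

#' Pairwise dissimilarity matrix for a count table
#'
#' Optionally rarefies every sample to a common depth first (one draw per
#' sample, so the matrix is internally consistent), then computes all
#' pairwise dissimilarities with the chosen metric. Samples below `depth`
#' are dropped with a warning.
#'
#' @param table A [count_table].
#' @param metric One of `"bray_curtis"`, `"jaccard"`, `"beta_sim"`.
#' @param depth Optional rarefaction depth; `NULL` uses raw counts.
#' @param seed Integer seed for the rarefaction draws.
#' @param relative If `TRUE`, convert each (possibly rarefied) sample to
#'   relative abundances before applying the metric, so libraries of unequal
#'   size are compared compositionally. Presence-based metrics are
#'   unaffected.
#' @return Symmetric matrix with zero diagonal, class `dissimilarity_matrix`,
#'   with attributes `metric`, `depth`, `seed`.
#' @export
distance_matrix <- function(table, metric = "bray_curtis", depth = NULL,
                            seed = NULL, relative = FALSE) {
  stopifnot(inherits(table, "count_table"))
  metric <- match.arg(metric, names(beta_metric_funs))
  fun <- beta_metric_funs[[metric]]
  counts <- table$counts
  if (!is.null(depth)) {
    totals <- rowSums(counts)
    keep <- totals >= depth
    if (sum(keep) < 2L) {
      stop("fewer than 2 samples have at least ", depth, " reads", call. = FALSE)
    }
    if (any(!keep)) {
      warning(sum(!keep), " sample(s) below depth ", depth, " dropped",
              call. = FALSE)
    }
    counts <- counts[keep, , drop = FALSE]
    counts <- t(vapply(rownames(counts), function(id) {
      rarefy(counts[id, ], depth, seed = derive_seed(seed %||% 0L, "dm", id))
    }, numeric(ncol(counts))))
  }
  if (nrow(counts) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (relative && metric == "bray_curtis") {
    vals <- counts / rowSums(counts)
    pair_fun <- function(i, j) {
      x <- vals[i, ]; y <- vals[j, ]
      sum(abs(x - y)) / sum(x + y)
    }
  } else {
    pair_fun <- function(i, j) fun(counts[i, ], counts[j, ])
  }
  n <- nrow(counts)
  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- pair_fun(i, j)
    }
  }
  structure(d, metric = metric, depth = depth, seed = seed,
            class = c("dissimilarity_matrix", class(d)))
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat("<dissimilarity_matrix> ", nrow(x), " samples; metric = ",
      attr(x, "metric"),
      if (!is.null(attr(x, "depth"))) paste0("; depth = ", attr(x, "depth")),
      "\n", sep = "")
  print(unclass_dm(x), ...)
  invisible(x)
}

unclass_dm <- function(x) {
  attr(x, "metric") <- NULL
  attr(x, "depth") <- NULL
  attr(x, "seed") <- NULL
  class(x) <- "matrix"
  x
}

#' Mean dissimilarity from a focal sample to the other samples of its group
#'
#' Averages the chosen dissimilarity between a focal library and all other
#' samples sharing its `group`, excluding technical replicates of the same
#' source sample. This is the per-replication-level beta-diversity summary
#' used to ask whether PCR pooling changes a sample's apparent distance to
#' its neighbours.
#'
#' @param table A [count_table] with metadata.
#' @param focal_sample Sample identifier.
#' @param metric Dissimilarity metric (see [distance_matrix]).
#' @return Mean dissimilarity (single number).
#' @export
mean_dissimilarity_to_plot <- function(table, focal_sample,
                                       metric = "bray_curtis") {
  stopifnot(inherits(table, "count_table"))
  if (is.null(table$metadata)) stop("table has no metadata", call. = FALSE)
  fun <- resolve_metric(metric)
  meta <- table$metadata
  row <- meta[meta$sample_id == focal_sample, ]
  if (nrow(row) != 1L) stop("unknown sample: ", focal_sample, call. = FALSE)
  comparators <- meta$sample_id[meta$group == row$group &
                                meta$source_id != row$source_id]
  if (!length(comparators)) {
    stop("no comparator samples share group '", row$group, "'", call. = FALSE)
  }
  x <- table$counts[focal_sample, ]
  mean(vapply(comparators, function(id) fun(x, table$counts[id, ]), numeric(1)))
}
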