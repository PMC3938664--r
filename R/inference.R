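#' Factorial ANOVA with sequential (Type-I) sums of squares
#'
#' Least-squares ANOVA for models such as
#' `richness ~ pool_size * source_id * platform`, decomposing the response
#' sum of squares sequentially in the order the terms appear in the
#' formula. This is the classical replication model used to ask whether the
#' number of pooled PCR replicates, sample identity or sequencing platform
#' drives a diversity estimate.
#'
#' @param response Numeric response vector.
#' @param data `data.frame` of predictors aligned with `response`.
#' @param formula One-sided formula over columns of `data`, e.g.
#'   `~ pool_size * source_id * platform`.
#' @return `data.frame` of class `anova_table` with columns `term`, `df`,
#'   `sum_sq`, `mean_sq`, `f_stat`, `p_value`, and attributes `residual_df`
#'   and `residual_sum_sq`.
#' @export
factorial_anova <- function(response, data, formula) {
  if (!is.numeric(response)) stop("response must be numeric", call. = FALSE)
  if (length(response) != nrow(data)) {
    stop("response and data are not aligned", call. = FALSE)
  }
  dat <- cbind(data.frame(.response = response), data)
  f <- stats::update(stats::as.formula(formula), .response ~ .)
  fit <- stats::lm(f, data = dat)
  if (stats::df.residual(fit) < 1L) {
    stop("model consumes all degrees of freedom (n <= model df)", call. = FALSE)
  }
  co <- stats::coef(fit)
  if (anyNA(co)) {
    bad <- names(co)[is.na(co)]
    ass <- fit$assign[is.na(co)]
    labs <- attr(stats::terms(fit), "term.labels")
    stop("rank-deficient model; aliased term(s): ",
         paste(unique(labs[ass]), collapse = ", "),
         " (coefficients ", paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  labs <- attr(stats::terms(fit), "term.labels")
  if (stats::var(response) < .Machine$double.eps * max(1, mean(response)^2)) {
    # Constant response: every SS is 0 and F is 0/0; report F = 0, p = 1
    # rather than letting the F-test blow up on a perfect fit.
    dfs <- as.integer(table(factor(fit$assign[fit$assign > 0],
                                   levels = seq_along(labs))))
    out <- data.frame(term = labs, df = dfs, sum_sq = 0, mean_sq = 0,
                      f_stat = 0, p_value = 1, stringsAsFactors = FALSE)
    attr(out, "residual_df") <- stats::df.residual(fit)
    attr(out, "residual_sum_sq") <- 0
    class(out) <- c("anova_table", class(out))
    return(out)
  }
  at <- stats::anova(fit)
  terms <- rownames(at)
  resid_row <- terms == "Residuals"
  out <- data.frame(term = terms[!resid_row],
                    df = at$Df[!resid_row],
                    sum_sq = at$`Sum Sq`[!resid_row],
                    mean_sq = at$`Mean Sq`[!resid_row],
                    f_stat = at$`F value`[!resid_row],
                    p_value = at$`Pr(>F)`[!resid_row],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "residual_df") <- at$Df[resid_row]
  attr(out, "residual_sum_sq") <- at$`Sum Sq`[resid_row]
  class(out) <- c("anova_table", class(out))
  out
}

as_plain_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (inherits(d, "dissimilarity_matrix")) d <- unclass_dm(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("expected a square dissimilarity matrix", call. = FALSE)
  }
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper off-diagonal entries, with significance
#' from simultaneous row/column permutation of the second matrix. The
#' one-sided upper p-value uses the `(1 + b) / (1 + m)` estimator, so it is
#' never zero and never below `1 / (n_permutations + 1)`.
#'
#' @param d1,d2 Square dissimilarity matrices (or `dist` objects) over the
#'   same samples in the same order.
#' @param n_permutations Number of permutations (>= 99; default 999).
#' @param seed Integer seed for the permutations.
#' @return Object of class `permutation_test` with `statistic` (Mantel r),
#'   `p_value`, `n_permutations`, `seed`.
#' @export
mantel <- function(d1, d2, n_permutations = 999L, seed = 1L) {
  m1 <- as_plain_matrix(d1)
  m2 <- as_plain_matrix(d2)
  if (!all(dim(m1) == dim(m2))) stop("matrices differ in size", call. = FALSE)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop("sample identifiers of the two matrices do not match", call. = FALSE)
  }
  if (n_permutations < 99L) stop("n_permutations must be >= 99", call. = FALSE)
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  r_obs <- stats::cor(v1, m2[ut])
  n <- nrow(m1)
  b <- with_seed_opt(seed, {
    sum(vapply(seq_len(n_permutations), function(k) {
      p <- sample.int(n)
      stats::cor(v1, m2[p, p][ut]) >= r_obs
    }, logical(1)))
  })
  structure(list(statistic = r_obs, p_value = (1 + b) / (1 + n_permutations),
                 n_permutations = as.integer(n_permutations),
                 r_squared = NULL, seed = seed, test = "mantel"),
            class = "permutation_test")
}

# Pseudo-F and R^2 for a one-way partition of squared dissimilarities.
permanova_stat <- function(d2, groups) {
  n <- nrow(d2)
  a <- length(unique(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  c(f = f, r2 = ss_between / ss_total)
}

#' One-way perMANOVA on a dissimilarity matrix
#'
#' Partitions the total sum of squared dissimilarities
#' (`sum_{i<j} d_ij^2 / n`) into between- and within-group components and
#' forms the pseudo-F statistic
#' `(SS_between / (a - 1)) / (SS_within / (n - a))`. Significance comes from
#' permuting group labels, with the `(1 + b) / (1 + m)` p-value estimator.
#'
#' @param d Square dissimilarity matrix (or `dist`).
#' @param groups Group label per sample; at least 2 groups, each of size
#'   >= 2.
#' @param n_permutations Number of permutations (>= 99; default 999).
#' @param seed Integer seed.
#' @return Object of class `permutation_test` with `statistic` (pseudo-F),
#'   `p_value`, `r_squared`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_permutations = 999L, seed = 1L) {
  m <- as_plain_matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) {
    stop("groups must have one label per sample", call. = FALSE)
  }
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 members; offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  if (n_permutations < 99L) stop("n_permutations must be >= 99", call. = FALSE)
  d2 <- m^2
  obs <- permanova_stat(d2, groups)
  b <- with_seed_opt(seed, {
    sum(vapply(seq_len(n_permutations), function(k) {
      permanova_stat(d2, groups[sample.int(length(groups))])["f"] >= obs["f"]
    }, logical(1)))
  })
  structure(list(statistic = unname(obs["f"]),
                 p_value = (1 + b) / (1 + n_permutations),
                 n_permutations = as.integer(n_permutations),
                 r_squared = unname(obs["r2"]), seed = seed,
                 df_between = length(sizes) - 1L,
                 df_within = nrow(m) - length(sizes),
                 test = "permanova"),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat("<permutation_test> ", x$test, ": statistic = ",
      format(x$statistic, digits = 4),
      if (!is.null(x$r_squared)) paste0(", R2 = ", format(x$r_squared, digits = 3)),
      ", p = ", format(x$p_value, digits = 4),
      " (", x$n_permutations, " permutations)\n", sep = "")
  invisible(x)
}

#' Shared and unique OTU counts between two sequencing platforms
#'
#' Classifies every observed OTU as shared (detected in at least one sample
#' of each platform) or unique to one platform. The three counts partition
#' the set of distinct observed OTUs.
#'
#' @param table A [count_table] with metadata containing exactly two
#'   platform levels.
#' @return Object of class `overlap_result` with `shared`, `unique_a`,
#'   `unique_b`, `platforms` and `total`.
#' @export
platform_overlap <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (is.null(table$metadata)) stop("table has no metadata", call. = FALSE)
  platforms <- unique(table$metadata$platform)
  if (length(platforms) != 2L) {
    stop("table must contain exactly 2 platforms, found ",
         length(platforms), call. = FALSE)
  }
  in_platform <- function(p) {
    rows <- table$metadata$sample_id[table$metadata$platform == p]
    colSums(table$counts[rows, , drop = FALSE]) > 0
  }
  pa <- in_platform(platforms[1])
  pb <- in_platform(platforms[2])
  structure(list(shared = sum(pa & pb),
                 unique_a = sum(pa & !pb),
                 unique_b = sum(!pa & pb),
                 platforms = platforms,
                 total = sum(pa | pb)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> %d OTUs: %d shared, %d unique to %s, %d unique to %s\n",
    x$total, x$shared, x$unique_a, x$platforms[1], x$unique_b, x$platforms[2]))
  invisible(x)
}
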