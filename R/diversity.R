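#' Rarefy one sample's counts to a fixed depth
#'
#' Subsamples reads without replacement (multivariate hypergeometric), the
#' standard way of equalizing sampling effort across libraries before
#' diversity estimation. The draw is deterministic given `seed`.
#'
#' @param counts Non-negative integer vector of per-OTU read counts.
#' @param depth Target depth, `1 <= depth <= sum(counts)`.
#' @param seed Optional integer seed; `NULL` uses the ambient RNG.
#' @return Integer vector of the same length (names preserved) summing
#'   exactly to `depth`, with each entry at most the original count.
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  check_counts(counts)
  total <- sum(counts)
  if (length(depth) != 1L || depth < 1 || abs(depth - round(depth)) > 1e-8) {
    stop("depth must be a single integer >= 1", call. = FALSE)
  }
  depth <- round(depth)
  if (depth > total) {
    stop("depth (", depth, ") exceeds total reads (", total, ")", call. = FALSE)
  }
  if (depth == total) return(counts)
  out <- with_seed_opt(seed, {
    taken <- sample(rep.int(seq_along(counts), counts), depth)
    tabulate(taken, nbins = length(counts))
  })
  names(out) <- names(counts)
  out
}

#' Observed richness (number of OTUs with at least one read)
#' @param counts Count vector.
#' @return Integer count of occupied taxa.
#' @export
observed_richness <- function(counts) {
  check_counts(counts)
  sum(counts > 0)
}

#' Chao1 richness estimator
#'
#' Classic form `S_obs + F1^2 / (2 F2)` from singleton (`F1`) and doubleton
#' (`F2`) frequencies; when no doubletons are present the bias-corrected
#' fallback `S_obs + F1 (F1 - 1) / 2` is used.
#'
#' @param counts Count vector with at least one read.
#' @return Estimated richness (>= observed richness).
#' @export
chao1 <- function(counts) {
  check_counts(counts)
  if (sum(counts) == 0) stop("chao1 undefined for an all-zero sample", call. = FALSE)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Fisher's alpha of the log-series abundance model
#'
#' Solves `S = alpha * log(1 + N / alpha)` for the unique positive root,
#' where `S` is observed richness and `N` total reads. The left side is
#' strictly increasing in `alpha` (towards `N`), so bracketed root-finding
#' converges; absolute tolerance 1e-9. Only `(S, N)` matter, not how reads
#' are partitioned among taxa.
#'
#' @param counts Count vector with `N > S` (strictly).
#' @return The positive root `alpha`.
#' @export
fishers_alpha <- function(counts) {
  check_counts(counts)
  s <- sum(counts > 0)
  n <- sum(counts)
  if (s < 1) stop("fishers_alpha requires at least one observed taxon", call. = FALSE)
  if (n <= s) {
    stop("fishers_alpha undefined when total reads <= richness (N = ", n,
         ", S = ", s, ")", call. = FALSE)
  }
  f <- function(a) a * log1p(n / a) - s
  stats::uniroot(f, interval = c(1e-10, 1e12), tol = 1e-10)$root
}

#' Simpson diversity (complement form)
#'
#' `1 - sum(p_i^2)`: the probability that two reads drawn at random belong
#' to different OTUs. Invariant to rescaling all counts by a common factor.
#'
#' @param counts Count vector with at least one read.
#' @return Value in `[0, 1]`.
#' @export
simpson <- function(counts) {
  check_counts(counts)
  n <- sum(counts)
  if (n == 0) stop("simpson undefined for an all-zero sample", call. = FALSE)
  p <- counts / n
  1 - sum(p^2)
}

#' Simpson's evenness
#'
#' Inverse Simpson diversity divided by observed richness,
#' `(1 / sum(p_i^2)) / S`; equals 1 for a perfectly even community and lies
#' in `(0, 1]` always.
#'
#' @param counts Count vector with at least one read.
#' @return Value in `(0, 1]`.
#' @export
simpson_evenness <- function(counts) {
  check_counts(counts)
  n <- sum(counts)
  if (n == 0) stop("simpson_evenness undefined for an all-zero sample", call. = FALSE)
  p <- counts / n
  (1 / sum(p^2)) / sum(counts > 0)
}

alpha_metric_funs <- list(
  observed = observed_richness,
  chao1 = chao1,
  fishers_alpha = function(x) {
    if (sum(x) <= sum(x > 0)) NA_real_ else fishers_alpha(x)
  },
  simpson = simpson,
  simpson_evenness = simpson_evenness
)

#' Alpha-diversity table at a common rarefaction depth
#'
#' Rarefies each sample to `depth` and computes the requested metrics,
#' averaged over `n_rarefactions` independent draws to damp subsampling
#' noise. Samples with fewer than `depth` reads are excluded and reported
#' via the `excluded` attribute (and a message).
#'
#' @param table A [count_table].
#' @param depth Rarefaction depth (reads per sample).
#' @param seed Integer seed governing all draws.
#' @param n_rarefactions Number of independent rarefaction draws to average
#'   (default 10).
#' @param metrics Subset of
#'   `c("observed", "chao1", "fishers_alpha", "simpson", "simpson_evenness")`.
#' @return Long `data.frame` with columns `sample_id`, `metric`, `value`,
#'   `depth`; attribute `excluded` lists under-depth samples.
#' @export
alpha_table <- function(table, depth, seed = 1L, n_rarefactions = 10L,
                        metrics = names(alpha_metric_funs)) {
  stopifnot(inherits(table, "count_table"))
  metrics <- match.arg(metrics, names(alpha_metric_funs), several.ok = TRUE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  totals <- rowSums(table$counts)
  keep <- totals >= depth
  excluded <- rownames(table$counts)[!keep]
  if (!any(keep)) {
    stop("no sample has at least ", depth, " reads", call. = FALSE)
  }
  if (length(excluded)) {
    message(length(excluded), " sample(s) below depth ", depth, " excluded: ",
            paste(excluded, collapse = ", "))
  }
  ids <- rownames(table$counts)[keep]
  res <- lapply(ids, function(id) {
    x <- table$counts[id, ]
    draws <- vapply(seq_len(n_rarefactions), function(r) {
      v <- rarefy(x, depth, seed = derive_seed(seed, "alpha", id, r))
      vapply(metrics, function(m) as.numeric(alpha_metric_funs[[m]](v)),
             numeric(1))
    }, numeric(length(metrics)))
    draws <- matrix(draws, nrow = length(metrics))
    data.frame(sample_id = id, metric = metrics,
               value = rowMeans(draws), depth = as.integer(depth),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  attr(out, "excluded") <- excluded
  out
}
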