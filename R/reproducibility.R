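#' Pseudo-beta-diversity depth curve for one source sample
#'
#' Pseudo-beta-diversity is the dissimilarity between independently
#' sequenced technical replicates of the same underlying sample: apparent
#' community turnover that is purely technical. This function quantifies it
#' as a function of sequencing depth. At each depth `d`, every replicate
#' library with at least `d` reads is rarefied to `d` (`n_draws`
#' independent draws); all between-replicate pairwise dissimilarities are
#' computed for each draw, and their mean and standard deviation across
#' pairs x draws are reported. Depths that fewer than two replicates can
#' support are dropped with a warning.
#'
#' @param table A [count_table] with metadata.
#' @param source_id Identifier of the underlying sample whose technical
#'   replicates are compared.
#' @param metric Dissimilarity metric (see [distance_matrix]).
#' @param depths Integer vector of rarefaction depths.
#' @param n_draws Independent rarefaction draws per replicate per depth.
#' @param seed Integer seed.
#' @param platform Optional platform level to restrict the replicate set to;
#'   required when the source was sequenced on more than one platform.
#' @return `data.frame` of class `depth_curve` with columns `depth`,
#'   `mean_dissimilarity`, `sd`, `n_pairs` and attributes `source_id`,
#'   `metric`.
#' @export
pseudo_beta_curve <- function(table, source_id, metric = "bray_curtis",
                              depths, n_draws = 10L, seed = 1L,
                              platform = NULL) {
  stopifnot(inherits(table, "count_table"))
  reps <- replicate_set(table, source_id, platform)
  fun <- resolve_metric(metric)
  if (any(depths < 1)) stop("all depths must be >= 1", call. = FALSE)
  depths <- sort(unique(round(depths)))
  counts <- table$counts[reps, , drop = FALSE]
  totals <- rowSums(counts)
  rows <- lapply(depths, function(d) {
    ok <- which(totals >= d)
    if (length(ok) < 2L) return(NULL)
    vals <- numeric(0)
    for (draw in seq_len(n_draws)) {
      sub <- lapply(ok, function(i) {
        rarefy(counts[i, ], d,
               seed = derive_seed(seed, "pbc", source_id, d, draw, i))
      })
      for (i in seq_len(length(ok) - 1L)) {
        for (j in seq.int(i + 1L, length(ok))) {
          vals <- c(vals, fun(sub[[i]], sub[[j]]))
        }
      }
    }
    data.frame(depth = as.integer(d), mean_dissimilarity = mean(vals),
               sd = stats::sd(vals), n_pairs = choose(length(ok), 2L))
  })
  dropped <- depths[vapply(rows, is.null, logical(1))]
  if (length(dropped)) {
    warning("depth(s) ", paste(dropped, collapse = ", "),
            " supported by fewer than 2 replicates; dropped", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no depth supported by at least 2 replicates",
                         call. = FALSE)
  attr(out, "source_id") <- source_id
  attr(out, "metric") <- metric
  class(out) <- c("depth_curve", class(out))
  out
}

replicate_set <- function(table, source_id, platform = NULL) {
  if (is.null(table$metadata)) stop("table has no metadata", call. = FALSE)
  meta <- table$metadata
  sel <- meta$source_id == source_id
  if (!is.null(platform)) sel <- sel & meta$platform == platform
  reps <- meta$sample_id[sel]
  if (is.null(platform) && length(unique(meta$platform[sel])) > 1L) {
    stop("source '", source_id, "' was sequenced on multiple platforms; ",
         "specify `platform`", call. = FALSE)
  }
  if (length(reps) < 2L) {
    stop("need at least 2 technical replicates of source '", source_id, "'",
         call. = FALSE)
  }
  reps
}

#' Per-OTU detection frequency across technical replicates
#'
#' For every OTU observed in at least one replicate library of a source
#' sample, reports its mean read count across all replicates (zeros
#' included) and the proportion of replicates in which it was detected.
#'
#' @param table A [count_table] with metadata.
#' @param source_id Source sample identifier.
#' @param platform Optional platform restriction (see [pseudo_beta_curve]).
#' @return `data.frame` with columns `otu_id`, `mean_abundance`,
#'   `detection_proportion`, `n_replicates`.
#' @export
detection_frequency <- function(table, source_id, platform = NULL) {
  stopifnot(inherits(table, "count_table"))
  reps <- replicate_set(table, source_id, platform)
  counts <- table$counts[reps, , drop = FALSE]
  present <- colSums(counts) > 0
  counts <- counts[, present, drop = FALSE]
  data.frame(otu_id = colnames(counts),
             mean_abundance = colMeans(counts),
             detection_proportion = colMeans(counts > 0),
             n_replicates = length(reps),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Logistic model of detection frequency vs. log10 mean abundance
#'
#' Fits a binomial GLM (logit link, trials = number of replicates) of
#' detection frequency on `log10(mean abundance)`. Two conventions for
#' zero mean abundance are supported before the log transform: replace
#' zeros by half the minimum observed positive value (`"half-min"`), or by
#' a fixed 0.1 (`"fixed-0.1"`). The likelihood-ratio chi-square compares
#' the fitted model against the intercept-only model.
#'
#' @param records Output of [detection_frequency] (or any `data.frame` with
#'   `mean_abundance`, `detection_proportion`, `n_replicates`).
#' @param zero_policy `"half-min"` (default) or `"fixed-0.1"`.
#' @return Object of class `logistic_fit` with elements `intercept`,
#'   `slope` (per log10 read unit), `se_intercept`, `se_slope`, `lr_chi2`,
#'   `converged`.
#' @export
fit_detection_model <- function(records, zero_policy = c("half-min", "fixed-0.1")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(all(c("mean_abundance", "detection_proportion", "n_replicates")
                %in% names(records)))
  mu <- records$mean_abundance
  if (any(mu < 0)) stop("mean_abundance must be >= 0", call. = FALSE)
  if (any(mu == 0)) {
    fill <- if (zero_policy == "half-min") {
      if (!any(mu > 0)) stop("all abundances zero; cannot apply half-min",
                             call. = FALSE)
      min(mu[mu > 0]) / 2
    } else 0.1
    mu[mu == 0] <- fill
  }
  x <- log10(mu)
  if (length(unique(x)) < 2L) {
    stop("need at least 2 distinct abundance values", call. = FALSE)
  }
  n <- records$n_replicates
  succ <- round(records$detection_proportion * n)
  if (any(abs(records$detection_proportion * n - succ) > 1e-6)) {
    stop("detection_proportion x n_replicates must be integral", call. = FALSE)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(cbind(succ, n - succ) ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  converged <- isTRUE(fit$converged) && !separation
  if (!converged) {
    warning("logistic fit did not converge cleanly (separation or iteration ",
            "limit); estimates capped", call. = FALSE)
  }
  cap <- function(v) pmin(pmax(v, -1e6), 1e6)
  structure(list(intercept = cap(unname(co[1])), slope = cap(unname(co[2])),
                 se_intercept = unname(se[1]), se_slope = unname(se[2]),
                 lr_chi2 = max(0, fit$null.deviance - fit$deviance),
                 converged = converged, zero_policy = zero_policy,
                 n_records = length(x)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> detection ~ log10(mean abundance)\n",
      sprintf("  intercept %.4f (SE %.4f), slope %.4f (SE %.4f)\n",
              x$intercept, x$se_intercept, x$slope, x$se_slope),
      sprintf("  LR chi-square %.2f; converged: %s; zeros: %s\n",
              x$lr_chi2, x$converged, x$zero_policy), sep = "")
  invisible(x)
}

#' Poisson closed form for detection probability
#'
#' If reads of an OTU arrive as Poisson with mean `mu` per library, the
#' probability of detecting it at least once is `1 - exp(-mu)`. Used as the
#' analytic reference for the simulator's detection behaviour (an OTU with
#' mean abundance 10 is detected with probability 0.99995...).
#'
#' @param mu Mean read count (>= 0); vectorized.
#' @return Detection probability in `[0, 1)`.
#' @export
detection_probability_closed_form <- function(mu) {
  if (any(mu < 0)) stop("mu must be >= 0", call. = FALSE)
  -expm1(-mu)
}

#' Abundance concordance between two technical replicates
#'
#' Compares per-OTU read counts between two libraries of the same source
#' sample on the `log10(x + 1)` scale, over OTUs present in at least one of
#' the two. Reports the ordinary least-squares slope and intercept of
#' `replicate_b` on `replicate_a` and their Pearson correlation. A slope
#' near 1 with high `r` means pooling level (or re-sequencing) preserved
#' relative abundances.
#'
#' @param table A [count_table] with metadata.
#' @param source_id Shared source sample of the two libraries.
#' @param replicate_a,replicate_b Sample identifiers.
#' @return Object of class `concordance_result` with `slope`, `intercept`,
#'   `pearson_r`, `n_otus`.
#' @export
abundance_concordance <- function(table, source_id, replicate_a, replicate_b) {
  stopifnot(inherits(table, "count_table"))
  if (is.null(table$metadata)) stop("table has no metadata", call. = FALSE)
  meta <- table$metadata
  for (id in c(replicate_a, replicate_b)) {
    row <- meta[meta$sample_id == id, ]
    if (nrow(row) != 1L) stop("unknown sample: ", id, call. = FALSE)
    if (row$source_id != source_id) {
      stop("sample '", id, "' does not derive from source '", source_id, "'",
           call. = FALSE)
    }
  }
  a <- table$counts[replicate_a, ]
  b <- table$counts[replicate_b, ]
  sel <- a > 0 | b > 0
  if (sum(sel) < 3L) {
    stop("fewer than 3 OTUs present in either replicate", call. = FALSE)
  }
  la <- log10(a[sel] + 1)
  lb <- log10(b[sel] + 1)
  fit <- stats::lm(lb ~ la)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = stats::cor(la, lb),
                 n_otus = sum(sel)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "<concordance_result> slope %.4f, intercept %.4f, r %.4f (%d OTUs)\n",
    x$slope, x$intercept, x$pearson_r, x$n_otus))
  invisible(x)
}
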