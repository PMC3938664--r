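# End-to-end study drivers: simulate a design, run the full analysis, and
# write TSV outputs plus a run manifest. Given a fixed master seed all data
# outputs are byte-identical across runs (the manifest carries a wall-clock
# timestamp and is the one non-reproducible file).

write_manifest <- function(out_dir, command, config) {
  manifest <- list(
    command = command,
    config_hash = format(derive_seed(0L, paste(
      utils::capture.output(utils::str(unclass(config))), collapse = "\n"))),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ampliconrep")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

resolve_config <- function(config) {
  if (is.character(config)) config <- sim_config_from_json(config)
  stopifnot(inherits(config, "sim_config"))
  config
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

# Rarefy every sample of a platform to that platform's depth (one seeded
# draw each), dropping under-depth samples; returns a count_table.
rarefy_platform_table <- function(table, platform, depth, seed) {
  sub <- ct_subset(table, table$metadata$platform == platform)
  totals <- rowSums(sub$counts)
  sub <- ct_subset(sub, totals >= depth)
  if (nrow(sub$counts) < 1L) {
    stop("no ", platform, " sample reaches depth ", depth, call. = FALSE)
  }
  sub$counts <- t(vapply(rownames(sub$counts), function(id) {
    rarefy(sub$counts[id, ], depth, seed = derive_seed(seed, "rt", id))
  }, numeric(ncol(sub$counts))))
  sub
}

#' Run the pooled-PCR replication study end to end
#'
#' Simulates the replication design, then computes: per-platform
#' alpha-diversity at the configured rarefaction depths; the factorial
#' ANOVA `metric ~ pool_size * source_id * platform` for every
#' alpha-diversity metric; Bray-Curtis and Jaccard pseudo-beta-diversity
#' depth curves per source and platform; per-OTU detection records with the
#' logistic detection model per platform; and abundance concordance between
#' the smallest and largest pooling levels. All results are written as TSV
#' files together with a `manifest.json`.
#'
#' @param config A [sim_config] or path to a JSON configuration.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the in-memory results.
#' @export
run_replication_study <- function(config, out_dir) {
  config <- resolve_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  platforms <- names(config$depth_by_platform)

  tab <- stage("simulate", simulate_experiment(config, "replication"))
  write_count_table(tab, file.path(out_dir, "table.tsv"))
  write_metadata(tab, file.path(out_dir, "metadata.tsv"))

  alpha <- stage("alpha", {
    do.call(rbind, lapply(platforms, function(p) {
      depth <- config$rarefy_depth_replication[[p]]
      sub <- ct_subset(tab, tab$metadata$platform == p)
      a <- suppressMessages(
        alpha_table(sub, depth, seed = derive_seed(config$seed, "alpha", p)))
      a$platform <- p
      a
    }))
  })
  write_tsv(alpha, file.path(out_dir, "alpha.tsv"))

  anova_tab <- stage("anova", {
    do.call(rbind, lapply(unique(alpha$metric), function(m) {
      sub <- alpha[alpha$metric == m, ]
      md <- tab$metadata[match(sub$sample_id, tab$metadata$sample_id), ]
      at <- factorial_anova(sub$value,
                            data.frame(pool_size = md$pool_size,
                                       source_id = factor(md$source_id),
                                       platform = factor(md$platform)),
                            ~ pool_size * source_id * platform)
      cbind(metric = m, as.data.frame(at),
            residual_df = attr(at, "residual_df"),
            residual_sum_sq = attr(at, "residual_sum_sq"))
    }))
  })
  write_tsv(anova_tab, file.path(out_dir, "anova.tsv"))

  curves <- stage("pseudo-beta", {
    grids <- list()
    for (p in platforms) {
      d <- config$depth_by_platform[[p]]
      dmax <- if (length(d) == 2L) d[2] else d
      grids[[p]] <- if (dmax <= 2000) {
        seq(50L, min(1000L, dmax), by = 50L)
      } else {
        ds <- c(100L, 250L, 500L, 1000L, 2500L, 5000L, 10000L, 20000L,
                40000L, 80000L)
        ds[ds <= dmax]
      }
    }
    out <- list()
    for (p in platforms) {
      for (src in unique(tab$metadata$source_id)) {
        for (m in c("bray_curtis", "jaccard")) {
          cur <- suppressWarnings(
            pseudo_beta_curve(tab, src, metric = m, depths = grids[[p]],
                              n_draws = 10L,
                              seed = derive_seed(config$seed, "curve", p, src, m),
                              platform = p))
          cur <- as.data.frame(cur)
          cur$source_id <- src
          cur$platform <- p
          cur$metric <- m
          out[[paste(p, src, m)]] <- cur
        }
      }
    }
    do.call(rbind, out)
  })
  rownames(curves) <- NULL
  write_tsv(curves, file.path(out_dir, "curves.tsv"))

  detect <- stage("detection", {
    recs <- list()
    fits <- list()
    for (p in platforms) {
      depth <- config$rarefy_depth_replication[[p]]
      rt <- rarefy_platform_table(tab, p, depth,
                                  derive_seed(config$seed, "detect", p))
      pr <- do.call(rbind, lapply(unique(rt$metadata$source_id), function(src) {
        r <- detection_frequency(rt, src, platform = p)
        r$source_id <- src
        r
      }))
      pr$platform <- p
      recs[[p]] <- pr
      fit <- fit_detection_model(pr, zero_policy = "half-min")
      fits[[p]] <- data.frame(platform = p, intercept = fit$intercept,
                              slope = fit$slope,
                              se_intercept = fit$se_intercept,
                              se_slope = fit$se_slope, lr_chi2 = fit$lr_chi2,
                              converged = fit$converged,
                              n_records = fit$n_records)
    }
    list(records = do.call(rbind, recs), fits = do.call(rbind, fits))
  })
  rownames(detect$records) <- rownames(detect$fits) <- NULL
  write_tsv(detect$records, file.path(out_dir, "detection.tsv"))
  write_tsv(detect$fits, file.path(out_dir, "logistic.tsv"))

  conc <- stage("concordance", {
    kmin <- min(config$pool_sizes)
    kmax <- max(config$pool_sizes)
    rows <- list()
    for (p in platforms) {
      for (src in unique(tab$metadata$source_id)) {
        a <- paste(src, paste0("k", kmin), p, sep = "_")
        b <- paste(src, paste0("k", kmax), p, sep = "_")
        cr <- abundance_concordance(tab, src, a, b)
        rows[[paste(p, src)]] <- data.frame(
          platform = p, source_id = src, pool_a = kmin, pool_b = kmax,
          slope = cr$slope, intercept = cr$intercept,
          pearson_r = cr$pearson_r, n_otus = cr$n_otus)
      }
    }
    do.call(rbind, rows)
  })
  rownames(conc) <- NULL
  write_tsv(conc, file.path(out_dir, "concordance.tsv"))

  manifest <- write_manifest(out_dir, "run_replication_study", config)
  invisible(list(table = tab, alpha = alpha, anova = anova_tab,
                 curves = curves, detection = detect$records,
                 logistic = detect$fits, concordance = conc,
                 manifest = manifest))
}

#' Run the cross-platform comparison study end to end
#'
#' Simulates the cross-platform design (every sample sequenced on both
#' platforms), then computes: per-platform alpha-diversity at the
#' configured depths; cross-platform regressions of each richness metric
#' (second platform on first); per-platform distance matrices for
#' Bray-Curtis, Jaccard and beta-sim with Mantel tests between platforms;
#' one-way perMANOVA for sequencing platform and for region on the combined
#' compositional distance matrix; and shared/unique OTU accounting between
#' platforms. Results are written as TSV files plus a `manifest.json`.
#'
#' @param config A [sim_config] or path to a JSON configuration.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the in-memory results.
#' @export
run_platform_study <- function(config, out_dir) {
  config <- resolve_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  platforms <- names(config$depth_by_platform)
  if (length(platforms) != 2L) {
    stop("the cross-platform study needs exactly 2 platforms", call. = FALSE)
  }
  metrics <- c("bray_curtis", "jaccard", "beta_sim")

  tab <- stage("simulate", simulate_experiment(config, "cross_platform"))
  write_count_table(tab, file.path(out_dir, "table.tsv"))
  write_metadata(tab, file.path(out_dir, "metadata.tsv"))

  alpha <- stage("alpha", {
    do.call(rbind, lapply(platforms, function(p) {
      depth <- config$rarefy_depth_cross[[p]]
      sub <- ct_subset(tab, tab$metadata$platform == p)
      a <- suppressMessages(alpha_table(
        sub, depth, seed = derive_seed(config$seed, "xalpha", p),
        metrics = c("observed", "chao1", "fishers_alpha")))
      a$platform <- p
      a$source_id <- tab$metadata$source_id[match(a$sample_id,
                                                  tab$metadata$sample_id)]
      a
    }))
  })
  write_tsv(alpha, file.path(out_dir, "alpha.tsv"))

  reg <- stage("alpha-regression", {
    do.call(rbind, lapply(unique(alpha$metric), function(m) {
      w <- alpha[alpha$metric == m, ]
      x <- w$value[w$platform == platforms[1]]
      names(x) <- w$source_id[w$platform == platforms[1]]
      y <- w$value[w$platform == platforms[2]]
      names(y) <- w$source_id[w$platform == platforms[2]]
      shared <- intersect(names(x), names(y))
      fit <- summary(stats::lm(y[shared] ~ x[shared]))
      data.frame(metric = m,
                 slope = fit$coefficients[2, 1],
                 se_slope = fit$coefficients[2, 2],
                 r_squared = fit$r.squared,
                 p_value = fit$coefficients[2, 4],
                 n = length(shared))
    }))
  })
  rownames(reg) <- NULL
  write_tsv(reg, file.path(out_dir, "alpha_regression.tsv"))

  # Per-platform rarefied tables, relabelled by source sample so the two
  # platforms' matrices share identifiers.
  rare <- lapply(platforms, function(p) {
    rt <- rarefy_platform_table(tab, p, config$rarefy_depth_cross[[p]],
                                derive_seed(config$seed, "xrare", p))
    ct_relabel(rt, rt$metadata$source_id)
  })
  names(rare) <- platforms
  shared_ids <- Reduce(intersect, lapply(rare, function(t) sample_ids(t)))
  rare <- lapply(rare, function(t) ct_subset(t, shared_ids))

  dms <- stage("distance", {
    out <- list()
    for (p in platforms) {
      for (m in metrics) {
        dm <- distance_matrix(rare[[p]], metric = m)
        out[[paste(p, m, sep = ".")]] <- dm
        utils::write.table(
          cbind(sample_id = rownames(dm), format(unclass_dm(dm), digits = 10)),
          file.path(out_dir, paste0("distance_", p, "_", m, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    out
  })

  mant <- stage("mantel", {
    do.call(rbind, lapply(metrics, function(m) {
      mt <- mantel(dms[[paste(platforms[1], m, sep = ".")]],
                   dms[[paste(platforms[2], m, sep = ".")]],
                   n_permutations = 999L,
                   seed = derive_seed(config$seed, "mantel", m))
      data.frame(metric = m, mantel_r = mt$statistic, p_value = mt$p_value,
                 n_permutations = mt$n_permutations, n_samples = length(shared_ids))
    }))
  })
  rownames(mant) <- NULL
  write_tsv(mant, file.path(out_dir, "mantel.tsv"))

  perma <- stage("permanova", {
    combined <- do.call(rbind, lapply(platforms, function(p) {
      t <- rare[[p]]
      rownames(t$counts) <- paste(sample_ids(t), p, sep = "|")
      t$counts
    }))
    meta_src <- sub("\\|.*$", "", rownames(combined))
    meta_platform <- sub("^.*\\|", "", rownames(combined))
    meta_group <- tab$metadata$group[match(meta_src, tab$metadata$source_id)]
    ctab <- count_table(combined)
    rows <- list()
    for (m in metrics) {
      dm <- distance_matrix(ctab, metric = m, relative = TRUE)
      for (fac in c("platform", "group")) {
        labels <- if (fac == "platform") meta_platform else meta_group
        pt <- permanova(dm, labels, n_permutations = 999L,
                        seed = derive_seed(config$seed, "perma", m, fac))
        rows[[paste(m, fac)]] <- data.frame(
          metric = m, factor = fac, pseudo_f = pt$statistic,
          r_squared = pt$r_squared, p_value = pt$p_value,
          df_between = pt$df_between, df_within = pt$df_within)
      }
    }
    do.call(rbind, rows)
  })
  rownames(perma) <- NULL
  write_tsv(perma, file.path(out_dir, "permanova.tsv"))

  overlap <- stage("overlap", platform_overlap(tab))
  write_tsv(data.frame(platform_a = overlap$platforms[1],
                       platform_b = overlap$platforms[2],
                       shared = overlap$shared, unique_a = overlap$unique_a,
                       unique_b = overlap$unique_b, total = overlap$total),
            file.path(out_dir, "overlap.tsv"))

  manifest <- write_manifest(out_dir, "run_platform_study", config)
  invisible(list(table = tab, alpha = alpha, alpha_regression = reg,
                 distances = dms, mantel = mant, permanova = perma,
                 overlap = overlap, manifest = manifest))
}
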