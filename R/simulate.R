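#' Configuration of the library-preparation generative model
#'
#' Collects every parameter of the simulator: the shape of the true
#' community, the PCR amplification model, replicate pooling, and
#' platform-specific sequencing. Defaults describe a pooled-PCR replication
#' study of diverse soil communities sequenced on a low-throughput
#' pyrosequencing-style platform ("p454", ~500-1,800 reads/sample) and a
#' high-throughput short-read platform ("illumina", ~38,000-92,000
#' reads/sample).
#'
#' @param n_taxa Number of taxa in the regional pool (default 200). The
#'   default community (with the default lognormal model) keeps the rarest
#'   resident taxa above the template-sampling resolution of one PCR, the
#'   regime in which sequencing-depth noise, not PCR sampling, limits
#'   inference.
#' @param abundance_model List describing the species-abundance
#'   distribution: `list(type = "lognormal", meanlog, sdlog)` or
#'   `list(type = "geometric", theta)`.
#' @param template_molecules DNA template molecules entering one PCR
#'   (default 10000).
#' @param cycles Total PCR cycles (default 30).
#' @param stochastic_cycles Early cycles simulated as exact binomial
#'   branching (default 5); the remaining cycles are applied as
#'   deterministic per-taxon growth. Compositional stochasticity is
#'   concentrated in early cycles, and full 30-cycle branching would
#'   overflow integer ranges.
#' @param efficiency_mean Mean per-cycle amplification efficiency in (0, 1]
#'   (default 0.85).
#' @param efficiency_sd_taxon SD of the per-taxon (primer-binding)
#'   efficiency offset; redrawn per platform (different primers).
#' @param efficiency_sd_reaction SD of the per-reaction, per-taxon
#'   efficiency offset (run-to-run PCR stochasticity).
#' @param pool_sizes Numbers of pooled PCR replicates per treatment
#'   (default `c(1, 2, 4, 8, 16)`).
#' @param depth_by_platform Named list: per-platform sequencing depth,
#'   either a single fixed value or a `c(min, max)` range sampled uniformly
#'   per library.
#' @param rarefy_depth_replication,rarefy_depth_cross Named vectors of
#'   per-platform rarefaction depths used by the study drivers (defaults
#'   500/38000 for the replication design and 1000/40000 for the
#'   cross-platform design).
#' @param platform_detectable_fraction Named vector: fraction of taxa each
#'   platform's primers can amplify (default 1 for both).
#' @param error_rate Per-read probability that a read becomes a spurious
#'   OTU through sequencing/clustering error (default 0.005).
#' @param group_concentration Dirichlet concentration controlling
#'   within-group community similarity in the cross-platform design
#'   (default 200; larger = more similar samples within a region).
#' @param n_sources Number of source soil samples in the replication design
#'   (default 3).
#' @param n_groups,sites_per_group,samples_per_site Shape of the
#'   cross-platform design (default 3 regions x 2 sites x 10 samples).
#' @param seed Master seed; every stage derives stable sub-seeds from it.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_taxa = 200L,
                       abundance_model = list(type = "lognormal",
                                              meanlog = 0, sdlog = 1.2),
                       template_molecules = 10000L,
                       cycles = 30L,
                       stochastic_cycles = 5L,
                       efficiency_mean = 0.85,
                       efficiency_sd_taxon = 0.05,
                       efficiency_sd_reaction = 0.005,
                       pool_sizes = c(1L, 2L, 4L, 8L, 16L),
                       depth_by_platform = list(p454 = c(500L, 1800L),
                                                illumina = c(38000L, 92000L)),
                       rarefy_depth_replication = c(p454 = 500L,
                                                    illumina = 38000L),
                       rarefy_depth_cross = c(p454 = 1000L,
                                              illumina = 40000L),
                       platform_detectable_fraction = c(p454 = 1,
                                                        illumina = 1),
                       error_rate = 0.005,
                       group_concentration = 200,
                       n_sources = 3L,
                       n_groups = 3L,
                       sites_per_group = 2L,
                       samples_per_site = 10L,
                       seed = 1L) {
  cfg <- list(n_taxa = as.integer(n_taxa), abundance_model = abundance_model,
              template_molecules = as.integer(template_molecules),
              cycles = as.integer(cycles),
              stochastic_cycles = as.integer(stochastic_cycles),
              efficiency_mean = efficiency_mean,
              efficiency_sd_taxon = efficiency_sd_taxon,
              efficiency_sd_reaction = efficiency_sd_reaction,
              pool_sizes = as.integer(pool_sizes),
              depth_by_platform = lapply(depth_by_platform, as.numeric),
              rarefy_depth_replication = unlist(rarefy_depth_replication),
              rarefy_depth_cross = unlist(rarefy_depth_cross),
              platform_detectable_fraction = unlist(platform_detectable_fraction),
              error_rate = error_rate,
              group_concentration = group_concentration,
              n_sources = as.integer(n_sources),
              n_groups = as.integer(n_groups),
              sites_per_group = as.integer(sites_per_group),
              samples_per_site = as.integer(samples_per_site),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_taxa >= 1L, cfg$template_molecules >= 1L,
            cfg$cycles >= 1L, cfg$stochastic_cycles >= 0L)
  if (cfg$stochastic_cycles > cfg$cycles) {
    stop("stochastic_cycles must be <= cycles", call. = FALSE)
  }
  if (cfg$efficiency_mean <= 0 || cfg$efficiency_mean > 1) {
    stop("efficiency_mean must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$efficiency_sd_taxon < 0 || cfg$efficiency_sd_reaction < 0) {
    stop("efficiency SDs must be >= 0", call. = FALSE)
  }
  if (cfg$error_rate < 0 || cfg$error_rate >= 1) {
    stop("error_rate must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$group_concentration <= 0) {
    stop("group_concentration must be > 0", call. = FALSE)
  }
  if (any(cfg$pool_sizes < 1L)) stop("pool sizes must be >= 1", call. = FALSE)
  if (is.null(names(cfg$depth_by_platform)) ||
      any(!nzchar(names(cfg$depth_by_platform)))) {
    stop("depth_by_platform must be a named list of platforms", call. = FALSE)
  }
  for (d in cfg$depth_by_platform) {
    if (!length(d) %in% 1:2 || any(d < 1)) {
      stop("each depth_by_platform entry must be a depth or c(min, max)",
           call. = FALSE)
    }
  }
  frac <- cfg$platform_detectable_fraction
  if (any(frac <= 0 | frac > 1)) {
    stop("platform_detectable_fraction must lie in (0, 1]", call. = FALSE)
  }
  type <- cfg$abundance_model$type %||% ""
  if (!type %in% c("lognormal", "geometric")) {
    stop("abundance_model$type must be 'lognormal' or 'geometric'",
         call. = FALSE)
  }
  if (type == "lognormal" &&
      (is.null(cfg$abundance_model$sdlog) || cfg$abundance_model$sdlog < 0)) {
    stop("lognormal abundance model needs sdlog >= 0", call. = FALSE)
  }
  if (type == "geometric") {
    th <- cfg$abundance_model$theta %||% NA_real_
    if (is.na(th) || th <= 0 || th >= 1) {
      stop("geometric abundance model needs theta in (0, 1)", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Read a simulation configuration from a JSON file
#'
#' The JSON object mirrors [sim_config] field names; missing fields take
#' their defaults.
#'
#' @param path Path to a JSON file.
#' @return A `sim_config`.
#' @export
sim_config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$depth_by_platform)) {
    raw$depth_by_platform <- as.list(raw$depth_by_platform)
  }
  do.call(sim_config, raw)
}

#' Write a simulation configuration to a JSON file
#'
#' Platform-keyed fields are serialized as JSON objects so that
#' [sim_config_from_json] reproduces the configuration exactly.
#'
#' @param config A [sim_config].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
sim_config_to_json <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  for (field in c("rarefy_depth_replication", "rarefy_depth_cross",
                  "platform_detectable_fraction")) {
    out[[field]] <- as.list(out[[field]])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

community_profile <- function(otu_ids, abundance) {
  stopifnot(length(otu_ids) == length(abundance))
  if (any(abundance < 0)) stop("abundances must be >= 0", call. = FALSE)
  s <- sum(abundance)
  if (abs(s - 1) > 1e-12) abundance <- abundance / s
  structure(list(otu_ids = otu_ids, abundance = abundance),
            class = "community_profile")
}

#' Draw a true community profile from the configured abundance model
#'
#' Abundances are drawn from the species-abundance distribution, sorted in
#' decreasing order and normalized to sum to one. Deterministic given the
#' seed.
#'
#' @param config A [sim_config].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return Object of class `community_profile` with `otu_ids` and
#'   `abundance`.
#' @export
make_community <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_taxa
  am <- config$abundance_model
  ab <- with_seed_opt(seed, {
    if (am$type == "lognormal") {
      stats::rlnorm(n, meanlog = am$meanlog %||% 0, sdlog = am$sdlog)
    } else {
      am$theta * (1 - am$theta)^(seq_len(n) - 1)
    }
  })
  ab <- sort(ab, decreasing = TRUE)
  community_profile(sprintf("OTU_%04d", seq_len(n)), ab / sum(ab))
}

#' @export
print.community_profile <- function(x, ...) {
  cat("<community_profile> ", length(x$otu_ids), " taxa; top abundance ",
      format(max(x$abundance), digits = 3), "\n", sep = "")
  invisible(x)
}

# Per-taxon platform efficiency offsets (primer-binding bias); shared by
# every reaction of an experiment on that platform.
taxon_efficiency_offsets <- function(config, platform) {
  with_seed_opt(derive_seed(config$seed, "taxon_eff", platform), {
    stats::rnorm(config$n_taxa, 0, config$efficiency_sd_taxon)
  })
}

# Realized per-taxon efficiencies for one reaction: mean + taxon offset +
# reaction offset, clamped to [0.01, 1].
reaction_efficiencies <- function(config, taxon_offsets, seed) {
  eff <- with_seed_opt(seed, {
    config$efficiency_mean + taxon_offsets +
      stats::rnorm(length(taxon_offsets), 0, config$efficiency_sd_reaction)
  })
  pmin(pmax(eff, 0.01), 1)
}

#' Simulate one PCR amplification of a community
#'
#' Template molecules are drawn multinomially from the community profile;
#' for `stochastic_cycles` rounds each taxon's molecule count grows by an
#' exact binomial draw with its per-reaction efficiency; the remaining
#' cycles are applied deterministically as multiplication by
#' `(1 + e_i)^(cycles - stochastic_cycles)`. The product is returned as a
#' renormalized profile. A taxon absent from the template draw stays
#' absent.
#'
#' @param community A `community_profile`.
#' @param config A [sim_config].
#' @param efficiencies Per-taxon efficiency vector in (0, 1].
#' @param seed Integer seed.
#' @return A `community_profile` of amplicon proportions.
#' @export
simulate_pcr <- function(community, config, efficiencies, seed = NULL) {
  stopifnot(inherits(community, "community_profile"),
            inherits(config, "sim_config"))
  if (config$template_molecules < 1L) {
    stop("template_molecules must be >= 1", call. = FALSE)
  }
  if (length(efficiencies) != length(community$abundance)) {
    stop("need one efficiency per taxon", call. = FALSE)
  }
  if (any(efficiencies <= 0 | efficiencies > 1)) {
    stop("efficiencies must lie in (0, 1]", call. = FALSE)
  }
  n <- with_seed_opt(seed, {
    x <- as.numeric(stats::rmultinom(1, config$template_molecules,
                                     community$abundance))
    for (t in seq_len(config$stochastic_cycles)) {
      x <- x + stats::rbinom(length(x), x, efficiencies)
    }
    x
  })
  n <- n * (1 + efficiencies)^(config$cycles - config$stochastic_cycles)
  community_profile(community$otu_ids, n / sum(n))
}

#' Pool PCR replicate profiles
#'
#' Weighted average of amplicon profiles (equal weights by default),
#' renormalized; models combining several independent reactions of the same
#' sample before sequencing.
#'
#' @param profiles List of `community_profile`s over the same taxa.
#' @param weights Optional non-negative weights, one per profile.
#' @return A pooled `community_profile`.
#' @export
pool_replicates <- function(profiles, weights = NULL) {
  if (!length(profiles)) stop("need at least one profile", call. = FALSE)
  ids <- profiles[[1]]$otu_ids
  for (p in profiles) {
    if (!identical(p$otu_ids, ids)) {
      stop("profiles cover different taxa; cannot pool", call. = FALSE)
    }
  }
  w <- weights %||% rep(1, length(profiles))
  if (length(w) != length(profiles) || any(w < 0) || sum(w) == 0) {
    stop("weights must be non-negative with positive sum", call. = FALSE)
  }
  ab <- Reduce(`+`, Map(function(p, wi) wi * p$abundance, profiles, w))
  community_profile(ids, ab / sum(ab))
}

#' Sequence a pooled amplicon profile on a platform
#'
#' Masks taxa the platform's primers cannot amplify (a seeded,
#' platform-stable subset when `platform_detectable_fraction < 1`),
#' renormalizes, draws reads multinomially at the platform depth, then
#' converts each read independently into a spurious-OTU read with
#' probability `error_rate`. Spurious reads are labelled
#' `ERR_<parent>_<j>` with `j` drawn from a geometric collision
#' distribution, so repeated errors can hit the same spurious OTU and some
#' noise OTUs recur across replicate libraries. Counts always sum exactly
#' to the depth.
#'
#' @param profile A `community_profile`.
#' @param platform Platform name (a key of `config$depth_by_platform`).
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @param depth Optional fixed depth overriding the platform setting.
#' @return Named count vector: the profile's taxa plus any spurious OTU
#'   columns.
#' @export
sequence_sample <- function(profile, platform, config, seed = NULL,
                            depth = NULL) {
  stopifnot(inherits(profile, "community_profile"),
            inherits(config, "sim_config"))
  spec_d <- config$depth_by_platform[[platform]]
  if (is.null(spec_d)) stop("unknown platform: ", platform, call. = FALSE)
  ab <- profile$abundance
  frac <- config$platform_detectable_fraction[[platform]] %||% 1
  if (frac < 1) {
    n_det <- max(1L, round(frac * length(ab)))
    detectable <- with_seed_opt(derive_seed(config$seed, "mask", platform), {
      sample.int(length(ab), n_det)
    })
    masked <- ab
    masked[-detectable] <- 0
    ab <- masked
  }
  if (sum(ab) == 0) {
    stop("no detectable taxa with positive abundance on platform ", platform,
         call. = FALSE)
  }
  with_seed_opt(seed, {
    d <- depth %||% (if (length(spec_d) == 1L) spec_d else
                       sample(seq.int(spec_d[1], spec_d[2]), 1L))
    if (d < 1) stop("sequencing depth must be >= 1", call. = FALSE)
    reads <- as.numeric(stats::rmultinom(1, d, ab / sum(ab)))
    names(reads) <- profile$otu_ids
    n_err <- if (config$error_rate > 0) stats::rbinom(1, d, config$error_rate) else 0L
    if (n_err > 0) {
      pool <- rep.int(seq_along(reads), reads)
      parents <- pool[sample.int(length(pool), n_err)]
      reads <- reads - tabulate(parents, nbins = length(reads))
      j <- stats::rgeom(n_err, 0.5) + 1L
      spur_tab <- table(paste0("ERR_", profile$otu_ids[parents], "_", j))
      spur <- as.numeric(spur_tab)
      names(spur) <- names(spur_tab)
      reads <- c(reads, spur)
    }
    reads
  })
}

#' Simulate a full sequencing experiment
#'
#' Two designs are supported. `"replication"` reproduces a pooled-PCR
#' replication study: for each source community, each pooling level and
#' each platform, `pool_size` independent PCRs are simulated, pooled and
#' sequenced once, giving `n_sources x length(pool_sizes) x n_platforms`
#' libraries. `"cross_platform"` simulates a multi-region survey
#' (`n_groups` regions x `sites_per_group` sites x `samples_per_site`
#' samples) in which every sample is amplified and sequenced on both
#' platforms; regional community structure is induced by drawing each
#' region's profile independently from the abundance model and sampling
#' site and sample profiles from Dirichlet distributions centred on it.
#'
#' @param config A [sim_config].
#' @param design `"replication"` or `"cross_platform"`.
#' @return A [count_table] with populated metadata (`source_id`,
#'   `pool_size`, `platform`, `group`, `replicate_index`).
#' @export
simulate_experiment <- function(config, design = c("replication",
                                                   "cross_platform")) {
  stopifnot(inherits(config, "sim_config"))
  design <- match.arg(design)
  if (design == "replication") simulate_replication(config)
  else simulate_cross_platform(config)
}

simulate_replication <- function(config) {
  platforms <- names(config$depth_by_platform)
  sources <- paste0("S", seq_len(config$n_sources))
  offsets <- lapply(platforms, function(p) taxon_efficiency_offsets(config, p))
  names(offsets) <- platforms
  vectors <- list()
  meta <- list()
  for (si in seq_along(sources)) {
    src <- sources[si]
    # Each source soil gets its own community: an independent abundance
    # draw assigned to a permuted subset of the taxon pool, thinned to a
    # source-specific effective richness. The sources' richness fractions
    # are drawn from staggered sub-ranges of (0.5, 1) so that, as for soils
    # from distinct biomes, the samples differ decisively in richness.
    comm <- make_community(config, seed = derive_seed(config$seed, "community", src))
    ab <- numeric(config$n_taxa)
    perm <- with_seed_opt(derive_seed(config$seed, "srcperm", src),
                          sample.int(config$n_taxa))
    ab[perm] <- comm$abundance
    band <- 0.5 / length(sources)
    frac <- with_seed_opt(derive_seed(config$seed, "srcrich", src),
                          stats::runif(1, 0.5 + (si - 1) * band,
                                       0.5 + si * band))
    comm <- community_profile(comm$otu_ids, thin_profile(ab, frac))
    for (platform in platforms) {
      for (k in config$pool_sizes) {
        profiles <- lapply(seq_len(k), function(r) {
          eff <- reaction_efficiencies(
            config, offsets[[platform]],
            seed = derive_seed(config$seed, "eff", src, platform, k, r))
          simulate_pcr(comm, config, eff,
                       seed = derive_seed(config$seed, "pcr", src, platform, k, r))
        })
        pooled <- pool_replicates(profiles)
        reads <- sequence_sample(pooled, platform, config,
                                 seed = derive_seed(config$seed, "seq", src,
                                                    platform, k))
        id <- paste(src, paste0("k", k), platform, sep = "_")
        vectors[[id]] <- reads
        meta[[id]] <- data.frame(sample_id = id, source_id = src,
                                 pool_size = k, platform = platform,
                                 group = src,
                                 replicate_index = match(k, config$pool_sizes),
                                 stringsAsFactors = FALSE)
      }
    }
  }
  assemble_table(vectors, meta)
}

# Zero out the rarest (1 - frac) share of taxa and renormalize: different
# soils differ in effective richness, not just in composition.
thin_profile <- function(ab, frac) {
  keep_n <- max(1L, round(frac * sum(ab > 0)))
  ranked <- order(ab, decreasing = TRUE)
  ab[ranked[-seq_len(keep_n)]] <- 0
  ab / sum(ab)
}

# Dirichlet draw centred on profile p with concentration c (alpha = c * p).
rdirichlet_profile <- function(p, concentration) {
  g <- stats::rgamma(length(p), shape = concentration * p, rate = 1)
  if (sum(g) == 0) stop("degenerate Dirichlet draw (concentration too low)",
                        call. = FALSE)
  g / sum(g)
}

simulate_cross_platform <- function(config) {
  platforms <- names(config$depth_by_platform)
  offsets <- lapply(platforms, function(p) taxon_efficiency_offsets(config, p))
  names(offsets) <- platforms
  otu_names <- sprintf("OTU_%04d", seq_len(config$n_taxa))
  vectors <- list()
  meta <- list()
  for (g in seq_len(config$n_groups)) {
    region <- paste0("region", g)
    # Independent regional profile: abundance draw assigned to a permuted
    # subset of the shared taxon pool, so regions overlap in membership but
    # differ strongly in composition.
    comm <- make_community(config, seed = derive_seed(config$seed, "groupcomm", g))
    perm <- with_seed_opt(derive_seed(config$seed, "groupperm", g), {
      sample.int(config$n_taxa)
    })
    region_ab <- numeric(config$n_taxa)
    region_ab[perm] <- comm$abundance
    for (s in seq_len(config$sites_per_group)) {
      site <- sprintf("G%d_T%d", g, s)
      site_ab <- with_seed_opt(derive_seed(config$seed, "site", g, s), {
        thin_profile(rdirichlet_profile(region_ab, 3 * config$group_concentration),
                     stats::runif(1, 0.6, 1))
      })
      for (j in seq_len(config$samples_per_site)) {
        base <- sprintf("%s_%02d", site, j)
        samp_ab <- with_seed_opt(derive_seed(config$seed, "sample", g, s, j), {
          rdirichlet_profile(site_ab, config$group_concentration)
        })
        samp_profile <- community_profile(otu_names, samp_ab)
        for (platform in platforms) {
          eff <- reaction_efficiencies(
            config, offsets[[platform]],
            seed = derive_seed(config$seed, "xeff", base, platform))
          amplified <- simulate_pcr(samp_profile, config, eff,
                                    seed = derive_seed(config$seed, "xpcr",
                                                       base, platform))
          reads <- sequence_sample(amplified, platform, config,
                                   seed = derive_seed(config$seed, "xseq",
                                                      base, platform))
          id <- paste(base, platform, sep = "_")
          vectors[[id]] <- reads
          meta[[id]] <- data.frame(sample_id = id, source_id = base,
                                   pool_size = 1L, platform = platform,
                                   group = region, replicate_index = 0L,
                                   stringsAsFactors = FALSE)
        }
      }
    }
  }
  assemble_table(vectors, meta)
}

assemble_table <- function(vectors, meta) {
  ids <- names(vectors)
  m <- bind_count_rows(vectors, ids)
  # real taxa first, spurious OTUs sorted after them
  spur <- grepl("^ERR_", colnames(m))
  m <- m[, c(which(!spur), which(spur)[order(colnames(m)[spur])]), drop = FALSE]
  count_table(m, do.call(rbind, meta))
}
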