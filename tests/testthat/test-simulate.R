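test_that("sim_config validates its parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(stochastic_cycles = 40), "stochastic_cycles")
  expect_error(sim_config(efficiency_mean = 0), "efficiency_mean")
  expect_error(sim_config(error_rate = 1), "error_rate")
  expect_error(sim_config(abundance_model = list(type = "zipf")), "type")
  expect_error(sim_config(abundance_model = list(type = "geometric",
                                                 theta = 1.2)), "theta")
  expect_error(sim_config(depth_by_platform = list(p454 = c(10, 20, 30))),
               "depth")
})

test_that("sim_config round-trips through JSON", {
  cfg <- small_sim_config(seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  sim_config_to_json(cfg, path)
  back <- sim_config_from_json(path)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
  writeLines('{"bogus_field": 3}', path)
  expect_error(sim_config_from_json(path), "bogus_field")
})

test_that("make_community draws a sorted, normalized profile", {
  cfg1 <- sim_config(n_taxa = 1)
  expect_equal(make_community(cfg1)$abundance, 1)

  for (i in 1:10) {
    cfg <- sim_config(n_taxa = 25, seed = i)
    com <- make_community(cfg)
    expect_equal(sum(com$abundance), 1, tolerance = 1e-12)
    expect_true(all(diff(com$abundance) <= 0))
  }
  flat <- sim_config(n_taxa = 10,
                     abundance_model = list(type = "lognormal", meanlog = 0,
                                            sdlog = 0))
  expect_equal(make_community(flat)$abundance, rep(0.1, 10))
  geo <- sim_config(n_taxa = 4,
                    abundance_model = list(type = "geometric", theta = 0.5))
  ab <- make_community(geo)$abundance
  expect_equal(ab / ab[1], c(1, 0.5, 0.25, 0.125), tolerance = 1e-12)
})

test_that("simulate_pcr: deterministic branch follows the closed form", {
  cfg <- sim_config(n_taxa = 6, template_molecules = 500,
                    stochastic_cycles = 0, seed = 1)
  com <- community_profile_for_test(c(0.4, 0.3, 0.15, 0.1, 0.05, 0))
  eff <- c(0.9, 0.8, 0.95, 0.85, 0.7, 0.9)
  out <- simulate_pcr(com, cfg, eff, seed = 77)
  # with no stochastic cycles the product is template * (1+e)^cycles exactly
  templates <- withr::with_seed(77, {
    as.numeric(rmultinom(1, 500, com$abundance))
  })
  expected <- templates * (1 + eff)^30
  expect_equal(out$abundance, expected / sum(expected), tolerance = 1e-12)
  expect_equal(out$abundance[6], 0)  # absent from template, absent from product
})

test_that("simulate_pcr with equal efficiencies recovers the input on average", {
  cfg <- sim_config(n_taxa = 15, template_molecules = 10000,
                    stochastic_cycles = 0, seed = 2,
                    abundance_model = list(type = "lognormal", meanlog = 0,
                                           sdlog = 1))
  com <- make_community(cfg)
  eff <- rep(0.9, 15)
  reps <- withr::with_seed(8, {
    vapply(1:200, function(i) simulate_pcr(com, cfg, eff)$abundance,
           numeric(15))
  })
  m <- rowMeans(reps)
  se <- apply(reps, 1, sd) / sqrt(ncol(reps))
  expect_true(all(abs(m - com$abundance) <= 3 * se + 1e-12))
})

test_that("pooling averages profiles and shrinks variance like 1/k", {
  com <- community_profile_for_test(c(0.5, 0.3, 0.2))
  expect_equal(pool_replicates(list(com, com, com))$abundance, com$abundance)
  other <- community_profile_for_test(c(0.1, 0.1, 0.8))
  expect_equal(pool_replicates(list(com, other), weights = c(1, 0))$abundance,
               com$abundance)
  bad <- community_profile_for_test(c(0.5, 0.5))
  expect_error(pool_replicates(list(com, bad)), "different taxa")

  cfg <- sim_config(n_taxa = 12, template_molecules = 300,
                    stochastic_cycles = 2, seed = 3,
                    abundance_model = list(type = "lognormal", meanlog = 0,
                                           sdlog = 1))
  truth <- make_community(cfg)
  eff <- rep(0.85, 12)
  ks <- c(1, 2, 4, 8, 16)
  v <- withr::with_seed(9, vapply(ks, function(k) {
    pooled <- vapply(1:300, function(i) {
      pool_replicates(lapply(seq_len(k), function(r) {
        simulate_pcr(truth, cfg, eff)
      }))$abundance[1]
    }, numeric(1))
    var(pooled)
  }, numeric(1)))
  slope <- coef(lm(log(v) ~ log(ks)))[2]
  expect_equal(unname(slope), -1, tolerance = 0.2)
})

test_that("sequencing draws exact depths and a calibrated error load", {
  com <- community_profile_for_test(rep(0.05, 20))
  clean <- sim_config(n_taxa = 20, error_rate = 0, seed = 4)
  x <- sequence_sample(com, "illumina", clean, seed = 1, depth = 5000)
  expect_equal(sum(x), 5000)
  expect_false(any(grepl("^ERR_", names(x))))

  noisy <- sim_config(n_taxa = 20, error_rate = 0.02, seed = 4)
  spur_reads <- withr::with_seed(10, vapply(1:50, function(i) {
    y <- sequence_sample(com, "illumina", noisy, depth = 5000)
    expect_equal(sum(y), 5000)
    sum(y[grepl("^ERR_", names(y))])
  }, numeric(1)))
  expected <- 5000 * 0.02
  se <- sqrt(5000 * 0.02 * 0.98 / 50)
  expect_lt(abs(mean(spur_reads) - expected), 4 * se)
})

test_that("deeper sequencing recovers at least as many spurious OTUs", {
  com <- community_profile_for_test(rep(0.1, 10))
  cfg <- sim_config(n_taxa = 10, error_rate = 0.01, seed = 5)
  mean_spur <- vapply(c(1e3, 1e4, 1e5), function(d) {
    withr::with_seed(12, mean(vapply(1:60, function(i) {
      y <- sequence_sample(com, "illumina", cfg, depth = d)
      sum(grepl("^ERR_", names(y)) & y > 0)
    }, numeric(1))))
  }, numeric(1))
  expect_true(all(diff(mean_spur) > 0))
})

test_that("platform masking limits the detectable taxon set", {
  com <- community_profile_for_test(rep(1 / 40, 40))
  cfg <- sim_config(n_taxa = 40, error_rate = 0,
                    platform_detectable_fraction = c(p454 = 0.5, illumina = 1),
                    seed = 6)
  x <- sequence_sample(com, "p454", cfg, seed = 2, depth = 4000)
  expect_lte(sum(x > 0), 20)
  y <- sequence_sample(com, "illumina", cfg, seed = 2, depth = 4000)
  expect_gt(sum(y > 0), 20)
})

test_that("simulate_experiment lays out the replication design deterministically", {
  cfg <- small_sim_config(seed = 31)
  tab <- simulate_experiment(cfg, "replication")
  expect_equal(nrow(tab$counts), 3 * 5 * 2)
  expect_setequal(unique(tab$metadata$pool_size), c(1, 2, 4, 8, 16))
  expect_setequal(unique(tab$metadata$platform), c("p454", "illumina"))
  expect_equal(sum(tab$metadata$platform == "p454"), 15)
  totals <- rowSums(tab$counts)
  expect_true(all(totals[tab$metadata$platform == "illumina"] >= 2000))

  tab2 <- simulate_experiment(cfg, "replication")
  expect_identical(tab$counts, tab2$counts)
  tab3 <- simulate_experiment(small_sim_config(seed = 32), "replication")
  expect_false(identical(tab$counts, tab3$counts))
})

test_that("tight cross-platform groups are separable by perMANOVA", {
  cfg <- small_sim_config(seed = 33, group_concentration = 1e6,
                          error_rate = 0)
  tab <- simulate_experiment(cfg, "cross_platform")
  expect_equal(nrow(tab$counts), 3 * 2 * 3 * 2)
  sub <- tab
  keep <- tab$metadata$platform == "illumina"
  sub$counts <- tab$counts[keep, , drop = FALSE]
  sub$metadata <- tab$metadata[keep, ]
  d <- distance_matrix(sub, "bray_curtis")
  res <- permanova(d, sub$metadata$group, n_permutations = 99, seed = 1)
  expect_gt(res$r_squared, 0.5)
  expect_equal(res$p_value, 0.01)
})
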