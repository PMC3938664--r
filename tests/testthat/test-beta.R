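test_that("pairwise metrics match hand-worked examples", {
  expect_equal(bray_curtis(c(2, 0), c(1, 1)), 0.5)
  expect_equal(bray_curtis(c(3, 1), c(3, 1)), 0)
  expect_equal(bray_curtis(c(5, 0), c(0, 9)), 1)

  expect_equal(jaccard_binary(c(1, 2, 0), c(0, 9, 4)), 1 - 1 / 3)
  expect_equal(jaccard_binary(c(1, 2, 0), c(100, 200, 0)), 0)
  expect_equal(jaccard_binary(c(1, 2, 0), 100 * c(0, 9, 4)),
               jaccard_binary(c(1, 2, 0), c(0, 9, 4)))

  expect_equal(beta_sim(c(1, 1, 0, 0, 0), c(1, 1, 1, 1, 1)), 0)  # nested
  expect_equal(beta_sim(c(1, 1, 0, 0), c(1, 0, 1, 1)), 0.5)      # a=1,b=1,c=2
  expect_equal(beta_sim(c(1, 0, 1), c(0, 1, 1)),
               beta_sim(c(0, 1, 1), c(1, 0, 1)))

  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(beta_sim(c(0, 0), c(1, 0)), "present")
})

test_that("all metrics are symmetric, bounded and zero on identity", {
  for (i in 1:100) {
    p <- withr::with_seed(500 + i, list(x = rpois(12, 2), y = rpois(12, 2)))
    x <- p$x; y <- p$y
    if (sum(x) == 0 || sum(y) == 0) next
    for (f in list(bray_curtis, jaccard_binary, beta_sim)) {
      d <- f(x, y)
      expect_gte(d, 0); expect_lte(d, 1)
      expect_equal(f(y, x), d)
      expect_equal(f(x, x), 0)
    }
    expect_lte(beta_sim(x, y), jaccard_binary(x, y) + 1e-12)
  }
})

test_that("pairwise metrics agree with vegan", {
  skip_if_not_installed("vegan")
  for (i in 1:25) {
    m <- withr::with_seed(600 + i, matrix(rpois(20, 3), nrow = 2))
    if (any(rowSums(m) == 0)) next
    expect_equal(bray_curtis(m[1, ], m[2, ]),
                 as.numeric(vegan::vegdist(m, "bray")), tolerance = 1e-12)
    expect_equal(jaccard_binary(m[1, ], m[2, ]),
                 as.numeric(vegan::vegdist(m, "jaccard", binary = TRUE)),
                 tolerance = 1e-12)
    expect_equal(beta_sim(m[1, ], m[2, ]),
                 as.numeric(vegan::betadiver(m, "sim")), tolerance = 1e-12)
  }
})

test_that("distance_matrix is consistent with the pairwise functions", {
  tab <- random_count_table(5, 15, lambda = 4, seed = 77)
  for (m in c("bray_curtis", "jaccard", "beta_sim")) {
    d <- distance_matrix(tab, metric = m)
    expect_equal(diag(d), setNames(rep(0, 5), rownames(tab$counts)))
    expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
    fun <- switch(m, bray_curtis = bray_curtis, jaccard = jaccard_binary,
                  beta_sim = beta_sim)
    expect_equal(d[2, 4], fun(tab$counts[2, ], tab$counts[4, ]))
    expect_identical(attr(d, "metric"), m)
  }
  expect_error(distance_matrix(tab, metric = "unifrac"))
})

test_that("duplicated samples are at distance zero; rarefaction drops and seeds", {
  m <- matrix(rep(c(4, 2, 0, 1), 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("OTU", 1:4)))
  d <- distance_matrix(count_table(m), "bray_curtis")
  expect_equal(d["a", "b"], 0)

  tab <- random_count_table(4, 10, lambda = 3, seed = 8)
  totals <- rowSums(tab$counts)
  depth <- sort(totals)[2]  # drops the shallowest sample
  expect_warning(d1 <- distance_matrix(tab, "bray_curtis", depth = depth,
                                       seed = 3), "dropped")
  expect_equal(nrow(d1), sum(totals >= depth))
  d2 <- suppressWarnings(distance_matrix(tab, "bray_curtis", depth = depth,
                                         seed = 3))
  expect_equal(unclass(d1), unclass(d2), ignore_attr = TRUE)
})

test_that("mean dissimilarity to other plot samples excludes same-source replicates", {
  counts <- rbind(focal = c(2, 0, 1), twin = c(2, 0, 1),
                  n1 = c(1, 1, 0), n2 = c(0, 2, 2),
                  o1 = c(5, 5, 5), o2 = c(5, 0, 5), lone = c(1, 2, 3))
  colnames(counts) <- paste0("OTU", 1:3)
  meta <- data.frame(sample_id = rownames(counts),
                     source_id = c("A", "A", "B", "C", "D", "E", "F"),
                     pool_size = 1L, platform = "p454",
                     group = c("g1", "g1", "g1", "g1", "g2", "g2", "g3"))
  tab <- count_table(counts, meta)
  # same-source technical replicate "twin" is excluded from the average
  expected <- mean(c(bray_curtis(counts["focal", ], counts["n1", ]),
                     bray_curtis(counts["focal", ], counts["n2", ])))
  expect_equal(mean_dissimilarity_to_plot(tab, "focal"), expected)
  # single comparator equals the pairwise value
  expect_equal(mean_dissimilarity_to_plot(tab, "o1"),
               bray_curtis(counts["o1", ], counts["o2", ]))
  # focal identical to its comparator scores zero
  expect_equal(mean_dissimilarity_to_plot(tab, "twin",
                                          metric = "jaccard"),
               mean(c(jaccard_binary(counts["twin", ], counts["n1", ]),
                      jaccard_binary(counts["twin", ], counts["n2", ]))))
  expect_error(mean_dissimilarity_to_plot(tab, "lone"), "no comparator")
  expect_error(mean_dissimilarity_to_plot(tab, "missing"), "unknown")
})
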