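test_that("one-way ANOVA F equals the squared two-sample t statistic", {
  y <- withr::with_seed(41, c(rnorm(8, 0), rnorm(8, 1)))
  g <- factor(rep(c("a", "b"), each = 8))
  at <- factorial_anova(y, data.frame(g = g), ~ g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(at$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(at$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("balanced 2x2 ANOVA reproduces a hand sum-of-squares decomposition", {
  # 2 x 2 design with 2 replicates per cell; SS computed from cell means
  y <- c(10, 12, 14, 16, 20, 22, 28, 30)
  a <- factor(rep(c("lo", "hi"), each = 4), levels = c("lo", "hi"))
  b <- factor(rep(c("x", "y", "x", "y"), each = 2))
  at <- factorial_anova(y, data.frame(a = a, b = b), ~ a * b)

  grand <- mean(y)
  m_a <- tapply(y, a, mean); m_b <- tapply(y, b, mean)
  m_ab <- tapply(y, interaction(a, b), mean)
  ss_a <- 4 * sum((m_a - grand)^2)
  ss_b <- 4 * sum((m_b - grand)^2)
  cells <- interaction(a, b)
  ss_cells <- 2 * sum((m_ab - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_res <- sum((y - ave(y, cells))^2)

  expect_equal(at$sum_sq, c(ss_a, ss_b, ss_ab), tolerance = 1e-10)
  expect_equal(attr(at, "residual_sum_sq"), ss_res, tolerance = 1e-10)
  expect_equal(at$df, c(1, 1, 1))
  expect_equal(attr(at, "residual_df"), 4)
})

test_that("degenerate and aliased designs are handled explicitly", {
  g <- factor(rep(c("a", "b"), each = 4))
  at <- factorial_anova(rep(3, 8), data.frame(g = g), ~ g)
  expect_equal(at$f_stat, 0)
  expect_equal(at$p_value, 1)

  # h is a copy of g: its coefficient is aliased
  expect_error(
    factorial_anova(rnorm(8), data.frame(g = g, h = g), ~ g + h), "aliased")
  expect_error(factorial_anova(rnorm(4), data.frame(g = factor(1:4)), ~ g),
               "degrees of freedom")
})

test_that("mantel statistic and p-value behave as a permutation test", {
  pts <- withr::with_seed(51, matrix(rnorm(24), ncol = 3))
  d1 <- as.matrix(dist(pts))
  m <- mantel(d1, d1, n_permutations = 99, seed = 1)
  expect_equal(m$statistic, 1)
  expect_equal(m$p_value, 1 / 100)  # identical matrices sit at the floor
  expect_gte(m$p_value, 1 / (m$n_permutations + 1))

  d2 <- as.matrix(dist(pts + withr::with_seed(52, matrix(rnorm(24), ncol = 3))))
  same1 <- mantel(d1, d2, n_permutations = 199, seed = 7)
  same2 <- mantel(d1, d2, n_permutations = 199, seed = 7)
  expect_identical(same1$p_value, same2$p_value)

  rownames(d2) <- colnames(d2) <- letters[1:8]
  rownames(d1) <- colnames(d1) <- LETTERS[1:8]
  expect_error(mantel(d1, d2), "identifiers")
  expect_error(mantel(unname(d1), unname(d2)[1:7, 1:7]), "size")
})

test_that("mantel r agrees with vegan", {
  skip_if_not_installed("vegan")
  pts <- withr::with_seed(53, matrix(rnorm(30), ncol = 3))
  d1 <- dist(pts)
  d2 <- dist(pts[, c(2, 3, 1)])
  ours <- mantel(as.matrix(d1), as.matrix(d2), n_permutations = 99, seed = 1)
  ref <- vegan::mantel(d1, d2, permutations = 99)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("permanova matches a brute-force double loop and vegan", {
  brute <- function(d, groups) {
    n <- nrow(d); a <- length(unique(groups))
    ss_total <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ss_total <- ss_total + d[i, j]^2 / n
    }
    ss_within <- 0
    for (g in unique(groups)) {
      idx <- which(groups == g)
      for (i in idx) for (j in idx) if (i < j) {
        ss_within <- ss_within + d[i, j]^2 / length(idx)
      }
    }
    ss_between <- ss_total - ss_within
    (ss_between / (a - 1)) / (ss_within / (n - a))
  }
  for (i in 1:20) {
    pts <- withr::with_seed(700 + i, matrix(rnorm(18), ncol = 3))
    d <- as.matrix(dist(pts))
    groups <- rep(c("a", "b"), each = 3)
    res <- permanova(d, groups, n_permutations = 99, seed = 1)
    expect_equal(res$statistic, brute(d, groups), tolerance = 1e-10)
  }
  skip_if_not_installed("vegan")
  pts <- withr::with_seed(54, matrix(rnorm(36), ncol = 3))
  d <- dist(pts)
  groups <- rep(c("a", "b", "c"), each = 4)
  res <- permanova(as.matrix(d), groups, n_permutations = 99, seed = 1)
  ref <- vegan::adonis2(d ~ g, data = data.frame(g = groups), permutations = 99)
  expect_equal(res$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(res$r_squared, ref$R2[1], tolerance = 1e-10)
})

test_that("permanova separates duplicated groups and validates input", {
  m <- matrix(1, 10, 10) - diag(10)
  m[1:5, 1:5] <- 0; m[6:10, 6:10] <- 0  # two blocks of identical samples
  res <- permanova(m, rep(c("a", "b"), each = 5), n_permutations = 999,
                   seed = 2)
  expect_lt(res$p_value, 0.02)
  expect_error(permanova(m, c("a", rep("b", 9))), "at least 2 members")
  expect_error(permanova(m, rep("a", 10)), "at least 2 groups")
  r1 <- permanova(m + withr::with_seed(3, {
    e <- matrix(runif(100, 0, 0.1), 10); e <- (e + t(e)) / 2; diag(e) <- 0; e
  }), rep(c("a", "b"), each = 5), n_permutations = 199, seed = 9)
  r2 <- permanova(m + withr::with_seed(3, {
    e <- matrix(runif(100, 0, 0.1), 10); e <- (e + t(e)) / 2; diag(e) <- 0; e
  }), rep(c("a", "b"), each = 5), n_permutations = 199, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("platform overlap partitions the observed OTUs", {
  counts <- rbind(a1 = c(1, 0, 2, 0), a2 = c(3, 0, 0, 0),
                  b1 = c(0, 4, 1, 0), b2 = c(1, 1, 0, 0))
  colnames(counts) <- paste0("OTU", 1:4)
  meta <- data.frame(sample_id = rownames(counts), source_id = "s",
                     pool_size = 1L, platform = rep(c("p454", "illumina"),
                                                    each = 2),
                     group = "g")
  ov <- platform_overlap(count_table(counts, meta))
  expect_equal(ov$shared, 2)    # OTU1, OTU3
  expect_equal(ov$unique_a, 0)
  expect_equal(ov$unique_b, 1)  # OTU2
  expect_equal(ov$shared + ov$unique_a + ov$unique_b, ov$total)
  expect_equal(ov$total, 3)     # OTU4 observed nowhere

  one <- count_table(counts, transform(meta, platform = "p454"))
  expect_error(platform_overlap(one), "exactly 2")
})
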