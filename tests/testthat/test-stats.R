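test_that("paired test matches the closed form and handles degeneracy", {
  r <- paired_difference_test(c(2, 3, 4), c(1, 1, 1))  # differences 1,2,3
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-12)  # 3.464
  expect_equal(r$df, 2L)
  expect_equal(r$p_value, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)  # 0.0742
  expect_equal(round(r$p_value, 4), 0.0742)
  # cross-check against stats::t.test on a noisy pair set
  set.seed(10)
  x <- rnorm(12); y <- rnorm(12)
  tt <- t.test(x, y, paired = TRUE)
  mine <- paired_difference_test(x, y)
  expect_equal(mine$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, tt$p.value, tolerance = 1e-12)
  # degenerate all-zero differences
  z <- paired_difference_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  expect_error(paired_difference_test(1:2, 2:3), "at least 3")
})

test_that("vs-control comparison reduces to the paired t for a single group", {
  set.seed(11)
  m <- cbind(Medium = rnorm(6, 10), LPS = rnorm(6, 11))
  r <- compare_to_control(m, control = "Medium")
  expect_equal(r$p_adjusted, r$p_raw)
  expect_equal(r$p_raw, paired_difference_test(m[, "LPS"], m[, "Medium"])$p_value)
})

test_that("vs-control adjusted p-values are monotone and detect a real shift", {
  set.seed(12)
  m <- cbind(Medium = rnorm(6, 10, 0.5), A = rnorm(6, 10, 0.5),
             B = rnorm(6, 13, 0.5), C = rnorm(6, 10.2, 0.5))
  r <- compare_to_control(m, control = "Medium", n_mc = 20000L, seed = 77)
  expect_true(all(r$p_adjusted >= r$p_raw))
  expect_true(all(r$p_adjusted <= 1 & r$p_adjusted >= 0))
  expect_lt(r$p_adjusted[r$group == "B"], 0.05)
  # identical groups: all adjusted p = 1
  same <- cbind(Medium = c(1, 2, 3, 4), A = c(1, 2, 3, 4), B = c(1, 2, 3, 4))
  rs <- compare_to_control(same, control = "Medium", n_mc = 500L, seed = 1)
  expect_equal(rs$p_adjusted, c(1, 1))
  # unbalanced designs are refused with the missing cell named
  mm <- m; mm[2, "A"] <- NA
  expect_error(compare_to_control(mm, control = "Medium"), "donor 2/A")
})

test_that("Monte-Carlo max-|t| adjustment agrees with a brute-force null oracle", {
  set.seed(13)
  n <- 8; k <- 3
  m <- cbind(Medium = rnorm(n), A = rnorm(n), B = rnorm(n), C = rnorm(n))
  r <- compare_to_control(m, control = "Medium", n_mc = 200000L, seed = 99)
  # oracle: the same max-over-paired-|t| null, simulated one repetition at
  # a time with scalar t tests, independent of the vectorised implementation
  set.seed(98)
  max_t <- replicate(50000, {
    z <- matrix(rnorm(n * (k + 1L)), n)
    max(abs(vapply(seq_len(k), function(j) {
      d <- z[, j] - z[, k + 1L]
      mean(d) / (sd(d) / sqrt(n))
    }, numeric(1))))
  })
  p_ref <- vapply(abs(r$statistic), function(t0) mean(max_t >= t0), numeric(1))
  expect_equal(r$p_adjusted, pmax(p_ref, r$p_raw), tolerance = 0.015)
})

test_that("Sidak adjustment matches its closed form and caps at 1", {
  expect_equal(sidak_adjust(0.05, 3), 1 - 0.95^3)
  expect_equal(sidak_adjust(0.05, 3), 0.142625)
  expect_equal(sidak_adjust(0.2, 1), 0.2)
  expect_equal(sidak_adjust(0.9, 10), 1)
  set.seed(18)
  p <- runif(20)
  expect_true(all(sidak_adjust(p, 5) >= p))
})

test_that("two-factor pairwise contrasts reproduce direct cell-mean computation", {
  set.seed(14)
  df <- expand.grid(metric = c("mito", "glyco"),
                    stim = c("Medium", "LPS", "IL4"), donor = 1:5)
  df$y <- rnorm(nrow(df), ifelse(df$stim == "LPS" & df$metric == "glyco", 3, 0))
  r <- pairwise_condition_tests(df$y, df$metric, df$stim)
  expect_equal(nrow(r), 2L * 3L)  # 2 metrics x 3 pairwise stim contrasts
  expect_true(all(r$p_adjusted >= r$p_raw))
  # estimate equals the plain difference of cell means
  est <- mean(df$y[df$metric == "glyco" & df$stim == "Medium"]) -
    mean(df$y[df$metric == "glyco" & df$stim == "LPS"])
  expect_equal(r$estimate[r$factor_a == "glyco" &
                            r$contrast == "Medium vs LPS"], est)
  gone <- !(df$metric == "mito" & df$stim == "LPS")  # empty one whole cell
  expect_error(pairwise_condition_tests(df$y[gone], df$metric[gone],
                                        df$stim[gone]), "empty cell")
})

test_that("PCA matches an eigen-decomposition oracle and fixes signs", {
  set.seed(15)
  x <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("s", 1:6),
                                               paste0("p", 1:4)))
  pca <- pca_profiles(x)
  eg <- eigen(cor(x))
  expect_equal(pca$explained_variance_fraction,
               eg$values / sum(eg$values), tolerance = 1e-9)
  for (j in 1:4) {
    ratio <- pca$loadings[, j] / eg$vectors[, j]
    expect_equal(abs(ratio), rep(1, 4), tolerance = 1e-9,
                 ignore_attr = TRUE)  # same axis up to sign
    lead <- which.max(abs(pca$loadings[, j]))
    expect_gt(pca$loadings[lead, j], 0)  # sign convention
  }
  # scores reconstruct the scaled matrix when all components are kept
  xs <- scale(x)
  expect_equal(pca$scores %*% t(pca$loadings), unclass(xs),
               tolerance = 1e-9, ignore_attr = TRUE)
  # explained fractions are non-increasing and sum to 1
  expect_true(all(diff(pca$explained_variance_fraction) <= 1e-12))
  expect_equal(sum(pca$explained_variance_fraction), 1, tolerance = 1e-9)
})

test_that("perfectly correlated features load entirely on PC1", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  pca <- suppressWarnings(pca_profiles(x + 0))
  expect_equal(pca$explained_variance_fraction[1], 1, tolerance = 1e-9)
  tl <- top_loadings(pca, 1, k = 1)
  expect_true(tl$feature %in% c("a", "b"))
  expect_equal(tl$feature, "a")  # tie on |loading| broken by name
})

test_that("PCA is invariant to sample and feature order, degenerate input errors", {
  set.seed(16)
  x <- matrix(rnorm(30), 6, 5, dimnames = list(paste0("s", 1:6),
                                               paste0("f", 1:5)))
  p1 <- pca_profiles(x)
  p2 <- pca_profiles(x[sample(6), sample(5)])
  expect_equal(p2$explained_variance_fraction,
               p1$explained_variance_fraction, tolerance = 1e-9)
  expect_equal(abs(p2$loadings[rownames(p1$loadings), 1]),
               abs(p1$loadings[, 1]), tolerance = 1e-9)
  expect_error(suppressWarnings(pca_profiles(matrix(1, 4, 3))),
               "nonzero variance")
  expect_error(pca_profiles(x[1, , drop = FALSE]), "at least 2")
})

test_that("top loadings rank by magnitude with deterministic tie-breaks", {
  set.seed(17)
  x <- matrix(rnorm(40), 8, 5)
  colnames(x) <- c("mono:glucose_dependence", "mono:mitochondrial_dependence",
                   "B:glucose_dependence", "B:mitochondrial_dependence",
                   "NK:glucose_dependence")
  rownames(x) <- paste0("s", 1:8)
  pca <- pca_profiles(x)
  tl <- top_loadings(pca, 1, k = 3)
  l <- abs(pca$loadings[, 1])
  expect_equal(tl$feature, names(sort(-l))[1:3])
  expect_equal(tl$metric,
               ifelse(grepl("glucose", tl$feature), "glucose", "mitochondrial"))
  expect_message(top_loadings(pca, 1, k = 99), "truncating")
  expect_error(top_loadings(pca, 9), "not available")
})

test_that("profile_matrix assembles sample-by-feature dependence values", {
  prof <- data.frame(sample_id = rep(c("s1", "s2"), each = 2),
                     population = rep(c("mono", "B"), 2),
                     glucose_dependence = c(90, 60, 85, 55),
                     mitochondrial_dependence = c(30, 45, 35, 50))
  m <- profile_matrix(prof)
  expect_equal(dim(m), c(2L, 4L))
  expect_equal(m["s1", "mono:glucose_dependence"], 90)
  expect_equal(m["s2", "B:mitochondrial_dependence"], 50)
})
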