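test_that("exceedance probability matches closed forms and Monte Carlo", {
  expect_equal(exceedance_probability(1, 1), 0.5)
  expect_equal(exceedance_probability(2, 1), 0.75)   # CDF y^2 at 0.5
  set.seed(1)
  mc <- mean(stats::rbeta(1e6, 5, 2) > 0.5)
  expect_equal(exceedance_probability(5, 2), mc, tolerance = 0.002)
  expect_error(exceedance_probability(-1, 2), "invalid")
})

test_that("exceedance probability is monotone in the shape parameters", {
  a_grid <- seq(0.5, 8, length.out = 12)
  p_a <- exceedance_probability(a_grid, 3)
  expect_true(all(diff(p_a) > 0))
  p_b <- exceedance_probability(3, a_grid)
  expect_true(all(diff(p_b) < 0))
})

test_that("difference-of-betas probability: symmetry and complements", {
  expect_equal(delta_probability(2, 2, 2, 2)$pr_delta_le_0, 0.5,
               tolerance = 1e-4)
  expect_equal(delta_probability(3.7, 1.2, 3.7, 1.2)$pr_delta_le_0, 0.5,
               tolerance = 1e-4)
  set.seed(2)
  for (i in 1:5) {
    a1 <- stats::runif(1, 0.6, 6); b1 <- stats::runif(1, 1.1, 6)
    a2 <- stats::runif(1, 0.6, 6); b2 <- stats::runif(1, 1.1, 6)
    pjk <- delta_probability(a1, b1, a2, b2)$pr_delta_le_0
    pkj <- delta_probability(a2, b2, a1, b1)$pr_delta_le_0
    expect_equal(pjk + pkj, 1, tolerance = 5e-4)
  }
})

test_that("difference-of-betas probability matches a sampling oracle", {
  set.seed(3)
  mc <- mean(stats::rbeta(1e6, 5, 1) - stats::rbeta(1e6, 1, 5) <= 0)
  expect_lt(abs(delta_probability(5, 1, 1, 5)$pr_delta_le_0 - mc), 0.002)
  # closed form for this pair: Pr = E[Y^5] with Y ~ Beta(1,5)
  expect_equal(delta_probability(5, 1, 1, 5)$pr_delta_le_0,
               beta(6, 5) / beta(1, 5), tolerance = 1e-3)
  # random pairs within 3 standard errors of a 10^6-sample Monte Carlo
  set.seed(4)
  for (i in 1:6) {
    a1 <- stats::runif(1, 0.5, 8); b1 <- stats::runif(1, 0.5, 8)
    a2 <- stats::runif(1, 0.5, 8); b2 <- stats::runif(1, 0.5, 8)
    if (a1 <= 1 && b1 <= 1) a1 <- a1 + 1
    if (a2 <= 1 && b2 <= 1) b2 <- b2 + 1
    p_hat <- mean(stats::rbeta(1e6, a1, b1) - stats::rbeta(1e6, a2, b2) <= 0)
    se <- sqrt(p_hat * (1 - p_hat) / 1e6)
    p <- delta_probability(a1, b1, a2, b2)$pr_delta_le_0
    expect_lt(abs(p - p_hat), 3 * se + 2e-4)
  }
})

test_that("KS distance: exact mode properties and sampled agreement", {
  expect_equal(ks_distance_beta(2.5, 3, 2.5, 3), 0)
  expect_gt(ks_distance_beta(50, 1, 1, 50), 0.99)
  set.seed(5)
  for (i in 1:4) {
    a1 <- stats::runif(1, 1.2, 8); b1 <- stats::runif(1, 1.2, 8)
    a2 <- stats::runif(1, 1.2, 8); b2 <- stats::runif(1, 1.2, 8)
    exact <- ks_distance_beta(a1, b1, a2, b2)
    samp <- ks_distance_beta(a1, b1, a2, b2, method = "sampled",
                             seed = i)
    expect_lt(abs(exact - samp), 0.01)   # DKW at n = 1e5
  }
})

test_that("one-sample KS distance matches stats::ks.test", {
  set.seed(6)
  x <- stats::rbeta(500, 2, 5)
  d <- ks_distance_empirical(x, 2.2, 4.5)
  d_ref <- unname(stats::ks.test(x, stats::pbeta, 2.2, 4.5)$statistic)
  expect_equal(d, d_ref, tolerance = 1e-12)
})

test_that("mean state duration follows the geometric closed form", {
  A <- matrix(c(0.5, 0.5, 0.2, 0.8), 2, byrow = TRUE)
  expect_equal(mean_state_duration(A, 1)$windows, 2)
  A2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  d <- mean_state_duration(A2, 1)
  expect_equal(d$windows, 10)
  expect_equal(d$seconds, 1.0)
  A3 <- matrix(c(0, 1, 0.5, 0.5), 2, byrow = TRUE)
  expect_equal(mean_state_duration(A3, 1)$windows, 1)
  A4 <- diag(2)
  expect_error(mean_state_duration(A4, 1), "infinite")
})

test_that("singleton-subset Monte Carlo durations bracket the closed form", {
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  d <- subset_duration_statistics(A, 1, N = 2000, n_mc = 500, seed = 9)
  dur <- d[d$statistic == "duration", ]
  expect_true(dur$lo_windows <= 10 && 10 <= dur$hi_windows)
  expect_equal(dur$median_windows, 10, tolerance = 0.1)
})

test_that("subset durations and intervals are complementary", {
  # two-state alternating case: interval of {1} is the duration of {2}
  A <- matrix(c(0.85, 0.15, 0.1, 0.9), 2, byrow = TRUE)
  d1 <- subset_duration_statistics(A, 1, N = 2000, n_mc = 400, seed = 10)
  d2 <- subset_duration_statistics(A, 2, N = 2000, n_mc = 400, seed = 10)
  int1 <- d1[d1$statistic == "interval", ]$median_windows
  dur2 <- d2[d2$statistic == "duration", ]$median_windows
  expect_equal(int1, dur2, tolerance = 1e-12)
  # K = 3: interval of all-but-one state equals the duration of that state
  A3 <- matrix(c(0.8, 0.1, 0.1,
                 0.15, 0.8, 0.05,
                 0.05, 0.1, 0.85), 3, byrow = TRUE)
  da <- subset_duration_statistics(A3, c(1, 2), N = 2000, n_mc = 400,
                                   seed = 11)
  db <- subset_duration_statistics(A3, 3, N = 2000, n_mc = 400, seed = 11)
  expect_equal(da[da$statistic == "interval", ]$median_windows,
               db[db$statistic == "duration", ]$median_windows,
               tolerance = 1e-12)
})

test_that("duration statistics are reproducible and validate inputs", {
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  d1 <- subset_duration_statistics(A, 1, n_mc = 100, seed = 12)
  d2 <- subset_duration_statistics(A, 1, n_mc = 100, seed = 12)
  expect_identical(d1, d2)
  expect_error(subset_duration_statistics(A, c(1, 2), n_mc = 10, seed = 1),
               "proper subset")
  expect_error(subset_duration_statistics(A, integer(0), n_mc = 10, seed = 1),
               "subset")
})

test_that("pairwise delta table covers all bands and state pairs", {
  m <- random_model(3, 2, seed = 13)
  tab <- delta_probability_table(m)
  expect_equal(nrow(tab), 2 * 3 * 2)   # H * K * (K-1)
  expect_true(all(tab$pr_delta_le_0 >= 0 & tab$pr_delta_le_0 <= 1))
  # complement identity within the table
  for (h in unique(tab$band)) {
    sub <- tab[tab$band == h, ]
    p12 <- sub$pr_delta_le_0[sub$state_j == 1 & sub$state_k == 2]
    p21 <- sub$pr_delta_le_0[sub$state_j == 2 & sub$state_k == 1]
    expect_equal(p12 + p21, 1, tolerance = 5e-4)
  }
})
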