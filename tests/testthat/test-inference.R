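test_that("forward-backward matches exhaustive path enumeration", {
  for (seed in 1:5) {
    m <- random_model(2, 3, seed = seed)
    set.seed(seed + 100)
    Y <- matrix(stats::runif(6 * 3, 0.05, 0.95), 6, 3)
    fb <- forward_backward(Y, m)
    bf <- brute_force_hmm(Y, m)
    expect_equal(fb$loglik, bf$loglik, tolerance = 1e-10)
    expect_equal(rowSums(fb$gamma), rep(1, 6), tolerance = 1e-12)
    xi_n_sums <- apply(fb$xi, 1, sum)
    expect_equal(xi_n_sums, rep(1, 5), tolerance = 1e-12)
    expect_equal(apply(fb$xi, 2:3, sum), fb$xi_sum, tolerance = 1e-12)
  }
})

test_that("single-state and absorbing-start degenerate cases", {
  m1 <- random_model(1, 2, seed = 1)
  set.seed(2)
  Y <- matrix(stats::runif(20, 0.1, 0.9), 10, 2)
  fb <- forward_backward(Y, m1)
  expect_true(all(fb$gamma == 1))
  expect_equal(fb$loglik, sum(emission_logdensity(Y, m1)[, 1]),
               tolerance = 1e-10)
  # identity dynamics with a deterministic start pin the posterior
  m2 <- random_model(2, 2, seed = 3)
  m2$A <- diag(2); m2$pi <- c(1, 0)
  fb2 <- forward_backward(Y, m2)
  expect_equal(fb2$gamma[, 1], rep(1, 10), tolerance = 1e-12)
})

test_that("forward-backward stays finite on long sequences", {
  m <- random_model(3, 5, seed = 4)
  sim <- simulate_obs(m, 10000, seed = 5)
  fb <- forward_backward(sim$Y, m, return_xi = FALSE)
  expect_true(is.finite(fb$loglik))
  expect_equal(range(rowSums(fb$gamma)), c(1, 1), tolerance = 1e-9)
})

test_that("viterbi equals the exhaustive argmax path on small instances", {
  for (seed in 1:5) {
    K <- 2
    m <- random_model(K, 2, seed = seed + 20)
    N <- sample(4:8, 1)
    set.seed(seed + 200)
    Y <- matrix(stats::runif(N * 2, 0.05, 0.95), N, 2)
    v <- viterbi(Y, m)
    bf <- brute_force_hmm(Y, m)
    logB <- emission_logdensity(Y, m)
    lp <- log(m$pi[v$state[1]]) +
      sum(log(m$A[cbind(v$state[-N], v$state[-1])])) +
      sum(logB[cbind(seq_len(N), v$state)])
    expect_equal(lp, bf$best_logp, tolerance = 1e-10)
  }
})

test_that("viterbi degenerate dynamics and tie-breaking", {
  m1 <- random_model(1, 2, seed = 6)
  set.seed(7)
  Y <- matrix(stats::runif(12, 0.2, 0.8), 6, 2)
  expect_true(all(viterbi(Y, m1)$state == 1))
  # identical emissions across states, identity dynamics, start in state 2
  m2 <- random_model(2, 2, seed = 8)
  m2$a[2, ] <- m2$a[1, ]; m2$b[2, ] <- m2$b[1, ]
  m2$A <- diag(2); m2$pi <- c(0, 1)
  expect_true(all(viterbi(Y, m2)$state == 2))
  # full tie (identical emissions, uniform dynamics): lower state index wins
  m3 <- m2
  m3$A <- matrix(0.5, 2, 2); m3$pi <- c(0.5, 0.5)
  expect_true(all(viterbi(Y, m3)$state == 1))
})

test_that("weighted beta MLE recovers parameters and honors weights", {
  set.seed(30)
  y <- stats::rbeta(50000, 3, 5)
  ab <- weighted_beta_mle(y)
  expect_lt(abs(ab["a"] - 3) / 3, 0.02)
  expect_lt(abs(ab["b"] - 5) / 5, 0.02)
  # indicator weights equal the unweighted MLE on the subset
  set.seed(31)
  y2 <- stats::rbeta(400, 2, 4)
  w <- rep(c(1, 0), 200)
  expect_equal(weighted_beta_mle(y2, w), weighted_beta_mle(y2[w == 1]),
               tolerance = 1e-8)
  expect_error(weighted_beta_mle(rep(0.4, 50)), "degenerate")
  expect_error(weighted_beta_mle(c(0, 0.5)), "strictly")
})

test_that("beta MLE beats a dense parameter grid", {
  set.seed(32)
  y <- stats::rbeta(200, 1.7, 6)
  ab <- weighted_beta_mle(y)
  ll <- function(a, b) sum(stats::dbeta(y, a, b, log = TRUE))
  grid <- expand.grid(a = seq(0.1, 20, length.out = 60),
                      b = seq(0.1, 20, length.out = 60))
  grid_best <- max(mapply(ll, grid$a, grid$b))
  expect_gte(ll(ab["a"], ab["b"]) + 1e-8, grid_best)
  # stationarity of the weighted gradient
  g <- c(mean(log(y)) - digamma(ab["a"]) + digamma(sum(ab)),
         mean(log1p(-y)) - digamma(ab["b"]) + digamma(sum(ab)))
  expect_lt(sqrt(sum(g^2)), 1e-6)
})

test_that("EM recovers a well-separated two-state model", {
  m <- raw_model(pi = c(0.6, 0.4),
                 A = matrix(c(0.9, 0.1, 0.15, 0.85), 2, byrow = TRUE),
                 a = matrix(c(8, 3, 2, 3), 2, 2),
                 b = matrix(c(2, 3, 8, 3), 2, 2))
  sim <- simulate_obs(m, 2000, seed = 40)
  fit <- fit_beta_hmm(sim$Y, 2, n_restarts = 2, seed = 1,
                      canonical_order = FALSE)
  perm <- align_labels(sim$z, viterbi(sim$Y, fit$model)$state, 2)
  inv <- order(perm)
  expect_lt(max(abs(fit$model$A[inv, inv] - m$A)), 0.05)
  expect_true(all(diff(fit$loglik_trace) >
                    -1e-8 * (abs(fit$loglik_trace[-1]) + 1)))
})

test_that("K = 1 EM degenerates to the unweighted beta MLE per band", {
  set.seed(41)
  Y <- cbind(stats::rbeta(500, 3, 2), stats::rbeta(500, 1.5, 4))
  fit <- fit_beta_hmm(Y, 1, n_restarts = 1, seed = 1)
  expect_equal(fit$model$A, matrix(1))
  expect_equal(fit$model$pi, 1)
  for (h in 1:2) {
    ab <- weighted_beta_mle(Y[, h])
    expect_equal(unname(fit$model$a[1, h]), unname(ab["a"]), tolerance = 1e-5)
    expect_equal(unname(fit$model$b[1, h]), unname(ab["b"]), tolerance = 1e-5)
  }
})

test_that("duplicated sessions leave the ratio-form M-steps unchanged", {
  m <- random_model(2, 2, seed = 42)
  sim <- simulate_obs(m, 400, seed = 43)
  init <- random_model(2, 2, seed = 44)
  f1 <- fit_beta_hmm(sim$Y, 2, init = init, max_iter = 50,
                     canonical_order = FALSE)
  f2 <- fit_beta_hmm(list(sim$Y, sim$Y), 2, init = init, max_iter = 50,
                     canonical_order = FALSE)
  expect_equal(f2$model$A, f1$model$A, tolerance = 1e-10)
  expect_equal(f2$model$a, f1$model$a, tolerance = 1e-10)
  expect_equal(f2$model$b, f1$model$b, tolerance = 1e-10)
  # pi is the average of identical first-window posteriors
  expect_equal(f2$model$pi, f1$model$pi, tolerance = 1e-10)
  # total log-likelihood doubles with the duplicated session
  expect_equal(f2$loglik_trace[length(f2$loglik_trace)],
               2 * f1$loglik_trace[length(f1$loglik_trace)],
               tolerance = 1e-8)
})

test_that("EM log-likelihood is monotone on random datasets", {
  for (seed in 1:10) {
    m <- random_model(sample(2:3, 1), 2, seed = seed + 50)
    sim <- simulate_obs(m, 300, seed = seed + 60)
    fit <- fit_beta_hmm(sim$Y, m$K, n_restarts = 1, seed = seed,
                        max_iter = 40, canonical_order = FALSE)
    expect_true(all(diff(fit$loglik_trace) >
                      -1e-8 * (abs(fit$loglik_trace[-1]) + 1)))
  }
})

test_that("parameter recovery improves with sequence length", {
  m <- raw_model(pi = c(0.5, 0.5),
                 A = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
                 a = matrix(c(6, 2, 2, 4), 2, 2),
                 b = matrix(c(2, 2, 6, 4), 2, 2))
  errs <- vapply(c(500, 2000, 8000), function(N) {
    sim <- simulate_obs(m, N, seed = 70)
    fit <- fit_beta_hmm(sim$Y, 2, n_restarts = 2, seed = 2,
                        canonical_order = FALSE)
    perm <- align_labels(sim$z, viterbi(sim$Y, fit$model)$state, 2)
    inv <- order(perm)
    max(abs(fit$model$A[inv, inv] - m$A))
  }, 0)
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.03)
})

test_that("fit results expose tidy and glance summaries", {
  m <- random_model(2, 3, seed = 80)
  sim <- simulate_obs(m, 300, seed = 81)
  fit <- fit_beta_hmm(sim$Y, 2, n_restarts = 1, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * 3)
  expect_true(all(td$pr_above_median >= 0 & td$pr_above_median <= 1))
  gl <- glance(fit)
  expect_equal(gl$K, 2)
  expect_true(is.finite(gl$loglik))
})
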