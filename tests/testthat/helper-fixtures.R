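# shared fixtures: all built in code at test time

# a valid random beta-HMM with well-behaved shapes
random_model <- function(K, H, seed) {
  set.seed(seed)
  A <- matrix(stats::rgamma(K * K, 2), K, K)
  A <- A / rowSums(A)
  pi <- stats::rgamma(K, 2); pi <- pi / sum(pi)
  a <- matrix(stats::runif(K * H, 1.2, 8), K, H)
  b <- matrix(stats::runif(K * H, 1.2, 8), K, H)
  beta_hmm(pi = pi, A = A, a = a, b = b)
}

# observations drawn from a model's generative process
simulate_obs <- function(model, N, seed) {
  set.seed(seed)
  z <- sample_markov_chain(model$pi, model$A, N)
  Y <- matrix(0, N, model$H)
  for (h in seq_len(model$H)) {
    Y[, h] <- stats::rbeta(N, model$a[z, h], model$b[z, h])
  }
  Y <- pmin(pmax(Y, 1e-12), 1 - 1e-12)
  list(Y = Y, z = z)
}

# exhaustive-path log-likelihood and best path for small N (independent oracle)
brute_force_hmm <- function(Y, model) {
  logB <- emission_logdensity(Y, model)
  N <- nrow(Y); K <- model$K
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  logp <- apply(paths, 1, function(p) {
    lp <- log(model$pi[p[1]]) + sum(logB[cbind(seq_len(N), p)])
    if (N > 1) lp <- lp + sum(log(model$A[cbind(p[-N], p[-1])]))
    lp
  })
  m <- max(logp)
  list(loglik = m + log(sum(exp(logp - m))),
       best_path = paths[which.max(logp), ],
       best_logp = max(logp))
}

# a bare emission-only model structure that skips constructor validation
# (used to evaluate densities at boundary parameter values like (1,1))
raw_model <- function(pi, A, a, b) {
  K <- length(pi); H <- ncol(a)
  structure(list(K = K, H = H, pi = pi, A = A, a = a, b = b,
                 bands = tibble::tibble(band = paste0("band", seq_len(H))),
                 window_step = 0.1, relabel = seq_len(K)),
            class = "beta_hmm")
}

# band-power tibble built directly from a matrix (bypasses the spectrogram)
fake_band_power <- function(vals, step = 0.1) {
  H <- ncol(vals)
  bands <- canonical_bands()[seq_len(H), ]
  colnames(vals) <- bands$band
  out <- dplyr::bind_cols(
    tibble::tibble(time = seq_len(nrow(vals)) * step),
    tibble::as_tibble(as.data.frame(vals)))
  attr(out, "bands") <- bands
  attr(out, "window_step") <- step
  out
}

# synthetic two-state alternating voltage trace (slow vs gamma oscillation)
# with per-window ground-truth labels
two_state_signal <- function(seconds = 120, fs = 250, diag_p = 0.99,
                             seed = 11) {
  set.seed(seed)
  n_steps <- seconds * 10                       # 0.1 s resolution
  dyn <- default_dynamics(2, diag_p = diag_p)
  z <- sample_markov_chain(c(0.5, 0.5), dyn$A, n_steps)
  seg <- fs %/% 10
  freq <- ifelse(rep(z, each = seg) == 1, 3, 40)
  amp <- ifelse(rep(z, each = seg) == 1, 30, 20)
  x <- amp * sin(2 * pi * cumsum(freq) / fs) +
    stats::rnorm(length(freq), 0, 5)
  list(samples = x, fs = fs, z_fine = z, label = "synthetic2state")
}

label_windows <- function(times, z_fine, step = 0.1) {
  z_fine[pmin(pmax(round(times / step), 1), length(z_fine))]
}
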