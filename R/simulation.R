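#' Default band-power profiles for synthetic spectral states
#'
#' Builds K distinct, well-separated spectral profiles over a band set: each
#' state elevates a characteristic subset of bands by `gap` dB above a common
#' baseline, echoing how band-limited oscillatory states such as slow-delta
#' versus gamma activity each dominate a distinct part of the spectrum. The
#' subsets are cyclic balanced binary codes (band h is elevated in state k iff
#' `(h + k) mod K < ceiling(K/2)`): any two states differ by the full `gap`
#' in at least one band, and every band is elevated in roughly half of the
#' states, so each band's power sequence has a genuine interquartile spread
#' under uniform state occupancy.
#'
#' @param K Number of states (at most H with the default 7 bands).
#' @param H Number of bands.
#' @param gap Elevation above baseline in dB (default 8).
#' @param base Baseline band power in dB (default -10).
#' @return K x H matrix of mean band power in dB.
#' @export
default_band_profiles <- function(K, H = 7, gap = 8, base = -10) {
  stopifnot(K >= 1, K <= H)
  prof <- matrix(base, K, H)
  for (k in seq_len(K)) {
    for (h in seq_len(H)) {
      if (((h + k) %% K) < ceiling(K / 2)) prof[k, h] <- base + gap
    }
  }
  prof
}

#' Synthetic seed spectrogram with known latent labels
#'
#' Generates a spectrogram whose windows are drawn from K labeled spectral
#' profiles with i.i.d. Gaussian noise (in dB) per frequency bin; labels are
#' i.i.d. uniform over states. This stands in for a real recording's
#' spectrogram as the raw material that [cluster_spectra()] and
#' [simulate_spectrogram()] resample; it is synthetic and carries no temporal
#' dependence.
#'
#' @param K Number of latent profiles.
#' @param N Number of windows.
#' @param band_profiles K x H matrix of per-band mean dB
#'   (default [default_band_profiles()]).
#' @param noise_sd Noise standard deviation in dB (default 1.5).
#' @param bands Band definition tibble.
#' @param freqs Frequency grid in Hz (default 0.25 to 49.75 by 0.5).
#' @param window_step Window step in seconds carried as metadata.
#' @param seed Integer seed.
#' @return A list with `spectrogram` (a `spectrogram` object) and `labels`
#'   (length-N integer vector).
#' @export
synthetic_seed_spectrogram <- function(K, N, band_profiles = NULL,
                                       noise_sd = 1.5,
                                       bands = canonical_bands(),
                                       freqs = seq(0.25, 49.75, by = 0.5),
                                       window_step = 0.1, seed = 1) {
  bands <- validate_bands(bands)
  H <- nrow(bands)
  if (is.null(band_profiles)) band_profiles <- default_band_profiles(K, H)
  stopifnot(nrow(band_profiles) == K, ncol(band_profiles) == H)
  set.seed(seed)
  labels <- sample.int(K, N, replace = TRUE)
  band_of_bin <- rep(NA_integer_, length(freqs))
  for (h in seq_len(H)) {
    band_of_bin[freqs >= bands$lo[h] & freqs < bands$hi[h]] <- h
  }
  if (any(is.na(band_of_bin))) stop("frequency grid extends outside the bands")
  mean_by_bin <- band_profiles[, band_of_bin, drop = FALSE]  # K x F
  power <- mean_by_bin[labels, , drop = FALSE] +
    matrix(stats::rnorm(N * length(freqs), 0, noise_sd), N, length(freqs))
  spec <- new_spectrogram(power, window_times = seq_len(N) * window_step,
                          frequencies = freqs, window_length = 1,
                          overlap_fraction = 1 - window_step, fs = 2 * max(freqs) + 1)
  list(spectrogram = spec, labels = labels)
}

#' Cluster spectrogram windows into K spectral clusters
#'
#' Unsupervised k-means (seeded, 10 restarts) on the logistically scaled band
#' powers of each window, ignoring temporal order. Used to carve a source
#' spectrogram into the K spectral classes that Markov-switching simulation
#' resamples from.
#'
#' @param spec A `spectrogram`.
#' @param K Number of clusters.
#' @param bands Band definition tibble.
#' @param seed Integer seed; on an empty cluster the call is re-seeded up to
#'   10 times before erroring.
#' @return Integer vector of cluster labels (length = windows).
#' @export
cluster_spectra <- function(spec, K, bands = canonical_bands(), seed = 1) {
  stopifnot(inherits(spec, "spectrogram"), K >= 1)
  if (nrow(spec$power_db) < 10 * K) {
    stop("need at least 10*K windows to cluster")
  }
  bp <- band_power(spec, bands)
  Y <- obs_matrix(scale_observations(bp, compute_scaling(bp)))
  if (K == 1) return(rep(1L, nrow(Y)))
  for (attempt in 0:9) {
    set.seed(seed + attempt)
    km <- tryCatch(stats::kmeans(Y, centers = K, nstart = 10, iter.max = 100),
                   error = function(e) NULL)
    if (!is.null(km) && all(tabulate(km$cluster, K) > 0)) return(km$cluster)
  }
  stop("k-means produced an empty cluster after 10 re-seeds")
}

#' Sample a first-order Markov chain
#'
#' @param pi Initial state probabilities.
#' @param A Row-stochastic transition matrix.
#' @param M Chain length.
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @return Integer vector of states in `1:K`.
#' @export
sample_markov_chain <- function(pi, A, M, seed = NULL) {
  A <- as.matrix(A)
  K <- length(pi)
  stopifnot(all(dim(A) == K), M >= 1,
            abs(sum(pi) - 1) < 1e-8, all(abs(rowSums(A) - 1) < 1e-8),
            all(pi >= 0), all(A >= 0))
  if (!is.null(seed)) set.seed(seed)
  z <- integer(M)
  cum_pi <- cumsum(pi); cum_pi[K] <- 1
  cumA <- t(apply(A, 1, cumsum)); cumA[, K] <- 1
  u <- stats::runif(M)
  z[1] <- findInterval(u[1], cum_pi, left.open = TRUE) + 1L
  for (m in seq_len(M - 1) + 1L) {
    z[m] <- findInterval(u[m], cumA[z[m - 1L], ], left.open = TRUE) + 1L
  }
  z
}

#' Simulate a Markov-switching spectrogram by resampling spectral clusters
#'
#' Given a source spectrogram carved into K spectral clusters, draws a latent
#' Markov path of length M and, for each instant, copies the spectrum of a
#' uniformly sampled source window from the active state's cluster. The
#' simulated spectrogram is then reduced to scaled observations through the
#' standard spectral pipeline (band averaging, quartile scaling estimated on
#' the simulated sequence itself).
#'
#' @param spec Source `spectrogram`.
#' @param labels Cluster labels for the source windows (from
#'   [cluster_spectra()] or known ground truth).
#' @param pi,A Generating initial distribution and transition matrix.
#' @param M Number of simulated windows.
#' @param bands Band definition tibble.
#' @param seed Integer seed.
#' @return A list of class `sim_ground_truth`: `z` (true path), `spectrogram`
#'   (simulated), `Y` (scaled-observation tibble), `pi`, `A`, `labels`
#'   (source cluster assignment), `seed`.
#' @export
simulate_spectrogram <- function(spec, labels, pi, A, M,
                                 bands = canonical_bands(), seed = 1) {
  stopifnot(inherits(spec, "spectrogram"),
            length(labels) == nrow(spec$power_db))
  K <- length(pi)
  idx_by_cluster <- split(seq_along(labels), labels)
  if (length(idx_by_cluster) < K) stop("some clusters are empty")
  set.seed(seed)
  z <- sample_markov_chain(pi, A, M)
  rows <- vapply(z, function(k) {
    pool <- idx_by_cluster[[k]]
    pool[sample.int(length(pool), 1)]
  }, 1L)
  sim_spec <- new_spectrogram(
    spec$power_db[rows, , drop = FALSE],
    window_times = seq_len(M) * spec$window_step,
    frequencies = spec$frequencies,
    window_length = spec$window_length,
    overlap_fraction = spec$overlap_fraction, fs = spec$fs)
  bp <- band_power(sim_spec, bands)
  Y <- scale_observations(bp, compute_scaling(bp))
  structure(list(z = z, spectrogram = sim_spec, Y = Y, pi = pi, A = A,
                 labels = labels, source_rows = rows, seed = seed),
            class = "sim_ground_truth")
}

perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perms(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Optimal alignment of estimated state labels to ground truth
#'
#' HMM state labels are arbitrary, so estimated labels are matched to true
#' labels by the permutation maximizing the diagonal of the confusion matrix
#' (solved exactly by exhaustive search over permutations, equivalent to the
#' Hungarian assignment for these sizes; supported for K <= 8).
#'
#' @param z_true,z_est Integer state paths of equal length.
#' @param K Number of states.
#' @return Integer permutation `perm` such that `perm[z_est]` is aligned with
#'   `z_true`.
#' @export
align_labels <- function(z_true, z_est, K) {
  if (length(z_true) != length(z_est)) stop("paths differ in length")
  if (K > 8) stop("exhaustive label alignment supported for K <= 8")
  conf <- matrix(0, K, K)
  for (i in seq_along(z_true)) conf[z_est[i], z_true[i]] <-
      conf[z_est[i], z_true[i]] + 1
  P <- perms(K)
  scores <- apply(P, 1, function(p) sum(conf[cbind(seq_len(K), p)]))
  P[which.max(scores), ]
}

#' Fraction of windows where two state paths agree
#'
#' @param z_true,z_est Integer paths of equal length.
#' @param align Align labels first with [align_labels()] (default `TRUE`).
#' @return Accuracy in `[0, 1]`.
#' @export
path_accuracy <- function(z_true, z_est, align = TRUE) {
  if (length(z_true) != length(z_est)) stop("paths differ in length")
  if (align) {
    K <- max(z_true, z_est)
    z_est <- align_labels(z_true, z_est, K)[z_est]
  }
  mean(z_true == z_est)
}

#' Scaled L1 error between transition matrices
#'
#' `sum_jk |A_jk - Ahat_jk| / (2K)`, in `[0, 1]`. Label alignment, if wanted,
#' must be applied to `A_hat` beforehand.
#'
#' @param A,A_hat K x K transition matrices.
#' @return Error in `[0, 1]`.
#' @export
transition_error <- function(A, A_hat) {
  A <- as.matrix(A); A_hat <- as.matrix(A_hat)
  if (!all(dim(A) == dim(A_hat))) stop("dimension mismatch")
  sum(abs(A - A_hat)) / (2 * nrow(A))
}

#' Scaled L1 error between initial state distributions
#'
#' `sum_k |pi_k - pihat_k| / 2`, in `[0, 1]`.
#'
#' @param pi,pi_hat Length-K probability vectors.
#' @return Error in `[0, 1]`.
#' @export
initial_error <- function(pi, pi_hat) {
  if (length(pi) != length(pi_hat)) stop("dimension mismatch")
  sum(abs(pi - pi_hat)) / 2
}

#' Default generating dynamics for the simulation study
#'
#' Strongly diagonal transition matrix (`A_kk = 0.85`) with the off-diagonal
#' mass on the cyclic successor (state k hands over to k+1, wrapping around),
#' mimicking the sequential alternation of spectral states; the chain starts
#' deterministically in state 1.
#'
#' @param K Number of states.
#' @param diag_p Self-transition probability.
#' @return List with `pi` and `A`.
#' @export
default_dynamics <- function(K, diag_p = 0.85) {
  A <- matrix(0, K, K)
  diag(A) <- diag_p
  if (K > 1) {
    for (k in seq_len(K)) A[k, (k %% K) + 1] <- 1 - diag_p
  } else {
    A[1, 1] <- 1
  }
  list(pi = c(1, rep(0, K - 1)), A = A)
}

score_replicate <- function(gt, fit, path) {
  K <- length(gt$pi)
  Ymat <- obs_matrix(gt$Y)
  perm <- align_labels(gt$z, path$state, K)
  z_aligned <- perm[path$state]
  inv <- order(perm)   # aligned state k corresponds to fitted state inv[k]
  A_hat <- fit$model$A[inv, inv, drop = FALSE]
  pi_hat <- fit$model$pi[inv]
  # ground-truth emission betas: MLE per state/band on the windows the true
  # path assigns to each state
  ks_vals <- matrix(NA_real_, K, ncol(Ymat))
  for (k in seq_len(K)) {
    yk <- Ymat[gt$z == k, , drop = FALSE]
    for (h in seq_len(ncol(Ymat))) {
      ab_true <- weighted_beta_mle(yk[, h])
      ks_vals[k, h] <- ks_distance_beta(
        ab_true[1], ab_true[2],
        fit$model$a[inv[k], h], fit$model$b[inv[k], h], method = "exact")
    }
  }
  tibble::tibble(
    path_accuracy = mean(gt$z == z_aligned),
    mean_ks = mean(ks_vals),
    eps_A = transition_error(gt$A, A_hat),
    eps_pi = initial_error(gt$pi, pi_hat),
    loglik = fit$loglik_trace[length(fit$loglik_trace)],
    converged = fit$converged
  )
}

#' Ground-truth recovery study for the beta-HMM
#'
#' For each model order K: build (or accept) a seed spectrogram with K
#' spectral classes, carve it into K clusters, then repeatedly simulate a
#' Markov-switching spectrogram, fit a K-state beta-HMM to its scaled
#' observations, decode the Viterbi path, and score the fit against the known
#' ground truth: path accuracy after optimal label alignment, mean exact KS
#' distance between true and fitted per-state per-band beta emissions, and the
#' scaled L1 errors of the transition matrix and initial distribution.
#'
#' @param K_values Integer vector of model orders (default `2:5`).
#' @param reps Replicates per K (default 25).
#' @param M Simulated sequence length (default 2000 windows).
#' @param seed Integer master seed; every source of randomness derives from it.
#' @param noise_sd Seed-spectrogram noise in dB (default 1.5).
#' @param gap Profile separation in dB (default 8).
#' @param N_seed Windows in each seed spectrogram (default 1500).
#' @param diag_p Generating self-transition probability (default 0.85).
#' @param n_restarts EM restarts per fit (default 1; the k-means
#'   initialization is reliable for well-separated profiles).
#' @param progress Print one line per K when `TRUE`.
#' @return A tibble with one row per (K, replicate): accuracy metrics plus
#'   fit diagnostics. Failed fits are recorded with `NA` metrics rather than
#'   aborting the study.
#' @export
run_simulation_study <- function(K_values = 2:5, reps = 25, M = 2000,
                                 seed = 1, noise_sd = 1.5, gap = 8,
                                 N_seed = 1500, diag_p = 0.85,
                                 n_restarts = 1, progress = FALSE) {
  stopifnot(reps >= 1)
  out <- list()
  for (K in K_values) {
    seed_K <- seed + 1000L * K
    seedspec <- synthetic_seed_spectrogram(
      K, N = N_seed, noise_sd = noise_sd,
      band_profiles = default_band_profiles(K, gap = gap), seed = seed_K)
    labels <- cluster_spectra(seedspec$spectrogram, K, seed = seed_K + 1)
    dyn <- default_dynamics(K, diag_p)
    for (r in seq_len(reps)) {
      rep_seed <- seed_K + 10L * r
      row <- tryCatch({
        gt <- simulate_spectrogram(seedspec$spectrogram, labels, dyn$pi,
                                   dyn$A, M, seed = rep_seed)
        fit <- fit_beta_hmm(gt$Y, K, n_restarts = n_restarts,
                            seed = rep_seed + 1, canonical_order = FALSE)
        path <- viterbi(gt$Y, fit$model)
        score_replicate(gt, fit, path)
      }, error = function(e) {
        tibble::tibble(path_accuracy = NA_real_, mean_ks = NA_real_,
                       eps_A = NA_real_, eps_pi = NA_real_,
                       loglik = NA_real_, converged = NA,
                       error = conditionMessage(e))
      })
      out[[length(out) + 1]] <- dplyr::mutate(row, K = K, rep = r,
                                              .before = 1)
    }
    if (progress) {
      done <- dplyr::bind_rows(out)
      dK <- done[done$K == K, ]
      message(sprintf("K = %d: min acc %.4f, max mean KS %.2e, max eps_A %.2e",
                      K, min(dK$path_accuracy), max(dK$mean_ks),
                      max(dK$eps_A)))
    }
  }
  dplyr::bind_rows(out)
}

#' Per-K summary of a simulation study
#'
#' Medians with central 90% intervals of each accuracy metric by model order.
#'
#' @param study Tibble from [run_simulation_study()].
#' @return A tibble with one row per K and metric.
#' @export
summarize_simulation_study <- function(study) {
  study |>
    tidyr::pivot_longer(c("path_accuracy", "mean_ks", "eps_A", "eps_pi"),
                        names_to = "metric") |>
    dplyr::group_by(.data$K, .data$metric) |>
    dplyr::summarize(
      median = stats::median(.data$value, na.rm = TRUE),
      lo05 = stats::quantile(.data$value, 0.05, na.rm = TRUE, names = FALSE),
      hi95 = stats::quantile(.data$value, 0.95, na.rm = TRUE, names = FALSE),
      n_failed = sum(is.na(.data$value)),
      .groups = "drop"
    )
}
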