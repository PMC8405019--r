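#' Forward-backward (Baum-Welch E-step) for one sequence
#'
#' Runs the scaled forward-backward recursions for a single scaled-observation
#' sequence under a beta-HMM. Per-window scaling constants (with a per-window
#' shift of the log emission densities) keep the recursion stable for long
#' sequences.
#'
#' @param Y N x H observation matrix or scaled-observation tibble.
#' @param model A `beta_hmm`.
#' @param return_xi If `TRUE` (default) also return the full (N-1) x K x K
#'   array of pairwise posteriors; the summed K x K version is always returned.
#' @return A list with `gamma` (N x K posterior state probabilities), `xi`
#'   ((N-1) x K x K, or `NULL`), `xi_sum` (K x K), and `loglik`.
#' @export
forward_backward <- function(Y, model, return_xi = TRUE) {
  viol <- validate_beta_hmm(model)
  if (length(viol)) stop("invalid model: ", paste(viol, collapse = "; "))
  logB <- emission_logdensity(Y, model)
  N <- nrow(logB); K <- model$K
  shift <- apply(logB, 1, max)
  B <- exp(logB - shift)                      # N x K, max 1 per row
  A <- model$A
  alpha <- matrix(0, N, K)
  cvec <- numeric(N)
  a1 <- model$pi * B[1, ]
  cvec[1] <- sum(a1)
  if (cvec[1] <= 0) stop("zero likelihood at window 1")
  alpha[1, ] <- a1 / cvec[1]
  for (n in 2:N) {
    an <- (alpha[n - 1, ] %*% A) * B[n, ]
    cvec[n] <- sum(an)
    if (cvec[n] <= 0) stop("zero likelihood at window ", n)
    alpha[n, ] <- an / cvec[n]
  }
  beta <- matrix(0, N, K)
  beta[N, ] <- 1
  for (n in (N - 1):1) {
    bn <- A %*% (B[n + 1, ] * beta[n + 1, ]) / cvec[n + 1]
    beta[n, ] <- bn
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  # xi_n(j,k) = alpha_n(j) A_jk B_{n+1}(k) beta_{n+1}(k) / c_{n+1}
  w <- B[-1, , drop = FALSE] * beta[-1, , drop = FALSE] / cvec[-1]
  xi_sum <- A * (t(alpha[-N, , drop = FALSE]) %*% w)
  xi <- NULL
  if (return_xi && N >= 2) {
    xi <- array(0, c(N - 1, K, K))
    for (n in seq_len(N - 1)) {
      xn <- A * outer(alpha[n, ], w[n, ])
      xi[n, , ] <- xn / sum(xn)
    }
  }
  list(gamma = gamma, xi = xi, xi_sum = xi_sum,
       loglik = sum(log(cvec)) + sum(shift))
}

#' Viterbi decoding of the most probable state path
#'
#' Dynamic program in log space; ties are broken toward the lower state index.
#'
#' @param Y N x H observation matrix or scaled-observation tibble.
#' @param model A `beta_hmm`.
#' @return A tibble with columns `window`, `time` (if available) and `state`.
#' @export
viterbi <- function(Y, model) {
  viol <- validate_beta_hmm(model)
  if (length(viol)) stop("invalid model: ", paste(viol, collapse = "; "))
  times <- if (is.data.frame(Y) && "time" %in% names(Y)) Y$time else NULL
  logB <- emission_logdensity(Y, model)
  N <- nrow(logB); K <- model$K
  logA <- log(model$A)
  delta <- log(model$pi) + logB[1, ]
  psi <- matrix(0L, N, K)
  for (n in 2:N) {
    cand <- delta + logA                      # K x K: cand[j,k]
    psi[n, ] <- apply(cand, 2, which.max)     # which.max takes lowest on ties
    delta <- cand[cbind(psi[n, ], seq_len(K))] + logB[n, ]
  }
  z <- integer(N)
  z[N] <- which.max(delta)
  for (n in (N - 1):1) z[n] <- psi[n + 1, z[n + 1]]
  out <- tibble::tibble(window = seq_len(N), state = z)
  if (!is.null(times)) out <- dplyr::mutate(out, time = times, .after = "window")
  attr(out, "window_step") <- model$window_step
  out
}

#' Weighted maximum likelihood estimation of beta shape parameters
#'
#' Maximizes the weighted beta log likelihood by Newton iterations on the
#' digamma stationarity conditions, starting from the weighted
#' method-of-moments estimate. The unimodality restriction is enforced by
#' projection: if the optimum lands with both shapes at or below 1, the larger
#' one is lifted to `1 + 1e-6`.
#'
#' @param y Numeric vector of observations in (0,1).
#' @param w Nonnegative weights (default all 1).
#' @param max_iter Maximum Newton iterations.
#' @param tol Gradient-norm convergence threshold.
#' @return Named numeric vector `c(a = , b = )`.
#' @export
weighted_beta_mle <- function(y, w = rep(1, length(y)), max_iter = 200,
                              tol = 1e-8) {
  stopifnot(length(y) == length(w), all(w >= 0))
  if (any(y <= 0 | y >= 1)) stop("observations must lie strictly in (0,1)")
  W <- sum(w)
  if (W <= 0) stop("weights sum to zero")
  m1 <- sum(w * y) / W
  v <- sum(w * (y - m1)^2) / W
  if (v < .Machine$double.eps * 100) stop("degenerate sample: zero variance")
  slog <- sum(w * log(y)) / W
  slog1 <- sum(w * log1p(-y)) / W
  common <- max(m1 * (1 - m1) / v - 1, 1e-3)
  theta <- log(c(m1, 1 - m1) * common)        # optimize in log(a), log(b)
  obj <- function(th) {
    ab <- exp(th)
    ab[1] * slog + ab[2] * slog1 - lbeta(ab[1], ab[2])
  }
  f <- obj(theta)
  for (it in seq_len(max_iter)) {
    ab <- exp(theta)
    g_ab <- c(slog - digamma(ab[1]) + digamma(sum(ab)),
              slog1 - digamma(ab[2]) + digamma(sum(ab)))
    if (sqrt(sum(g_ab^2)) < tol) break
    tg <- trigamma(sum(ab))
    Hess <- matrix(c(-trigamma(ab[1]) + tg, tg,
                     tg, -trigamma(ab[2]) + tg), 2, 2)
    step_ab <- tryCatch(-solve(Hess, g_ab), error = function(e) g_ab)
    # chain rule to log scale; fall back to gradient ascent direction
    step <- step_ab / ab
    g_th <- g_ab * ab
    if (sum(step * g_th) <= 0) step <- g_th / max(1, sqrt(sum(g_th^2)))
    s <- 1
    repeat {
      f_new <- obj(theta + s * step)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      s <- s / 2
      if (s < 1e-10) break
    }
    theta <- theta + s * step
    f <- obj(theta)
  }
  ab <- exp(theta)
  if (ab[1] <= 1 && ab[2] <= 1) {
    if (ab[1] >= ab[2]) ab[1] <- 1 + 1e-6 else ab[2] <- 1 + 1e-6
  }
  c(a = ab[1], b = ab[2])
}

as_sequence_list <- function(data) {
  if (is.matrix(data) || is.data.frame(data)) data <- list(data)
  lapply(data, obs_matrix)
}

init_model <- function(Ys, K, bands, window_step, seed) {
  Yall <- do.call(rbind, Ys)
  H <- ncol(Yall)
  set.seed(seed)
  if (K == 1) {
    centers <- matrix(colMeans(Yall), 1)
    cl <- rep(1L, nrow(Yall))
  } else {
    km <- stats::kmeans(Yall, centers = K, nstart = 5, iter.max = 50)
    cl <- km$cluster
  }
  a <- matrix(2, K, H); b <- matrix(2, K, H)
  for (k in seq_len(K)) {
    yk <- Yall[cl == k, , drop = FALSE]
    for (h in seq_len(H)) {
      m1 <- mean(yk[, h]); v <- stats::var(yk[, h])
      if (!is.finite(v) || v < 1e-8) v <- 1e-4
      common <- max(m1 * (1 - m1) / v - 1, 0.5)
      ah <- m1 * common; bh <- (1 - m1) * common
      if (ah <= 1 && bh <= 1) { if (ah >= bh) ah <- 1 + 1e-6 else bh <- 1 + 1e-6 }
      a[k, h] <- max(ah, 1e-3); b[k, h] <- max(bh, 1e-3)
    }
  }
  A <- matrix(0.2 / K, K, K)
  diag(A) <- diag(A) + 0.8
  beta_hmm(pi = rep(1 / K, K), A = A, a = a, b = b, bands = bands,
           window_step = window_step)
}

#' Fit a beta-HMM by expectation-maximization
#'
#' Fits a K-state beta-HMM to one or more scaled-observation sequences.
#' Sequences are treated as mutually independent recording sessions: they are
#' never concatenated; the E-step is run per sequence and sufficient
#' statistics are pooled in the M-step. The initial distribution is the
#' average of the per-session first-window posteriors, the transition matrix
#' comes from pooled pairwise posteriors, and the emission shapes from pooled
#' responsibility-weighted beta MLE. Initialization is seeded k-means on the
#' pooled observations with method-of-moments emission estimates; the best of
#' `n_restarts` runs (by final log likelihood) is returned.
#'
#' @param data One sequence (matrix or scaled-observation tibble) or a list of
#'   them, all with the same bands.
#' @param K Number of states.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param n_restarts Number of random restarts.
#' @param seed Integer seed controlling initialization.
#' @param canonical_order Relabel states by ascending highest-band beta mean
#'   after fitting (default `TRUE`); the permutation is recorded in the model.
#' @param init Optional `beta_hmm` to start EM from; when supplied,
#'   `n_restarts` is ignored and a single run is performed.
#' @return An object of class `beta_hmm_fit`: list with `model`,
#'   `loglik_trace`, `n_iterations`, `converged`, `seed`, `posteriors` (list of
#'   N_l x K gamma matrices) and `restart_logliks`.
#' @export
fit_beta_hmm <- function(data, K, max_iter = 500, tol = 1e-6, n_restarts = 5,
                         seed = 1, canonical_order = TRUE, init = NULL) {
  Ys <- as_sequence_list(data)
  stopifnot(K >= 1, length(Ys) >= 1)
  H <- unique(vapply(Ys, ncol, 1L))
  if (length(H) != 1) stop("sequences disagree on the number of bands")
  if (any(vapply(Ys, nrow, 1L) <= K)) stop("every sequence must be longer than K")
  first <- if (is.data.frame(data)) data else if (is.list(data) &&
    is.data.frame(data[[1]])) data[[1]] else data
  bands <- attr(first, "bands")
  window_step <- attr(first, "window_step") %||% 0.1
  best <- NULL
  restart_logliks <- numeric(0)
  if (!is.null(init)) n_restarts <- 1L
  sub_seeds <- seed + seq_len(n_restarts) - 1
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(
      em_once(Ys, K, max_iter, tol, bands, window_step, sub_seeds[r],
              init = init),
      error = function(e) NULL)
    if (is.null(fit)) { restart_logliks <- c(restart_logliks, -Inf); next }
    ll <- fit$loglik_trace[length(fit$loglik_trace)]
    restart_logliks <- c(restart_logliks, ll)
    if (is.null(best) || ll > best$loglik_trace[length(best$loglik_trace)]) {
      best <- fit
    }
  }
  if (is.null(best)) stop("all EM restarts failed to produce a finite likelihood")
  if (canonical_order && K > 1) {
    perm <- canonical_state_order(best$model)
    best$model <- relabel_states(best$model, perm)
    best$posteriors <- lapply(best$posteriors,
                              function(g) g[, perm, drop = FALSE])
  }
  best$seed <- seed
  best$restart_logliks <- restart_logliks
  class(best) <- "beta_hmm_fit"
  best
}

em_once <- function(Ys, K, max_iter, tol, bands, window_step, seed,
                    init = NULL) {
  model <- if (is.null(init)) init_model(Ys, K, bands, window_step, seed)
           else init
  L <- length(Ys)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    es <- lapply(Ys, forward_backward, model = model, return_xi = FALSE)
    ll <- sum(vapply(es, `[[`, 0, "loglik"))
    trace <- c(trace, ll)
    if (it > 1 && abs(ll - trace[it - 1]) <
        tol * (abs(trace[it - 1]) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    # M-step: pool sufficient statistics across the L independent sessions
    pi_new <- Reduce(`+`, lapply(es, function(e) e$gamma[1, ])) / L
    xi_tot <- Reduce(`+`, lapply(es, `[[`, "xi_sum"))
    A_new <- xi_tot / rowSums(xi_tot)
    a_new <- model$a; b_new <- model$b
    for (k in seq_len(K)) {
      wk <- unlist(lapply(es, function(e) e$gamma[, k]))
      if (sum(wk) < 1e-3) next   # empty state: keep previous shapes
      for (h in seq_len(model$H)) {
        yk <- unlist(lapply(Ys, function(Y) Y[, h]))
        ab <- tryCatch(weighted_beta_mle(yk, wk), error = function(e) NULL)
        if (!is.null(ab)) { a_new[k, h] <- ab[1]; b_new[k, h] <- ab[2] }
      }
    }
    model$pi <- pi_new; model$A <- A_new; model$a <- a_new; model$b <- b_new
  }
  es <- lapply(Ys, forward_backward, model = model, return_xi = FALSE)
  list(model = model, loglik_trace = trace, n_iterations = length(trace),
       converged = converged,
       posteriors = lapply(es, `[[`, "gamma"))
}

#' @export
print.beta_hmm_fit <- function(x, ...) {
  cat(sprintf(
    "<beta_hmm_fit> K = %d, %d iteration(s), %sconverged, log-likelihood %.4f\n",
    x$model$K, x$n_iterations, if (x$converged) "" else "NOT ",
    x$loglik_trace[length(x$loglik_trace)]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted beta-HMM
#'
#' One row per state and band: the beta shapes, the implied mean scaled power
#' and the probability that scaled power exceeds the median (0.5).
#'
#' @param x A `beta_hmm_fit` or `beta_hmm`.
#' @param ... Unused.
#' @return A tibble with columns `state`, `band`, `a`, `b`, `mean`,
#'   `pr_above_median`.
#' @export
tidy.beta_hmm_fit <- function(x, ...) tidy.beta_hmm(x$model, ...)

#' @rdname tidy.beta_hmm_fit
#' @export
tidy.beta_hmm <- function(x, ...) {
  grid <- tidyr::expand_grid(state = seq_len(x$K), band_idx = seq_len(x$H))
  tibble::tibble(
    state = grid$state,
    band = x$bands$band[grid$band_idx],
    a = x$a[cbind(grid$state, grid$band_idx)],
    b = x$b[cbind(grid$state, grid$band_idx)],
    mean = .data_mean(x, grid),
    pr_above_median = exceedance_probability(
      x$a[cbind(grid$state, grid$band_idx)],
      x$b[cbind(grid$state, grid$band_idx)])
  )
}

.data_mean <- function(x, grid) {
  a <- x$a[cbind(grid$state, grid$band_idx)]
  b <- x$b[cbind(grid$state, grid$band_idx)]
  a / (a + b)
}

#' Glance at a fitted beta-HMM
#'
#' @param x A `beta_hmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `K`, `H`, `loglik`, `n_iterations`, `converged`,
#'   `seed`.
#' @export
glance.beta_hmm_fit <- function(x, ...) {
  tibble::tibble(
    K = x$model$K, H = x$model$H,
    loglik = x$loglik_trace[length(x$loglik_trace)],
    n_iterations = x$n_iterations, converged = x$converged, seed = x$seed
  )
}
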