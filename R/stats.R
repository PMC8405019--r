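#' Probability that scaled power exceeds a threshold in a given state
#'
#' `Pr(Y_h > t | Z = k)` for `Y_h | Z = k ~ Beta(a, b)`; with the default
#' threshold 0.5 this is the probability of exceeding the median scaled power
#' of the band. Vectorized over `a` and `b`.
#'
#' @param a,b Beta shape parameters (> 0).
#' @param threshold Threshold in (0,1); default 0.5.
#' @return Probability in `[0, 1]`.
#' @export
exceedance_probability <- function(a, b, threshold = 0.5) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0)) {
    stop("invalid beta parameters")
  }
  stopifnot(threshold > 0, threshold < 1)
  stats::pbeta(threshold, a, b, lower.tail = FALSE)
}

#' Probability that one beta variable is below another
#'
#' For independent `X_j ~ Beta(a_j, b_j)` and `X_k ~ Beta(a_k, b_k)`, computes
#' `Pr(X_j - X_k <= 0)` by integrating the density of the difference
#' `delta = X_j - X_k` over `[-1, 0]`. The density at each `delta` is itself an
#' integral of the joint density over its piecewise support, evaluated by
#' nested adaptive quadrature. When a shape parameter is below 1 the inner
#' integrand has integrable endpoint singularities, which the adaptive rule
#' handles on the open interval.
#'
#' @param a_j,b_j Shape parameters of state j's beta distribution.
#' @param a_k,b_k Shape parameters of state k's beta distribution.
#' @param tol Absolute tolerance of the outer quadrature.
#' @return A one-row tibble with `pr_delta_le_0` and quadrature metadata
#'   (`abs_error`, `subdivisions`).
#' @export
delta_probability <- function(a_j, b_j, a_k, b_k, tol = 1e-4) {
  for (p in c(a_j, b_j, a_k, b_k)) {
    if (!is.finite(p) || p <= 0) stop("invalid beta parameters")
  }
  dens <- function(delta_vec) {
    vapply(delta_vec, function(d) {
      lo <- max(0, d); hi <- min(1, 1 + d)
      if (hi <= lo) return(0)
      inner <- function(x) {
        stats::dbeta(x, a_j, b_j) * stats::dbeta(x - d, a_k, b_k)
      }
      r <- tryCatch(
        stats::integrate(inner, lo, hi, rel.tol = tol / 10,
                         abs.tol = tol / 10, subdivisions = 400L,
                         stop.on.error = FALSE),
        error = function(e) NULL)
      if (is.null(r) || !is.finite(r$value)) {
        stop("inner quadrature failed at delta = ", signif(d, 6))
      }
      r$value
    }, 0)
  }
  out <- stats::integrate(dens, -1, 0, abs.tol = tol, rel.tol = tol,
                          subdivisions = 200L, stop.on.error = FALSE)
  if (!is.finite(out$value)) {
    stop("outer quadrature failed: ", out$message)
  }
  tibble::tibble(
    pr_delta_le_0 = min(max(out$value, 0), 1),
    abs_error = out$abs.error,
    subdivisions = out$subdivisions
  )
}

#' Pairwise comparisons of state emission distributions
#'
#' For every band and every ordered pair of states (j, k), computes
#' `Pr(X_hj - X_hk <= 0)`: the probability that scaled power in state j is
#' below that of state k in band h. Two models may be supplied to compare
#' states across independently fitted models (e.g. two subjects).
#'
#' @param model A `beta_hmm` or `beta_hmm_fit` (state j side).
#' @param model2 Optional second model (state k side); defaults to `model`.
#' @param tol Quadrature tolerance passed to [delta_probability()].
#' @return A tibble with columns `band`, `state_j`, `state_k`,
#'   `pr_delta_le_0`.
#' @export
delta_probability_table <- function(model, model2 = NULL, tol = 1e-4) {
  m1 <- if (inherits(model, "beta_hmm_fit")) model$model else model
  m2 <- if (is.null(model2)) m1 else
    if (inherits(model2, "beta_hmm_fit")) model2$model else model2
  stopifnot(m1$H == m2$H)
  grid <- tidyr::expand_grid(h = seq_len(m1$H), j = seq_len(m1$K),
                             k = seq_len(m2$K))
  if (is.null(model2)) grid <- dplyr::filter(grid, .data$j != .data$k)
  pr <- purrr::pmap_dbl(grid, function(h, j, k) {
    delta_probability(m1$a[j, h], m1$b[j, h], m2$a[k, h], m2$b[k, h],
                      tol = tol)$pr_delta_le_0
  })
  tibble::tibble(band = m1$bands$band[grid$h], state_j = grid$j,
                 state_k = grid$k, pr_delta_le_0 = pr)
}

#' Kolmogorov-Smirnov distance between two beta distributions
#'
#' Either the empirical two-sample KS distance from a large number of draws
#' (`method = "sampled"`, matching a sampling-based comparison of fitted
#' states), or the exact supremum of the absolute CDF difference located on a
#' dense grid and polished with local optimization (`method = "exact"`).
#'
#' @param a1,b1,a2,b2 Beta shape parameters.
#' @param method `"exact"` or `"sampled"`.
#' @param n_samples Draws per distribution for the sampled mode.
#' @param seed Optional seed for the sampled mode.
#' @param grid_n Grid resolution for the exact mode.
#' @return KS distance in `[0, 1]`.
#' @export
ks_distance_beta <- function(a1, b1, a2, b2,
                             method = c("exact", "sampled"),
                             n_samples = 100000, seed = NULL, grid_n = 4001) {
  for (p in c(a1, b1, a2, b2)) {
    if (!is.finite(p) || p <= 0) stop("invalid beta parameters")
  }
  method <- match.arg(method)
  if (method == "sampled") {
    stopifnot(n_samples >= 2)
    if (!is.null(seed)) set.seed(seed)
    x <- stats::rbeta(n_samples, a1, b1)
    y <- stats::rbeta(n_samples, a2, b2)
    # only the statistic is used; tie warnings concern the p-value
    return(unname(suppressWarnings(stats::ks.test(x, y))$statistic))
  }
  g <- seq(0, 1, length.out = grid_n)
  diffs <- abs(stats::pbeta(g, a1, b1) - stats::pbeta(g, a2, b2))
  i <- which.max(diffs)
  lo <- g[max(1, i - 1)]; hi <- g[min(grid_n, i + 1)]
  opt <- stats::optimize(
    function(x) abs(stats::pbeta(x, a1, b1) - stats::pbeta(x, a2, b2)),
    lower = lo, upper = hi, maximum = TRUE, tol = 1e-10)
  max(diffs[i], opt$objective)
}

#' One-sample Kolmogorov-Smirnov distance against a beta CDF
#'
#' Supremum difference between the empirical CDF of `x` and the
#' `Beta(a, b)` CDF, evaluated at the sample points (where the supremum of a
#' step-versus-continuous comparison is attained).
#'
#' @param x Sample in (0,1).
#' @param a,b Beta shape parameters.
#' @return KS distance in `[0, 1]`.
#' @export
ks_distance_empirical <- function(x, a, b) {
  n <- length(x)
  fx <- stats::pbeta(sort(x), a, b)
  max(abs(fx - seq_len(n) / n), abs(fx - (seq_len(n) - 1) / n))
}

#' Mean sojourn duration of a single HMM state
#'
#' Under first-order Markov dynamics the duration spent in state k is
#' geometric, so the mean duration is `1 / (1 - A_kk)` windows.
#'
#' @param A K x K row-stochastic transition matrix.
#' @param k State index.
#' @param window_step Seconds per window (default 0.1; used for the seconds
#'   conversion).
#' @return A one-row tibble with `state`, `windows`, `seconds`.
#' @export
mean_state_duration <- function(A, k, window_step = 0.1) {
  A <- as.matrix(A)
  stopifnot(k >= 1, k <= nrow(A))
  if (any(abs(rowSums(A) - 1) > 1e-8) || any(A < 0)) {
    stop("A must be row-stochastic")
  }
  if (A[k, k] >= 1) stop("A[k,k] = 1: infinite expected duration")
  w <- 1 / (1 - A[k, k])
  tibble::tibble(state = k, windows = w, seconds = w * window_step)
}

run_length_means <- function(z01, drop_boundary = TRUE) {
  r <- rle(z01)
  len <- r$lengths; val <- r$values
  if (drop_boundary && length(len) > 1) {
    keep <- seq_along(len)[-c(1, length(len))]
  } else if (drop_boundary) {
    keep <- integer(0)
  } else {
    keep <- seq_along(len)
  }
  c(duration = if (any(val[keep] == 1)) mean(len[keep][val[keep] == 1]) else NA_real_,
    interval = if (any(val[keep] == 0)) mean(len[keep][val[keep] == 0]) else NA_real_)
}

#' Monte-Carlo duration statistics for a subset of states
#'
#' A neurophysiological activity (e.g. "gamma activity") is a subset of HMM
#' states. Its mean duration is the average number of consecutive windows the
#' chain spends inside the subset, and its mean interval the average number of
#' consecutive windows outside it between two visits. Both are estimated by
#' simulating Markov chains of length `N` from the transition matrix,
#' binarizing membership, and averaging run lengths; the replicate-level means
#' are summarized by their median and central 95% interval over `n_mc`
#' replicates. The chain start is drawn uniformly over states and a burn-in is
#' discarded; runs touching the chain ends are censored and excluded.
#'
#' @param A K x K transition matrix.
#' @param subset Integer vector of state labels (proper nonempty subset).
#' @param N Chain length per replicate (default 2000).
#' @param n_mc Number of Monte-Carlo replicates (default 4000).
#' @param seed Integer seed.
#' @param window_step Seconds per window for the seconds conversion.
#' @param burn_in Windows discarded at the chain start (default 100).
#' @return A tibble with one row per statistic (`duration`, `interval`):
#'   median and 95% interval in windows and in seconds, plus the number of
#'   replicates contributing.
#' @export
subset_duration_statistics <- function(A, subset, N = 2000, n_mc = 4000,
                                       seed = 1, window_step = 0.1,
                                       burn_in = 100) {
  A <- as.matrix(A)
  K <- nrow(A)
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) == 0 || length(subset) >= K ||
      any(subset < 1 | subset > K)) {
    stop("subset must be a nonempty proper subset of 1:", K)
  }
  if (any(abs(rowSums(A) - 1) > 1e-8) || any(A < 0)) {
    stop("A must be row-stochastic")
  }
  stopifnot(N > burn_in + 1)
  set.seed(seed)
  # simulate all replicates in parallel, one vectorized step per window
  z <- matrix(0L, n_mc, N)
  z[, 1] <- sample.int(K, n_mc, replace = TRUE)
  cumA <- t(apply(A, 1, cumsum))
  cumA[, K] <- 1
  for (n in 2:N) {
    u <- stats::runif(n_mc)
    z[, n] <- max.col(1 * (u < cumA[z[, n - 1], , drop = FALSE]),
                      ties.method = "first")
  }
  z01 <- matrix(as.integer(matrix(z %in% subset, n_mc, N)), n_mc, N)
  z01 <- z01[, (burn_in + 1):N, drop = FALSE]
  per_rep <- t(apply(z01, 1, run_length_means))
  summarize_stat <- function(x, name) {
    x <- x[is.finite(x)]
    qs <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    tibble::tibble(
      statistic = name,
      median_windows = qs[2], lo_windows = qs[1], hi_windows = qs[3],
      median_seconds = qs[2] * window_step,
      lo_seconds = qs[1] * window_step, hi_seconds = qs[3] * window_step,
      n_replicates = length(x)
    )
  }
  out <- dplyr::bind_rows(
    summarize_stat(per_rep[, "duration"], "duration"),
    summarize_stat(per_rep[, "interval"], "interval")
  )
  attr(out, "subset") <- subset
  attr(out, "N") <- N
  attr(out, "n_mc") <- n_mc
  attr(out, "seed") <- seed
  out
}
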