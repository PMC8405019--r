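#' Construct a beta-observation hidden Markov model
#'
#' A K-state HMM whose emissions in each of H frequency bands are independent
#' beta distributions given the state: `p(y_h | z = k) = Beta(a[k,h], b[k,h])`.
#' Each state's marginals are required to be unimodal, i.e. `a` and `b` may not
#' both be at or below 1 for the same state and band (such a pair would make a
#' single state stand for two spectral profiles).
#'
#' @param pi Length-K initial state probability vector.
#' @param A K x K row-stochastic transition matrix.
#' @param a,b K x H matrices of beta shape parameters (`a[k, h]` is the first
#'   shape of state k in band h).
#' @param bands Optional band definition tibble (length-H); band names are used
#'   in reporting.
#' @param window_step Seconds per observation window (used to convert
#'   durations to seconds); default 0.1.
#' @return An object of class `beta_hmm`.
#' @export
beta_hmm <- function(pi, A, a, b, bands = NULL, window_step = 0.1) {
  a <- as.matrix(a); b <- as.matrix(b); A <- as.matrix(A)
  K <- length(pi); H <- ncol(a)
  if (is.null(bands)) {
    bands <- tibble::tibble(band = paste0("band", seq_len(H)),
                            lo = NA_real_, hi = NA_real_)
  }
  m <- structure(
    list(K = K, H = H, pi = as.numeric(pi), A = A, a = a, b = b,
         bands = tibble::as_tibble(bands), window_step = window_step,
         relabel = seq_len(K)),
    class = "beta_hmm"
  )
  viol <- validate_beta_hmm(m)
  if (length(viol)) stop("invalid beta_hmm: ", paste(viol, collapse = "; "))
  m
}

#' Check beta-HMM invariants
#'
#' Reports (rather than raises) violations: probability simplex sums within
#' 1e-8, nonnegative probabilities, positive beta shapes, and the unimodality
#' restriction that forbids `a <= 1` and `b <= 1` simultaneously.
#'
#' @param model A `beta_hmm` (or a list with the same fields).
#' @param tol Tolerance on simplex sums.
#' @return Character vector of violation messages; empty if the model is valid.
#' @export
validate_beta_hmm <- function(model, tol = 1e-8) {
  v <- character()
  K <- model$K; H <- model$H
  if (length(model$pi) != K) v <- c(v, "pi length != K")
  if (!all(dim(model$A) == c(K, K))) v <- c(v, "A is not K x K")
  if (!all(dim(model$a) == c(K, H)) || !all(dim(model$b) == c(K, H))) {
    v <- c(v, "a/b are not K x H")
  }
  if (length(v)) return(v)
  if (any(model$pi < 0)) v <- c(v, "negative entries in pi")
  if (abs(sum(model$pi) - 1) > tol) {
    v <- c(v, sprintf("pi sums to %.10g, not 1", sum(model$pi)))
  }
  if (any(model$A < 0)) v <- c(v, "negative entries in A")
  rs <- rowSums(model$A)
  for (j in which(abs(rs - 1) > tol)) {
    v <- c(v, sprintf("row %d of A sums to %.10g, not 1", j, rs[j]))
  }
  if (any(!is.finite(model$a)) || any(model$a <= 0) ||
      any(!is.finite(model$b)) || any(model$b <= 0)) {
    v <- c(v, "beta shape parameters must be finite and > 0")
  } else {
    bad <- which(model$a <= 1 & model$b <= 1, arr.ind = TRUE)
    for (i in seq_len(nrow(bad))) {
      v <- c(v, sprintf(
        "unimodality violated for state %d, band %d (a = %.4g, b = %.4g)",
        bad[i, 1], bad[i, 2], model$a[bad[i, 1], bad[i, 2]],
        model$b[bad[i, 1], bad[i, 2]]))
    }
  }
  v
}

#' @export
print.beta_hmm <- function(x, ...) {
  cat(sprintf("<beta_hmm> K = %d states, H = %d bands (%s)\n",
              x$K, x$H, paste(x$bands$band, collapse = ", ")))
  cat("Transition matrix diagonal:",
      paste(sprintf("%.3f", diag(x$A)), collapse = " "), "\n")
  invisible(x)
}

#' Per-window log observation densities under every state
#'
#' Returns the N x K matrix of `log p(y_n | z_n = k)` with band independence:
#' the sum over bands of beta log-densities.
#'
#' @param Y N x H matrix (or scaled-observation tibble) with entries in (0,1).
#' @param model A `beta_hmm`.
#' @return N x K matrix of log densities.
#' @export
emission_logdensity <- function(Y, model) {
  Y <- obs_matrix(Y)
  if (any(Y <= 0 | Y >= 1)) {
    bad <- which(Y <= 0 | Y >= 1, arr.ind = TRUE)[1, ]
    stop("observation outside (0,1) at window ", bad[1], ", band ", bad[2])
  }
  if (ncol(Y) != model$H) stop("observation has ", ncol(Y),
                               " bands but model has ", model$H)
  logY <- log(Y); log1mY <- log1p(-Y)
  const <- rowSums(lbeta(model$a, model$b))     # length K
  out <- logY %*% t(model$a - 1) + log1mY %*% t(model$b - 1)
  out <- sweep(out, 2, const, "-")
  if (any(!is.finite(out))) {
    bad <- which(!is.finite(out), arr.ind = TRUE)[1, ]
    stop("non-finite log density at window ", bad[1], ", state ", bad[2])
  }
  out
}

#' Log density of a single observation vector under one state
#'
#' @param y Length-H vector in (0,1).
#' @param k State index (1-based).
#' @param model A `beta_hmm`.
#' @return Scalar log density.
#' @export
observation_logdensity <- function(y, k, model) {
  stopifnot(k >= 1, k <= model$K)
  emission_logdensity(matrix(y, nrow = 1), model)[1, k]
}

#' Canonical state ordering
#'
#' HMM state labels are arbitrary; for comparable reporting across runs,
#' states are relabeled by ascending beta mean `a/(a+b)` in the
#' highest-frequency band. Returns the permutation `perm` such that new state
#' `k` is old state `perm[k]`.
#'
#' @param model A `beta_hmm`.
#' @return Integer permutation of `1:K`.
#' @export
canonical_state_order <- function(model) {
  means <- model$a[, model$H] / (model$a[, model$H] + model$b[, model$H])
  order(means)
}

#' Apply a state relabeling permutation to a model
#'
#' @param model A `beta_hmm`.
#' @param perm Permutation of `1:K`; new state `k` is old state `perm[k]`.
#' @return The relabeled `beta_hmm`, with the composed permutation recorded in
#'   `$relabel`.
#' @export
relabel_states <- function(model, perm) {
  stopifnot(sort(perm) == seq_len(model$K))
  model$pi <- model$pi[perm]
  model$A <- model$A[perm, perm, drop = FALSE]
  model$a <- model$a[perm, , drop = FALSE]
  model$b <- model$b[perm, , drop = FALSE]
  model$relabel <- model$relabel[perm]
  model
}

#' Write a beta-HMM to JSON
#'
#' Serializes K, H, band names, pi, A (row-major), the shape matrices, the
#' relabeling permutation and any fit metadata. States use 1-based labels.
#'
#' @param model A `beta_hmm`.
#' @param path Output file path.
#' @param meta Optional named list of fit metadata (loglik, iterations, seed).
#' @export
write_beta_hmm <- function(model, path, meta = NULL) {
  obj <- list(
    K = model$K, H = model$H, bands = model$bands$band,
    pi = model$pi, A = as.vector(t(model$A)),
    a = unname(as.matrix(model$a)), b = unname(as.matrix(model$b)),
    window_step = model$window_step, relabel = model$relabel,
    meta = meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a beta-HMM from JSON
#'
#' @param path Path written by [write_beta_hmm()].
#' @return A `beta_hmm`; fit metadata, if present, is attached as attribute
#'   `meta`.
#' @export
read_beta_hmm <- function(path) {
  obj <- jsonlite::fromJSON(path)
  m <- beta_hmm(
    pi = obj$pi,
    A = matrix(obj$A, obj$K, obj$K, byrow = TRUE),
    a = matrix(unlist(obj$a), obj$K, obj$H),
    b = matrix(unlist(obj$b), obj$K, obj$H),
    bands = tibble::tibble(band = obj$bands, lo = NA_real_, hi = NA_real_),
    window_step = obj$window_step %||% 0.1
  )
  if (!is.null(obj$relabel)) m$relabel <- obj$relabel
  if (!is.null(obj$meta)) attr(m, "meta") <- obj$meta
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x
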