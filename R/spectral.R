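#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-halfbandwidth
#' product `nw`, via the eigenvectors of the symmetric tridiagonal matrix whose
#' extremal eigenvectors are the Slepian sequences. Tapers are normalized to
#' unit energy and sign-fixed so that each taper has a nonnegative mean
#' (nonnegative first lag for odd-symmetric tapers).
#'
#' @param n Taper length in samples.
#' @param nw Time-halfbandwidth product (typically 2-4).
#' @param k Number of tapers; must satisfy `k <= 2 * nw - 1` for well
#'   concentrated tapers.
#' @return An `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 2, nw > 0, k >= 1)
  if (k > 2 * nw - 1) {
    stop("n_tapers = ", k, " incompatible with time-halfbandwidth = ", nw,
         " (need n_tapers <= 2*nw - 1)")
  }
  if (n < 2 * k) stop("taper length too short for ", k, " tapers")
  w <- nw / n
  t_idx <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * w)
  diag_off <- t_idx[-1] * (n - t_idx[-1]) / 2
  tri <- matrix(0, n, n)
  diag(tri) <- diag_main
  tri[cbind(2:n, 1:(n - 1))] <- diag_off
  tri[cbind(1:(n - 1), 2:n)] <- diag_off
  eig <- eigen(tri, symmetric = TRUE)
  tapers <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- tapers[, j]
    v <- v / sqrt(sum(v^2))
    s <- sum(v)
    if (abs(s) > 1e-10) {
      if (s < 0) v <- -v
    } else if (v[2] - v[1] < 0) {
      v <- -v
    }
    tapers[, j] <- v
  }
  tapers
}

new_spectrogram <- function(power_db, window_times, frequencies,
                            window_length, overlap_fraction, fs) {
  structure(
    list(power_db = power_db, window_times = window_times,
         frequencies = frequencies, window_length = window_length,
         overlap_fraction = overlap_fraction,
         window_step = window_length * (1 - overlap_fraction), fs = fs),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram> %d windows x %d frequencies (%.3g-%.3g Hz), window %.3g s, step %.3g s\n",
    nrow(x$power_db), ncol(x$power_db), min(x$frequencies), max(x$frequencies),
    x$window_length, x$window_step))
  invisible(x)
}

#' @export
dim.spectrogram <- function(x) dim(x$power_db)

#' Multitaper spectrogram of a single-channel voltage trace
#'
#' Estimates the power spectral density in overlapping windows by averaging
#' periodograms over DPSS tapers, and reports it in dB. Each window is demeaned
#' before tapering. With the defaults (1 s windows, 90% overlap,
#' time-halfbandwidth 2, 3 tapers), consecutive windows are 0.1 s apart, which
#' is the time resolution carried through all downstream duration statistics.
#'
#' @param samples Numeric vector of voltage samples.
#' @param fs Sampling rate in Hz.
#' @param window_length Window duration in seconds.
#' @param overlap_fraction Fractional overlap between consecutive windows, in
#'   `[0, 1)`.
#' @param time_halfbandwidth DPSS time-halfbandwidth product.
#' @param n_tapers Number of DPSS tapers.
#' @return A `spectrogram` object: list with `power_db` (N x F matrix, dB),
#'   `window_times` (window centers, s), `frequencies` (Hz, all below `fs/2`),
#'   `window_length`, `overlap_fraction`, `window_step` and `fs`.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 5, by = 1 / 250))
#' sp <- compute_spectrogram(x, fs = 250)
#' sp$frequencies[which.max(sp$power_db[1, ])]
compute_spectrogram <- function(samples, fs, window_length = 1,
                                overlap_fraction = 0.9,
                                time_halfbandwidth = 2, n_tapers = 3) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("empty signal")
  if (any(!is.finite(samples))) stop("signal contains non-finite samples")
  stopifnot(fs > 0, window_length > 0,
            overlap_fraction >= 0, overlap_fraction < 1)
  nwin <- round(window_length * fs)
  if (nwin < 2 * n_tapers) {
    stop("window of ", nwin, " samples too short for ", n_tapers, " tapers")
  }
  if (length(samples) < nwin) {
    stop("signal shorter than one window (", nwin, " samples)")
  }
  hop <- round(nwin * (1 - overlap_fraction))
  if (hop < 1) stop("overlap too large: hop is below one sample")
  n_windows <- floor((length(samples) - nwin) / hop) + 1
  tapers <- dpss_tapers(nwin, time_halfbandwidth, n_tapers)
  # zero-pad to the next power of two (doubled) for a denser frequency grid,
  # so narrow low-frequency bands span several bins
  nfft <- 2 * 2^ceiling(log2(nwin))
  freq_all <- (seq_len(nfft) - 1) * fs / nfft
  # drop the 0 Hz bin: after per-window demeaning it is not a PSD estimate
  keep <- freq_all > 0 & freq_all < fs / 2
  starts <- (seq_len(n_windows) - 1) * hop + 1
  power <- matrix(0, n_windows, sum(keep))
  padded <- matrix(0, nfft, n_tapers)
  for (i in seq_len(n_windows)) {
    seg <- samples[starts[i]:(starts[i] + nwin - 1)]
    seg <- seg - mean(seg)
    padded[seq_len(nwin), ] <- tapers * seg
    # mean over tapers of |FFT|^2 / fs: one-sided PSD up to a factor irrelevant
    # after dB scaling and band differencing
    spec <- rowMeans(abs(stats::mvfft(padded))^2) / fs
    power[i, ] <- spec[keep]
  }
  power_db <- 10 * log10(pmax(power, .Machine$double.xmin))
  window_times <- (starts - 1) / fs + window_length / 2
  new_spectrogram(power_db, window_times, freq_all[keep],
                  window_length, overlap_fraction, fs)
}

bp_attrs <- function(x) {
  list(bands = attr(x, "bands"), window_step = attr(x, "window_step"))
}

#' Average spectrogram power within frequency bands
#'
#' Reduces a spectrogram to one dB value per window per band by taking the
#' arithmetic mean of the dB values over the frequency bins falling in each
#' half-open band interval `[lo, hi)`.
#'
#' @param spec A `spectrogram`.
#' @param bands Band definition tibble (default [canonical_bands()]).
#' @return A tibble with a `time` column (window centers, s) and one column per
#'   band holding band-averaged power in dB. Attributes `bands` and
#'   `window_step` carry the band definition and the window hop in seconds.
#' @export
band_power <- function(spec, bands = canonical_bands()) {
  stopifnot(inherits(spec, "spectrogram"))
  bands <- validate_bands(bands)
  vals <- matrix(NA_real_, nrow(spec$power_db), nrow(bands))
  for (h in seq_len(nrow(bands))) {
    in_band <- spec$frequencies >= bands$lo[h] & spec$frequencies < bands$hi[h]
    if (!any(in_band)) {
      stop("band '", bands$band[h], "' [", bands$lo[h], ", ", bands$hi[h],
           ") contains no frequency bins")
    }
    vals[, h] <- rowMeans(spec$power_db[, in_band, drop = FALSE])
  }
  colnames(vals) <- bands$band
  out <- tibble::as_tibble(as.data.frame(vals))
  out <- dplyr::bind_cols(tibble::tibble(time = spec$window_times), out)
  attr(out, "bands") <- bands
  attr(out, "window_step") <- spec$window_step
  class(out) <- c("band_power_tbl", class(out))
  out
}

band_matrix <- function(bp) {
  bands <- attr(bp, "bands")
  if (is.null(bands)) {
    bands <- tibble::tibble(band = setdiff(names(bp), "time"))
  }
  as.matrix(bp[, bands$band, drop = FALSE])
}

#' Per-band logistic scaling parameters
#'
#' For each band computes the quartiles Q1, Q2, Q3 of the band power sequence
#' (linear interpolation between order statistics) and the logistic slope
#' `lambda = 2 log(3) / (Q3 - Q1)` that places the quartiles at 0.25/0.5/0.75
#' after scaling.
#'
#' @param bp A band power tibble from [band_power()].
#' @return A tibble with columns `band`, `q1`, `q2`, `q3` (dB) and `lambda`
#'   (1/dB), carrying the same `bands`/`window_step` attributes.
#' @export
compute_scaling <- function(bp) {
  a <- bp_attrs(bp)
  vals <- band_matrix(bp)
  if (nrow(vals) < 4) stop("need at least 4 windows to compute quartiles")
  qs <- apply(vals, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE, type = 7)
  iqr <- qs[3, ] - qs[1, ]
  if (any(iqr <= 0)) {
    bad <- colnames(vals)[iqr <= 0]
    stop("degenerate band(s) with Q3 = Q1: ", paste(bad, collapse = ", "))
  }
  out <- tibble::tibble(
    band = colnames(vals),
    q1 = unname(qs[1, ]), q2 = unname(qs[2, ]), q3 = unname(qs[3, ]),
    lambda = unname(2 * log(3) / iqr)
  )
  attr(out, "bands") <- a$bands
  attr(out, "window_step") <- a$window_step
  out
}

#' Logistically scale band power into the unit interval
#'
#' Maps each band power value through
#' `y = 1 / (1 + exp(-lambda * (s - q2)))`, so the per-band median lands on
#' 0.5 and (for quartile-symmetric bands) Q1 and Q3 land on 0.25 and 0.75.
#' Values are clipped to `[eps, 1 - eps]` purely to guard downstream
#' logarithms against floating-point underflow; the logistic itself never
#' reaches 0 or 1.
#'
#' @param bp A band power tibble from [band_power()].
#' @param scaling Scaling parameters from [compute_scaling()] over the same
#'   bands.
#' @param eps Clipping guard (default `1e-12`).
#' @return A tibble with `time` plus one column per band, entries strictly in
#'   (0, 1); attributes `bands`, `window_step` and `scaling`.
#' @export
scale_observations <- function(bp, scaling, eps = 1e-12) {
  a <- bp_attrs(bp)
  vals <- band_matrix(bp)
  if (!identical(colnames(vals), scaling$band)) {
    stop("band mismatch between band power (",
         paste(colnames(vals), collapse = ","), ") and scaling (",
         paste(scaling$band, collapse = ","), ")")
  }
  lin <- sweep(sweep(vals, 2, scaling$q2, "-"), 2, scaling$lambda, "*")
  y <- 1 / (1 + exp(-lin))
  y <- pmin(pmax(y, eps), 1 - eps)
  out <- tibble::as_tibble(as.data.frame(y))
  out <- dplyr::bind_cols(tibble::tibble(time = bp$time), out)
  attr(out, "bands") <- a$bands
  attr(out, "window_step") <- a$window_step
  attr(out, "scaling") <- scaling
  class(out) <- c("scaled_obs_tbl", class(out))
  out
}

#' Extract the observation matrix from a scaled-observation tibble
#'
#' @param y A tibble from [scale_observations()], or a bare numeric matrix
#'   already in (0,1) (returned unchanged).
#' @return An N x H numeric matrix with band names as columns.
#' @export
obs_matrix <- function(y) {
  if (is.matrix(y)) return(y)
  stopifnot(is.data.frame(y))
  as.matrix(y[, setdiff(names(y), "time"), drop = FALSE])
}

#' Run the full spectral reduction in one call
#'
#' Convenience wrapper: spectrogram, band averaging, scaling-parameter
#' estimation over the whole recording, and logistic scaling.
#'
#' @inheritParams compute_spectrogram
#' @param bands Band definition tibble.
#' @return A scaled-observation tibble (see [scale_observations()]).
#' @export
spectral_pipeline <- function(samples, fs, window_length = 1,
                              overlap_fraction = 0.9, time_halfbandwidth = 2,
                              n_tapers = 3, bands = canonical_bands()) {
  spec <- compute_spectrogram(samples, fs, window_length, overlap_fraction,
                              time_halfbandwidth, n_tapers)
  bp <- band_power(spec, bands)
  scale_observations(bp, compute_scaling(bp))
}
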