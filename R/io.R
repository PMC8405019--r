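#' Read a single-channel signal from delimited text
#'
#' One sample per row (a header row is tolerated); the sampling rate must be
#' supplied. Non-finite samples are rejected.
#'
#' @param path Path to the file.
#' @param fs Sampling rate in Hz.
#' @param column Column index or name holding the samples (default 1).
#' @return A list with `samples`, `fs`, `label`.
#' @export
read_signal_csv <- function(path, fs, column = 1) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  stopifnot(fs > 0)
  df <- utils::read.csv(path, header = is_headered(path))
  x <- as.numeric(df[[column]])
  if (length(x) == 0) stop("no samples in ", path)
  if (any(!is.finite(x))) stop("non-finite samples in ", path)
  list(samples = x, fs = fs, label = basename(path))
}

is_headered <- function(path) {
  first <- readLines(path, n = 1)
  is.na(suppressWarnings(as.numeric(strsplit(first, "[,;\t]")[[1]][1])))
}

#' Read one channel from a European Data Format (EDF) file
#'
#' Minimal reader for uncompressed 16-bit EDF: parses the fixed-width ASCII
#' header, applies each channel's physical calibration, and concatenates the
#' selected channel across data records. Annotation channels and
#' discontinuous (EDF+D) files are not supported.
#'
#' @param path Path to the EDF file.
#' @param channel Channel name (matched against the header labels) or index.
#' @return A list with `samples` (physical units), `fs`, `label`.
#' @export
read_edf <- function(path, channel = 1) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_chr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr_chr(8)
  invisible(hdr_chr(80 + 80 + 8 + 8))       # patient, recording, date, time
  header_bytes <- as.integer(hdr_chr(8))
  invisible(hdr_chr(44))
  n_records <- as.integer(hdr_chr(8))
  record_dur <- as.numeric(hdr_chr(8))
  ns <- as.integer(hdr_chr(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header in ", path)
  labels <- vapply(seq_len(ns), function(i) hdr_chr(16), "")
  invisible(hdr_chr(80 * ns))               # transducer
  invisible(hdr_chr(8 * ns))                # physical dimension
  num_field <- function(w) vapply(seq_len(ns), function(i)
    as.numeric(hdr_chr(w)), 0)
  phys_min <- num_field(8); phys_max <- num_field(8)
  dig_min <- num_field(8); dig_max <- num_field(8)
  invisible(hdr_chr(80 * ns))               # prefiltering
  n_samp <- vapply(seq_len(ns), function(i) as.integer(hdr_chr(8)), 0L)
  invisible(hdr_chr(32 * ns))               # reserved
  ch <- if (is.character(channel)) match(channel, labels) else as.integer(channel)
  if (is.na(ch) || ch < 1 || ch > ns) {
    stop("channel '", channel, "' not found; available: ",
         paste(labels, collapse = ", "))
  }
  gain <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
  offset <- phys_min[ch] - gain * dig_min[ch]
  seek(con, header_bytes)
  rec_len <- sum(n_samp)
  samples <- numeric(n_records * n_samp[ch])
  pre <- if (ch > 1) sum(n_samp[seq_len(ch - 1)]) else 0L
  for (r in seq_len(n_records)) {
    rec <- readBin(con, "integer", n = rec_len, size = 2, signed = TRUE,
                   endian = "little")
    if (length(rec) < rec_len) stop("truncated EDF record ", r, " in ", path)
    samples[((r - 1) * n_samp[ch] + 1):(r * n_samp[ch])] <-
      rec[(pre + 1):(pre + n_samp[ch])]
  }
  samples <- gain * samples + offset
  if (any(!is.finite(samples))) stop("non-finite samples after calibration")
  list(samples = samples, fs = n_samp[ch] / record_dur, label = labels[ch])
}

# minimal EDF writer (single use: building test inputs and round-trips)
write_edf <- function(path, channels, fs, record_dur = 1,
                      labels = names(channels)) {
  ns <- length(channels)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ns))
  n_samp <- as.integer(fs * record_dur)
  n_records <- min(vapply(channels, length, 1L)) %/% n_samp
  pad <- function(x, w) formatC(as.character(x), width = -w)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(pad(s, w)), con)
  wr("0", 8); wr("local patient", 80); wr("local recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8); wr("", 44); wr(n_records, 8); wr(record_dur, 8)
  wr(ns, 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  # integer physical bounds keep the 8-char header fields exact
  phys_max <- vapply(channels, function(x) ceiling(max(abs(x))) + 1, 0)
  for (i in seq_len(ns)) wr(-phys_max[i], 8)
  for (i in seq_len(ns)) wr(phys_max[i], 8)
  for (i in seq_len(ns)) wr(-32768, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(n_samp, 8)
  for (i in seq_len(ns)) wr("", 32)
  gain <- 2 * phys_max / 65535
  offset <- -phys_max + 32768 * gain
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      seg <- channels[[i]][((r - 1) * n_samp + 1):(r * n_samp)]
      dig <- as.integer(round((seg - offset[i]) / gain[i]))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Write band power or scaled observations to CSV
#'
#' @param x A tibble from [band_power()] or [scale_observations()].
#' @param path Output path.
#' @export
write_observations_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read scaled observations (or band power) from CSV
#'
#' @param path CSV written by [write_observations_csv()].
#' @param window_step Seconds per window (default inferred from the `time`
#'   column, falling back to 0.1).
#' @return A tibble with `time` plus band columns and `bands`/`window_step`
#'   attributes.
#' @export
read_observations_csv <- function(path, window_step = NULL) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  df <- tibble::as_tibble(utils::read.csv(path))
  band_names <- setdiff(names(df), "time")
  if (is.null(window_step)) {
    window_step <- if ("time" %in% names(df) && nrow(df) > 1)
      stats::median(diff(df$time)) else 0.1
  }
  attr(df, "bands") <- tibble::tibble(band = band_names, lo = NA_real_,
                                      hi = NA_real_)
  attr(df, "window_step") <- window_step
  df
}

#' Write per-band scaling parameters to JSON
#'
#' @param scaling Tibble from [compute_scaling()].
#' @param path Output path.
#' @export
write_scaling_json <- function(scaling, path) {
  jsonlite::write_json(as.data.frame(scaling), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline on one or more recordings
#'
#' Executes the whole workflow on each session: multitaper spectrogram, band
#' averaging, logistic scaling, then a single multi-session EM fit, per-session
#' Viterbi decoding, and post-fit statistics. All intermediates are written
#' under `out_dir` (band power and scaled observations per session, scaling
#' JSON, model JSON, state path CSVs, duration statistics and pairwise
#' comparison CSVs, plus the resolved configuration and a log).
#'
#' @param signals A list of signal objects (`list(samples=, fs=, label=)`, as
#'   returned by [read_signal_csv()] / [read_edf()]).
#' @param out_dir Output directory (created if needed).
#' @param K Number of HMM states.
#' @param bands Band definition tibble.
#' @param window_length,overlap_fraction,time_halfbandwidth,n_tapers Spectral
#'   parameters (see [compute_spectrogram()]).
#' @param max_iter,tol,n_restarts EM controls (see [fit_beta_hmm()]).
#' @param seed Integer seed.
#' @param subsets Optional named list of state subsets for duration
#'   statistics, e.g. `list(gamma = c(4, 5))`.
#' @return Invisibly, a list with `fit`, `paths` (per-session tibbles),
#'   `durations`, `delta_pairs`, `out_dir`.
#' @export
run_pipeline <- function(signals, out_dir, K,
                         bands = canonical_bands(), window_length = 1,
                         overlap_fraction = 0.9, time_halfbandwidth = 2,
                         n_tapers = 3, max_iter = 500, tol = 1e-6,
                         n_restarts = 5, seed = 1, subsets = NULL) {
  stopifnot(length(signals) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                                sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cfg <- list(K = K, window_length = window_length,
              overlap_fraction = overlap_fraction,
              time_halfbandwidth = time_halfbandwidth, n_tapers = n_tapers,
              max_iter = max_iter, tol = tol, n_restarts = n_restarts,
              seed = seed, bands = as.data.frame(bands),
              sessions = vapply(signals, function(s) s$label %||% "signal", ""))
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("pipeline start: %d session(s), K = %d, seed = %d",
           length(signals), K, seed)
  Ys <- vector("list", length(signals))
  for (i in seq_along(signals)) {
    s <- signals[[i]]
    tag <- gsub("[^A-Za-z0-9_.-]", "_", s$label %||% paste0("session", i))
    spec <- compute_spectrogram(s$samples, s$fs, window_length,
                                overlap_fraction, time_halfbandwidth, n_tapers)
    bp <- band_power(spec, bands)
    sc <- compute_scaling(bp)
    Ys[[i]] <- scale_observations(bp, sc)
    write_observations_csv(bp, file.path(out_dir, paste0("bandpower_", tag, ".csv")))
    write_observations_csv(Ys[[i]], file.path(out_dir, paste0("scaled_", tag, ".csv")))
    write_scaling_json(sc, file.path(out_dir, paste0("scaling_", tag, ".json")))
    log_line("session %s: %d windows", tag, nrow(bp))
  }
  fit <- fit_beta_hmm(Ys, K, max_iter = max_iter, tol = tol,
                      n_restarts = n_restarts, seed = seed)
  log_line("fit: %d iterations, converged = %s, loglik = %.6f",
           fit$n_iterations, fit$converged,
           fit$loglik_trace[length(fit$loglik_trace)])
  write_beta_hmm(fit$model, file.path(out_dir, "model.json"),
                 meta = list(loglik = fit$loglik_trace[length(fit$loglik_trace)],
                             iterations = fit$n_iterations, seed = seed))
  paths <- vector("list", length(signals))
  for (i in seq_along(signals)) {
    tag <- gsub("[^A-Za-z0-9_.-]", "_",
                signals[[i]]$label %||% paste0("session", i))
    paths[[i]] <- viterbi(Ys[[i]], fit$model)
    utils::write.csv(as.data.frame(paths[[i]]),
                     file.path(out_dir, paste0("path_", tag, ".csv")),
                     row.names = FALSE)
  }
  durations <- NULL
  if (!is.null(subsets)) {
    durations <- dplyr::bind_rows(lapply(names(subsets), function(nm) {
      dplyr::mutate(
        subset_duration_statistics(fit$model$A, subsets[[nm]], seed = seed,
                                   window_step = fit$model$window_step),
        activity = nm, .before = 1)
    }))
    utils::write.csv(as.data.frame(durations),
                     file.path(out_dir, "durations.csv"), row.names = FALSE)
  }
  delta_pairs <- delta_probability_table(fit$model)
  utils::write.csv(as.data.frame(delta_pairs),
                   file.path(out_dir, "delta_pairs.csv"), row.names = FALSE)
  log_line("pipeline done")
  invisible(list(fit = fit, paths = paths, durations = durations,
                 delta_pairs = delta_pairs, out_dir = out_dir))
}
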