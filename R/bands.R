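#' Canonical neural oscillation frequency bands
#'
#' The seven bands commonly used to describe neural oscillations between 0 and
#' 50 Hz: slow (0-1 Hz), delta (1-4), theta (4-8), alpha (8-12), beta (12-25),
#' low gamma (25-35) and gamma (35-50 Hz). Each band is the half-open interval
#' `[lo, hi)`.
#'
#' @return A tibble with columns `band` (character), `lo` and `hi` (Hz).
#' @export
#' @examples
#' canonical_bands()
canonical_bands <- function() {
  tibble::tibble(
    band = c("slow", "delta", "theta", "alpha", "beta", "low_gamma", "gamma"),
    lo   = c(0, 1, 4, 8, 12, 25, 35),
    hi   = c(1, 4, 8, 12, 25, 35, 50)
  )
}

#' Validate a band definition table
#'
#' Bands must be a data frame with columns `band`, `lo`, `hi`, ordered,
#' non-overlapping, with `lo < hi` and unique names.
#'
#' @param bands A data frame of band intervals.
#' @return The bands as a tibble, invisibly validated.
#' @export
validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("band", "lo", "hi") %in% names(bands)))
  bands <- tibble::as_tibble(bands)
  if (nrow(bands) < 1) stop("band definition is empty")
  if (anyDuplicated(bands$band)) stop("duplicated band names")
  if (any(!is.finite(bands$lo)) || any(!is.finite(bands$hi))) {
    stop("band edges must be finite")
  }
  if (any(bands$lo >= bands$hi)) {
    bad <- bands$band[bands$lo >= bands$hi]
    stop("band(s) with lo >= hi: ", paste(bad, collapse = ", "))
  }
  if (is.unsorted(bands$lo, strictly = TRUE)) stop("bands must be ordered by lo")
  if (nrow(bands) > 1 && any(bands$lo[-1] < bands$hi[-nrow(bands)])) {
    stop("bands must not overlap")
  }
  bands
}

#' Read a band definition from a JSON file
#'
#' The file holds an array of objects with fields `band`, `lo`, `hi`, or the
#' string preset `"canonical7"` may be passed directly.
#'
#' @param path Path to a JSON band file, or `"canonical7"`.
#' @return A validated band tibble.
#' @export
read_bands <- function(path) {
  if (identical(path, "canonical7")) return(canonical_bands())
  validate_bands(tibble::as_tibble(jsonlite::fromJSON(path)))
}
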