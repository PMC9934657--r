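#' Construct a fragmentation spectrum
#'
#' A `fragment_spectrum` is the unit of all spectral I/O and similarity math:
#' an m/z-sorted peak list with optional precursor metadata.  Intensities are
#' kept on their raw scale; normalization happens inside the scoring
#' functions, which are scale-invariant.
#'
#' @param mz numeric vector of fragment m/z values (Da, > 0).
#' @param intensity numeric vector of intensities (arbitrary units, >= 0),
#'   same length as `mz`.
#' @param precursor_mz precursor m/z in Da, or `NA` when absent (composite
#'   spectra deconvoluted from MS1 data carry no precursor).
#' @param precursor_rt precursor retention time in minutes, or `NA`.
#' @param metadata named list of free-form character metadata
#'   (Name, InChIKey, adduct annotations, ...).
#'
#' @details Peaks are sorted ascending by m/z.  Two peaks with an identical
#'   m/z value are collapsed into one peak by summing their intensities, so
#'   the stored peak list never contains duplicate masses.
#'
#' @return An object of class `fragment_spectrum` with elements `mz`,
#'   `intensity`, `precursor_mz`, `precursor_rt`, `metadata`.
#' @export
#' @examples
#' sp <- fragment_spectrum(c(146.06, 192.065, 209.092), c(30, 55, 100))
#' n_peaks(sp)
fragment_spectrum <- function(mz, intensity,
                              precursor_mz = NA_real_,
                              precursor_rt = NA_real_,
                              metadata = list()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("`mz` and `intensity` must have the same length", call. = FALSE)
  }
  keep <- is.finite(mz) & is.finite(intensity)
  mz <- mz[keep]
  intensity <- intensity[keep]
  if (any(mz <= 0)) stop("all m/z values must be > 0", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(
    list(
      mz = mz,
      intensity = intensity,
      precursor_mz = as.numeric(precursor_mz)[1],
      precursor_rt = as.numeric(precursor_rt)[1],
      metadata = as.list(metadata)
    ),
    class = "fragment_spectrum"
  )
}

#' Number of peaks in a spectrum
#' @param x a `fragment_spectrum`.
#' @return integer peak count.
#' @export
n_peaks <- function(x) {
  stopifnot(inherits(x, "fragment_spectrum"))
  length(x$mz)
}

#' Total ion intensity of a spectrum
#' @param x a `fragment_spectrum`.
#' @return sum of fragment intensities.
#' @export
total_intensity <- function(x) {
  stopifnot(inherits(x, "fragment_spectrum"))
  sum(x$intensity)
}

#' @export
print.fragment_spectrum <- function(x, ...) {
  nm <- x$metadata$Name
  cat("<fragment_spectrum>",
      if (!is.null(nm)) paste0(" ", nm) else "", "\n", sep = "")
  cat("  peaks: ", length(x$mz), sep = "")
  if (length(x$mz)) {
    cat(sprintf("  (m/z %.4f - %.4f)", min(x$mz), max(x$mz)))
  }
  cat("\n")
  if (is.finite(x$precursor_mz)) {
    cat(sprintf("  precursor m/z: %.5f\n", x$precursor_mz))
  }
  if (is.finite(x$precursor_rt)) {
    cat(sprintf("  retention time: %.3f min\n", x$precursor_rt))
  }
  invisible(x)
}

# intensities normalized to unit sum; errors on an all-zero spectrum
normalize_intensity <- function(x) {
  tot <- sum(x$intensity)
  if (tot <= 0) stop("cannot normalize a spectrum with zero total intensity",
                     call. = FALSE)
  x$intensity <- x$intensity / tot
  x
}
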