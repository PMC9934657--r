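#' Construct a scan table
#'
#' In-memory container for centroided scan data: parallel vectors over
#' scans plus per-scan centroid arrays.  Retention times are minutes
#' everywhere in this package.
#'
#' @param rt numeric, scan start times in minutes, non-decreasing.
#' @param ms_level integer, 1 or 2 per scan.
#' @param mz list of ascending m/z vectors (Da), one per scan.
#' @param intensity list of intensity vectors, same lengths as `mz`.
#' @param precursor_mz numeric, MS2 selected-ion m/z (`NA` for MS1).
#' @param iso_lower,iso_upper numeric, isolation-window bounds in Da
#'   (`NA` when not recorded).
#' @return a `scan_table`.
#' @export
scan_table <- function(rt, ms_level, mz, intensity,
                       precursor_mz = rep(NA_real_, length(rt)),
                       iso_lower = rep(NA_real_, length(rt)),
                       iso_upper = rep(NA_real_, length(rt))) {
  rt <- as.numeric(rt)
  ms_level <- as.integer(ms_level)
  n <- length(rt)
  stopifnot(length(ms_level) == n, length(mz) == n, length(intensity) == n,
            length(precursor_mz) == n, length(iso_lower) == n,
            length(iso_upper) == n)
  if (is.unsorted(rt)) stop("scan retention times must be non-decreasing",
                            call. = FALSE)
  bad <- which(lengths(mz) != lengths(intensity))
  if (length(bad)) {
    stop("mz/intensity length mismatch in scan(s) ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  structure(
    list(rt = rt, ms_level = ms_level, mz = mz, intensity = intensity,
         precursor_mz = as.numeric(precursor_mz),
         iso_lower = as.numeric(iso_lower),
         iso_upper = as.numeric(iso_upper)),
    class = "scan_table"
  )
}

#' @export
print.scan_table <- function(x, ...) {
  cat("<scan_table> ", length(x$rt), " scans (",
      sum(x$ms_level == 1L), " MS1, ", sum(x$ms_level == 2L), " MS2), rt ",
      sprintf("%.3f-%.3f", min(x$rt), max(x$rt)), " min\n", sep = "")
  invisible(x)
}

#' Read LC/HRMS scan data
#'
#' Currently dispatches to the bundled mzML reader; the contract (a
#' centroided [scan_table()] with minutes-based retention times) is
#' independent of the source format.
#'
#' @param path data file path (`.mzML`).
#' @return a `scan_table`.
#' @export
read_scans <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext != "mzml") {
    stop("unsupported scan data format: .", ext,
         " (mzML is supported)", call. = FALSE)
  }
  read_mzml(path)
}

# Required columns of the chromatographic peak-list schema; mz_13C is the
# only optional column.
.peaklist_required <- c("peak_id", "mz_12C", "rt_apex", "rt_start",
                        "rt_end", "height", "snr")

#' Read an MS1 chromatographic peak list
#'
#' Tabular text (TSV or CSV by extension) with named columns `peak_id`,
#' `mz_12C`, `mz_13C` (optional; blank when no carbon-isotopologue partner
#' was certified), `rt_apex`, `rt_start`, `rt_end` (minutes), `height`,
#' `snr` — the schema emitted by upstream MS1 peak pickers.  Rows that
#' violate the peak invariants (`rt_start < rt_apex < rt_end`,
#' `height > 0`, `snr > 0`, isotopologue spacing in `[1.0000, 1.0070]` Da)
#' are dropped with a warning.
#'
#' @param path peak-list path.
#' @return a data.frame of validated peaks.
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  miss <- setdiff(.peaklist_required, names(df))
  if (length(miss)) {
    stop("peak list is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"mz_13C" %in% names(df)) df$mz_13C <- NA_real_
  df$mz_13C <- suppressWarnings(as.numeric(df$mz_13C))
  ok <- with(df, rt_start < rt_apex & rt_apex < rt_end &
                   height > 0 & snr > 0 & mz_12C > 0)
  iso <- df$mz_13C - df$mz_12C
  ok <- ok & (is.na(df$mz_13C) | (iso >= 1.0000 & iso <= 1.0070))
  ok[is.na(ok)] <- FALSE
  if (any(!ok)) {
    warning(sum(!ok), " peak-list row(s) violate peak invariants; dropped",
            call. = FALSE)
  }
  df <- df[ok, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Extract an ion chromatogram (EIC)
#'
#' One intensity per scan of the requested MS level inside the retention
#' window: the summed intensity of all centroids within the m/z tolerance
#' (0 when none).  The window is half-open, `[start, end)`, so adjacent
#' windows never double-count a scan.
#'
#' @param scans a [scan_table()].
#' @param mz target m/z in Da.
#' @param mz_tol tolerance value; interpreted per `tol_unit`.
#' @param tol_unit `"ppm"` (default) or `"da"`.
#' @param rt_window `c(start, end)` in minutes, or `NULL` for the full run.
#' @param ms_level scans of this MS level only.
#' @param precursor_in_window for MS2 extraction from data-independent
#'   acquisition: when `TRUE`-like (a precursor m/z), only MS2 scans whose
#'   isolation window contains that m/z are used (scans without a recorded
#'   window are accepted).
#' @return an `eic`: list with `rt`, `intensity`, `smoothed = FALSE`.
#' @export
extract_eic <- function(scans, mz, mz_tol = 10, tol_unit = c("ppm", "da"),
                        rt_window = NULL, ms_level = 1L,
                        precursor_in_window = NULL) {
  stopifnot(inherits(scans, "scan_table"))
  tol_unit <- match.arg(tol_unit)
  tol_da <- if (tol_unit == "ppm") mz * mz_tol * 1e-6 else mz_tol
  sel <- scans$ms_level == ms_level
  if (!is.null(rt_window)) {
    if (rt_window[2] <= rt_window[1]) {
      stop("empty retention-time window", call. = FALSE)
    }
    sel <- sel & scans$rt >= rt_window[1] & scans$rt < rt_window[2]
  }
  if (!is.null(precursor_in_window)) {
    in_iso <- is.na(scans$iso_lower) |
      (scans$iso_lower <= precursor_in_window &
         scans$iso_upper >= precursor_in_window)
    sel <- sel & in_iso
  }
  idx <- which(sel)
  ints <- vapply(idx, function(i) {
    m <- scans$mz[[i]]
    if (!length(m)) return(0)
    hit <- abs(m - mz) <= tol_da
    if (any(hit)) sum(scans$intensity[[i]][hit]) else 0
  }, numeric(1))
  structure(list(mz = mz, rt = scans$rt[idx], intensity = ints,
                 smoothed = FALSE),
            class = "eic")
}

#' Smooth an EIC (LOESS then cubic spline)
#'
#' A locally weighted quadratic regression (span `loess_span`) is fitted
#' to the raw chromatogram and evaluated at the raw retention times, then
#' cubic-spline interpolated onto a uniform grid of `grid_n` points over
#' the EIC's retention interval.  Negative interpolated values are clipped
#' to zero.  The smoothing removes scan-to-scan jaggedness before
#' elution-profile correlation without moving the peak apex.
#'
#' @param eic an `eic` with at least 5 points.
#' @param loess_span LOESS span as a fraction of points (default 0.2; the
#'   effective span is raised when the chromatogram is short, since a
#'   quadratic local fit needs several points per window).
#' @param grid_n number of uniform grid points (default 100).
#' @param grid optional explicit retention-time grid (minutes) to
#'   interpolate onto instead of the EIC's own uniform grid; used to put
#'   chromatograms from different scan sets (e.g. MS1 vs MS2 channels)
#'   onto one grid before correlation.
#' @return a smoothed `eic` (`smoothed = TRUE`) on the uniform grid.
#' @export
smooth_eic <- function(eic, loess_span = 0.2, grid_n = 100, grid = NULL) {
  stopifnot(inherits(eic, "eic"))
  n <- length(eic$rt)
  if (n < 5) {
    stop("EIC has fewer than 5 points; too short to smooth/correlate",
         call. = FALSE)
  }
  # a quadratic local fit needs >= 3 points in the neighborhood
  span_use <- min(1, max(loess_span, 3 / n))
  fit <- tryCatch(
    suppressWarnings(
      stats::loess(eic$intensity ~ eic$rt, span = span_use, degree = 2,
                   family = "gaussian",
                   control = stats::loess.control(surface = "direct"))),
    error = function(e) NULL
  )
  fitted_vals <- if (is.null(fit)) eic$intensity else stats::fitted(fit)
  if (is.null(grid)) grid <- seq(min(eic$rt), max(eic$rt), length.out = grid_n)
  sm <- stats::spline(eic$rt, fitted_vals, xout = grid, method = "fmm")
  structure(list(mz = eic$mz, rt = sm$x, intensity = pmax(sm$y, 0),
                 smoothed = TRUE),
            class = "eic")
}
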