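#' Parameters for DDA spectrum extraction
#'
#' @param consolidation how repeated MS2 scans of the same precursor
#'   within one chromatographic peak are combined: `"integrate_all"`
#'   (per-fragment-bin intensity sum), `"most_abundant"` (the single scan
#'   with the largest total ion intensity), or `"denoise"` (drop flat
#'   fragments by RSD, then keep fragments whose across-scan profile
#'   correlates with the precursor's MS1 chromatogram).
#' @param rsd_flat_max percent; fragments with across-scan relative
#'   standard deviation at or below this are considered flat
#'   (acquisition-level noise) and removed under `"denoise"`.
#' @param pearson_min correlation threshold for `"denoise"`.
#' @param precursor_mz_tol Da; MS2 precursor matching tolerance.
#' @param resolution_tol Da; fragment binning width across repeated scans
#'   (the same notion of "same fragment" as [resolve_adjacent()]).
#' @return a `dda_params` list.
#' @export
dda_params <- function(consolidation = c("integrate_all", "most_abundant",
                                         "denoise"),
                       rsd_flat_max = 25,
                       pearson_min = 0.8,
                       precursor_mz_tol = 0.01,
                       resolution_tol = 0.01) {
  consolidation <- match.arg(consolidation)
  p <- list(consolidation = consolidation,
            rsd_flat_max = as.numeric(rsd_flat_max),
            pearson_min = as.numeric(pearson_min),
            precursor_mz_tol = as.numeric(precursor_mz_tol),
            resolution_tol = as.numeric(resolution_tol))
  stopifnot(p$rsd_flat_max >= 0, p$pearson_min >= -1, p$pearson_min <= 1,
            p$precursor_mz_tol > 0, p$resolution_tol >= 0)
  class(p) <- "dda_params"
  p
}

#' Parameters for DIA spectrum extraction
#'
#' @param pearson_min minimum correlation between a fragment's MS2-level
#'   chromatogram and the precursor peak's MS1 chromatogram.
#' @param height_fraction correlation trimming as in [csa_params()].
#' @param fragment_mz_tol Da; MS2-level EIC extraction tolerance.
#' @param loess_span,grid_n smoothing controls.
#' @return a `dia_params` list.
#' @export
dia_params <- function(pearson_min = 0.8,
                       height_fraction = 0.5,
                       fragment_mz_tol = 0.01,
                       loess_span = 0.2, grid_n = 100) {
  p <- list(pearson_min = as.numeric(pearson_min),
            height_fraction = as.numeric(height_fraction),
            fragment_mz_tol = as.numeric(fragment_mz_tol),
            loess_span = as.numeric(loess_span),
            grid_n = as.integer(grid_n))
  stopifnot(p$pearson_min >= -1, p$pearson_min <= 1,
            p$height_fraction >= 0, p$height_fraction < 1,
            p$fragment_mz_tol > 0)
  class(p) <- "dia_params"
  p
}

# Bin pooled fragment m/z values by run-merging with `tol` (the
# resolve_adjacent rule); returns for each input point its bin index and
# the per-bin reference m/z (intensity-weighted mean).
.bin_fragments <- function(mz, intensity, tol) {
  o <- order(mz)
  run <- cumsum(c(0L, as.integer(diff(mz[o]) > tol)))
  bin_of <- integer(length(mz))
  bin_of[o] <- run + 1L
  wm <- vapply(split(seq_along(mz), bin_of), function(ii) {
    w <- intensity[ii]
    if (sum(w) > 0) sum(mz[ii] * w) / sum(w) else mean(mz[ii])
  }, numeric(1))
  list(bin = bin_of, bin_mz = wm)
}

#' Extract DDA fragmentation spectra
#'
#' For each MS1 chromatographic peak, MS2 scans whose selected precursor
#' matches the peak's carbon-12 m/z within tolerance and whose retention
#' time lies inside the peak's bounds are collected and consolidated per
#' `params$consolidation`.  Peaks with no matching MS2 scan are skipped.
#'
#' @param scans a [scan_table()] containing MS2 scans with precursors.
#' @param peaks peak-list data.frame (see [read_peaklist()]).
#' @param params a [dda_params()].
#' @param mz_tol,tol_unit MS1 EIC tolerance for the denoise reference.
#' @return list of `fragment_spectrum` with precursor m/z and retention
#'   time set; empty when nothing matched.
#' @export
extract_dda <- function(scans, peaks, params = dda_params(),
                        mz_tol = 10, tol_unit = "ppm") {
  stopifnot(inherits(scans, "scan_table"))
  out <- list()
  ms2 <- which(scans$ms_level == 2L & is.finite(scans$precursor_mz))
  for (p in seq_len(nrow(peaks))) {
    hit <- ms2[abs(scans$precursor_mz[ms2] - peaks$mz_12C[p]) <=
                 params$precursor_mz_tol &
               scans$rt[ms2] >= peaks$rt_start[p] &
               scans$rt[ms2] <= peaks$rt_end[p]]
    if (!length(hit)) {
      message("peak ", peaks$peak_id[p], ": no matching MS2 scans; skipped")
      next
    }
    meta <- list(Name = sprintf("DDA_peak_%d", peaks$peak_id[p]),
                 Consolidation = params$consolidation)
    if (length(hit) == 1L || params$consolidation == "most_abundant") {
      tic <- vapply(hit, function(i) sum(scans$intensity[[i]]), numeric(1))
      i <- hit[which.max(tic)]
      sp <- fragment_spectrum(scans$mz[[i]], scans$intensity[[i]],
                              precursor_mz = peaks$mz_12C[p],
                              precursor_rt = peaks$rt_apex[p],
                              metadata = meta)
      out[[length(out) + 1L]] <- sp
      next
    }
    # pooled per-scan x per-bin intensity matrix
    all_mz <- unlist(scans$mz[hit])
    all_int <- unlist(scans$intensity[hit])
    scan_of <- rep(seq_along(hit), lengths(scans$mz[hit]))
    bins <- .bin_fragments(all_mz, all_int, params$resolution_tol)
    nb <- length(bins$bin_mz)
    mat <- matrix(0, nrow = length(hit), ncol = nb)
    mat[cbind(scan_of, bins$bin)] <- all_int
    keep <- rep(TRUE, nb)
    if (params$consolidation == "denoise") {
      mu <- colMeans(mat)
      rsd <- 100 * apply(mat, 2, stats::sd) / ifelse(mu > 0, mu, Inf)
      keep <- rsd > params$rsd_flat_max
      # correlation against the precursor's MS1 chromatogram sampled at
      # the MS2 scan retention times
      eic <- extract_eic(scans, peaks$mz_12C[p], mz_tol = mz_tol,
                         tol_unit = tol_unit,
                         rt_window = c(peaks$rt_start[p], peaks$rt_end[p]))
      ref <- stats::approx(eic$rt, eic$intensity, xout = scans$rt[hit],
                           rule = 2)$y
      for (b in which(keep)) {
        r <- suppressWarnings(stats::cor(mat[, b], ref))
        if (!is.finite(r) || r < params$pearson_min) keep[b] <- FALSE
      }
    }
    if (!any(keep)) {
      message("peak ", peaks$peak_id[p],
              ": all fragments removed during consolidation; skipped")
      next
    }
    sp <- fragment_spectrum(bins$bin_mz[keep], colSums(mat)[keep],
                            precursor_mz = peaks$mz_12C[p],
                            precursor_rt = peaks$rt_apex[p],
                            metadata = meta)
    out[[length(out) + 1L]] <- sp
  }
  out
}

#' Extract DIA fragmentation spectra
#'
#' For each MS1 peak, candidate fragment m/z values are read from the MS2
#' scan nearest in retention time to the peak's MS1 apex (honoring the
#' isolation window when recorded).  Each candidate's MS2-level
#' chromatogram over the peak's bounds is smoothed and correlated against
#' the peak's own MS1 chromatogram; fragments at r >= `pearson_min` form
#' the spectrum, with the MS1 peak as precursor and each fragment's apex
#' chromatogram height as its intensity.
#'
#' @param scans a [scan_table()] with MS2 scans (MSe/SWATH channels).
#' @param peaks peak-list data.frame.
#' @param params a [dia_params()].
#' @param mz_tol,tol_unit MS1 EIC tolerance for the precursor reference.
#' @return list of `fragment_spectrum`.
#' @export
extract_dia <- function(scans, peaks, params = dia_params(),
                        mz_tol = 10, tol_unit = "ppm") {
  stopifnot(inherits(scans, "scan_table"))
  if (!any(scans$ms_level == 2L)) {
    warning("no MS2 scans present; DIA extraction yields nothing",
            call. = FALSE)
    return(list())
  }
  out <- list()
  for (p in seq_len(nrow(peaks))) {
    window <- c(peaks$rt_start[p], peaks$rt_end[p])
    in_iso <- scans$ms_level == 2L &
      (is.na(scans$iso_lower) |
         (scans$iso_lower <= peaks$mz_12C[p] &
            scans$iso_upper >= peaks$mz_12C[p]))
    ms2 <- which(in_iso & scans$rt >= window[1] & scans$rt <= window[2])
    if (!length(ms2)) next
    apex_scan <- ms2[which.min(abs(scans$rt[ms2] - peaks$rt_apex[p]))]
    cand_mz <- scans$mz[[apex_scan]]
    cand_mz <- cand_mz[scans$intensity[[apex_scan]] > 0]
    if (!length(cand_mz)) next
    ms1_eic <- extract_eic(scans, peaks$mz_12C[p], mz_tol = mz_tol,
                           tol_unit = tol_unit, rt_window = window)
    if (length(ms1_eic$rt) < 5 || max(ms1_eic$intensity) <= 0) next
    ms1_sm <- smooth_eic(ms1_eic, params$loess_span, params$grid_n)
    frag_mz <- numeric(0); frag_int <- numeric(0)
    for (fm in cand_mz) {
      feic <- extract_eic(scans, fm, mz_tol = params$fragment_mz_tol,
                          tol_unit = "da", rt_window = window,
                          ms_level = 2L, precursor_in_window = peaks$mz_12C[p])
      if (length(feic$rt) < 5 || max(feic$intensity) <= 0) next
      fsm <- smooth_eic(feic, params$loess_span, params$grid_n,
                        grid = ms1_sm$rt)
      r <- profile_correlation(ms1_sm, fsm, params$height_fraction)
      if (r >= params$pearson_min) {
        frag_mz <- c(frag_mz, fm)
        frag_int <- c(frag_int, max(feic$intensity))
      }
    }
    if (!length(frag_mz)) next
    out[[length(out) + 1L]] <- fragment_spectrum(
      frag_mz, frag_int,
      precursor_mz = peaks$mz_12C[p],
      precursor_rt = peaks$rt_apex[p],
      metadata = list(Name = sprintf("DIA_peak_%d", peaks$peak_id[p]))
    )
  }
  out
}
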