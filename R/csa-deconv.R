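#' Parameters for composite-spectra (CSA) deconvolution
#'
#' Defaults follow the published filter chain: seeds need S/N >= 5,
#' co-elution candidates are gathered in a 0.01-min retention window,
#' members must correlate with the seed's smoothed elution profile at
#' Pearson r >= 0.98, clusters need at least two peaks and a carbon-12
#' m/z span greater than 8 Da (suppressing pure isotopologue envelopes).
#'
#' @param seed_snr_min minimum S/N for a seed peak.
#' @param rt_group_window minutes; half-width of the co-elution grouping
#'   window (closed on both ends).
#' @param pearson_min minimum Pearson correlation between smoothed EICs.
#' @param height_fraction fraction of each EIC's own apex height below
#'   which grid points are excluded from the correlation (trims tailing
#'   and fronting).
#' @param min_ions minimum number of carbon-12 members per cluster.
#' @param min_mz_span Da; the carbon-12 m/z span must exceed this.
#' @param intersample_r_min minimum across-sample height correlation with
#'   the seed on the aligned table (`NA` disables the filter).
#' @param mz_tol,tol_unit EIC extraction tolerance (see [extract_eic()]).
#' @param loess_span,grid_n smoothing controls (see [smooth_eic()]).
#' @return a `csa_params` list.
#' @export
csa_params <- function(seed_snr_min = 5,
                       rt_group_window = 0.01,
                       pearson_min = 0.98,
                       height_fraction = 0.5,
                       min_ions = 2,
                       min_mz_span = 8,
                       intersample_r_min = 0.5,
                       mz_tol = 10, tol_unit = "ppm",
                       loess_span = 0.2, grid_n = 100) {
  p <- list(seed_snr_min = as.numeric(seed_snr_min),
            rt_group_window = as.numeric(rt_group_window),
            pearson_min = as.numeric(pearson_min),
            height_fraction = as.numeric(height_fraction),
            min_ions = as.integer(min_ions),
            min_mz_span = as.numeric(min_mz_span),
            intersample_r_min = as.numeric(intersample_r_min),
            mz_tol = as.numeric(mz_tol), tol_unit = tol_unit,
            loess_span = as.numeric(loess_span),
            grid_n = as.integer(grid_n))
  stopifnot(p$pearson_min > 0, p$pearson_min <= 1,
            p$height_fraction >= 0, p$height_fraction < 1,
            p$min_ions >= 2, p$min_mz_span > 0,
            p$rt_group_window > 0, p$seed_snr_min >= 0,
            is.na(p$intersample_r_min) ||
              (p$intersample_r_min >= -1 && p$intersample_r_min <= 1))
  class(p) <- "csa_params"
  p
}

#' Select the next seed peak
#'
#' The unassigned peak of maximal height with S/N at or above the
#' threshold; height ties break to the lower `peak_id` for determinism.
#'
#' @param peaks validated peak-list data.frame.
#' @param assigned logical vector over `peaks` rows.
#' @param params a [csa_params()].
#' @return the row index of the seed, or `NULL` when no eligible peak
#'   remains (the deconvolution loop terminator).
#' @export
select_seed <- function(peaks, assigned, params) {
  cand <- which(!assigned & peaks$snr >= params$seed_snr_min)
  if (!length(cand)) return(NULL)
  cand[order(-peaks$height[cand], peaks$peak_id[cand])][1]
}

#' Group potentially co-eluting candidate peaks around a seed
#'
#' Unassigned peaks whose retention-time apex lies within
#' `rt_group_window` of the seed's apex (window closed on both ends),
#' excluding the seed itself.
#'
#' @param peaks peak-list data.frame.
#' @param seed_idx seed row index.
#' @param assigned logical vector over rows.
#' @param params a [csa_params()].
#' @return integer vector of candidate row indices.
#' @export
group_candidates <- function(peaks, seed_idx, assigned, params) {
  drt <- abs(peaks$rt_apex - peaks$rt_apex[seed_idx])
  which(!assigned & drt <= params$rt_group_window &
          seq_len(nrow(peaks)) != seed_idx)
}

#' Pearson correlation between two smoothed elution profiles
#'
#' Computed over grid points where BOTH profiles exceed `height_fraction`
#' of their own apex, which trims peak tails and fronts.  Fewer than 5
#' such shared points, or a degenerate (zero-variance) profile, returns
#' -1, marking the pair non-correlatable.
#'
#' @param eic_a,eic_b smoothed `eic` objects on the same grid.
#' @param height_fraction fraction of each profile's own apex.
#' @return Pearson r in `[-1, 1]`.
#' @export
profile_correlation <- function(eic_a, eic_b, height_fraction = 0.5) {
  stopifnot(inherits(eic_a, "eic"), inherits(eic_b, "eic"))
  if (!eic_a$smoothed || !eic_b$smoothed) {
    stop("profile_correlation requires smoothed EICs", call. = FALSE)
  }
  if (length(eic_a$rt) != length(eic_b$rt) ||
      max(abs(eic_a$rt - eic_b$rt)) > 1e-9) {
    stop("EICs are not on the same retention-time grid", call. = FALSE)
  }
  ma <- max(eic_a$intensity); mb <- max(eic_b$intensity)
  if (ma <= 0 || mb <= 0) return(-1)
  idx <- eic_a$intensity > height_fraction * ma &
         eic_b$intensity > height_fraction * mb
  if (sum(idx) < 5) return(-1)
  r <- suppressWarnings(stats::cor(eic_a$intensity[idx],
                                   eic_b$intensity[idx]))
  if (!is.finite(r)) -1 else r
}

#' Across-sample correlation filter on the aligned peak table
#'
#' Retains candidates whose across-sample height vector correlates with
#' the seed's at Pearson r >= `r_min`, computed on samples where both
#' peaks were detected (height > 0).  With fewer than 5 shared samples
#' the candidate is retained by default (the filter abstains rather than
#' rejects on thin evidence).  Candidates or seeds with no aligned-table
#' row are retained.
#'
#' @param aligned aligned table data.frame: columns `row_id`, `mz`, `rt`,
#'   then one numeric height column per sample (see [read_aligned()]).
#' @param peaks peak-list data.frame.
#' @param seed_idx,candidate_idx row indices into `peaks`.
#' @param r_min correlation threshold.
#' @param mz_tol_da,rt_tol Da / minutes tolerances used to map peaks onto
#'   aligned rows.
#' @return the retained subset of `candidate_idx`.
#' @export
intersample_filter <- function(aligned, peaks, seed_idx, candidate_idx,
                               r_min, mz_tol_da = 0.01, rt_tol = 0.05) {
  if (is.null(aligned) || is.na(r_min) || !length(candidate_idx)) {
    return(candidate_idx)
  }
  samp_cols <- setdiff(names(aligned), c("row_id", "mz", "rt"))
  find_row <- function(i) {
    d_mz <- abs(aligned$mz - peaks$mz_12C[i])
    d_rt <- abs(aligned$rt - peaks$rt_apex[i])
    hit <- which(d_mz <= mz_tol_da & d_rt <= rt_tol)
    if (!length(hit)) return(NA_integer_)
    hit[which.min(d_mz[hit])]
  }
  srow <- find_row(seed_idx)
  if (is.na(srow)) return(candidate_idx)
  sv <- as.numeric(aligned[srow, samp_cols])
  keep <- vapply(candidate_idx, function(i) {
    crow <- find_row(i)
    if (is.na(crow)) return(TRUE)
    cv <- as.numeric(aligned[crow, samp_cols])
    shared <- which(sv > 0 & cv > 0)
    if (length(shared) < 5) return(TRUE)
    r <- suppressWarnings(stats::cor(sv[shared], cv[shared]))
    is.finite(r) && r >= r_min
  }, logical(1))
  candidate_idx[keep]
}

#' Read an aligned peak-height table
#'
#' Tabular text with columns `row_id`, `mz`, `rt` followed by one numeric
#' column of peak heights per sample (0 = not detected).
#'
#' @param path TSV/CSV path.
#' @return a data.frame.
#' @export
read_aligned <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("row_id", "mz", "rt"), names(df))
  if (length(miss)) {
    stop("aligned table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

# Smooth a member EIC over the seed's retention window onto the common
# grid; NULL when the raw EIC is too short.
.smoothed_member_eic <- function(scans, mz, window, params) {
  eic <- extract_eic(scans, mz, mz_tol = params$mz_tol,
                     tol_unit = params$tol_unit, rt_window = window)
  if (length(eic$rt) < 5 || max(eic$intensity) <= 0) return(NULL)
  smooth_eic(eic, loess_span = params$loess_span, grid_n = params$grid_n)
}

#' Build one CSA cluster around a seed
#'
#' Correlates each candidate's smoothed EIC (extracted over the seed's
#' retention bounds) against the seed's profile; candidates at r >=
#' `pearson_min` become members.  A cluster is emitted only when the
#' member count reaches `min_ions` and the carbon-12 m/z span exceeds
#' `min_mz_span`.  The exported spectrum holds every member's carbon-12
#' m/z at the apex height of its own EIC plus, for members carrying a
#' certified carbon-13 partner, that isotopologue m/z at its own apex EIC
#' height; isotopologues never count toward the ion or span filters.
#'
#' @param peaks peak-list data.frame.
#' @param seed_idx,candidate_idx row indices.
#' @param scans a [scan_table()].
#' @param params a [csa_params()].
#' @param file_id label stored on the cluster.
#' @return a list: `members` (row indices incl. seed, the set to mark
#'   assigned) and `cluster` (a `csa_cluster` or `NULL` when the filters
#'   reject the seed's neighborhood).
#' @export
build_cluster <- function(peaks, seed_idx, candidate_idx, scans, params,
                          file_id = "file1") {
  window <- c(peaks$rt_start[seed_idx], peaks$rt_end[seed_idx])
  seed_sm <- .smoothed_member_eic(scans, peaks$mz_12C[seed_idx], window,
                                  params)
  if (is.null(seed_sm)) {
    return(list(members = seed_idx, cluster = NULL))
  }
  rs <- vapply(candidate_idx, function(i) {
    cand_sm <- .smoothed_member_eic(scans, peaks$mz_12C[i], window, params)
    if (is.null(cand_sm)) return(-1)
    profile_correlation(seed_sm, cand_sm, params$height_fraction)
  }, numeric(1))
  keep <- rs >= params$pearson_min
  members <- c(seed_idx, candidate_idx[keep])
  member_r <- c(1, rs[keep])
  span <- max(peaks$mz_12C[members]) - min(peaks$mz_12C[members])
  if (length(members) < params$min_ions || span <= params$min_mz_span) {
    return(list(members = members, cluster = NULL))
  }
  mzs <- peaks$mz_12C[members]
  ints <- peaks$height[members]
  iso <- which(!is.na(peaks$mz_13C[members]))
  for (k in iso) {
    i <- members[k]
    eic13 <- extract_eic(scans, peaks$mz_13C[i], mz_tol = params$mz_tol,
                         tol_unit = params$tol_unit,
                         rt_window = c(peaks$rt_start[i], peaks$rt_end[i]))
    h13 <- if (length(eic13$intensity)) max(eic13$intensity) else 0
    if (h13 > 0) {
      mzs <- c(mzs, peaks$mz_13C[i])
      ints <- c(ints, h13)
    }
  }
  spec <- fragment_spectrum(
    mzs, ints,
    precursor_rt = peaks$rt_apex[seed_idx],
    metadata = list(
      Name = sprintf("CSA_%s_%d", file_id, peaks$peak_id[seed_idx]),
      Comment = paste(sprintf("mz=%.5f r=%.4f", peaks$mz_12C[members],
                              member_r), collapse = "; ")
    )
  )
  cluster <- structure(
    list(seed_peak_id = peaks$peak_id[seed_idx],
         member_peak_ids = peaks$peak_id[members],
         member_r = member_r,
         rt_apex = peaks$rt_apex[seed_idx],
         spectrum = spec,
         file_id = file_id),
    class = "csa_cluster"
  )
  list(members = members, cluster = cluster)
}

#' @export
print.csa_cluster <- function(x, ...) {
  cat(sprintf("<csa_cluster> seed %d @ %.3f min, %d ions, file %s\n",
              x$seed_peak_id, x$rt_apex, length(x$member_peak_ids),
              x$file_id))
  invisible(x)
}

#' Deconvolute one file into CSA clusters
#'
#' Iterates seed selection, retention-window grouping, the optional
#' across-sample filter, and cluster construction until no eligible seed
#' remains.  Every peak is assigned to at most one cluster; a seed whose
#' neighborhood fails the filters is still marked assigned (it can never
#' be absorbed later), which guarantees termination and a deterministic,
#' input-order-independent result.
#'
#' @param scans a [scan_table()].
#' @param peaks validated peak-list data.frame (see [read_peaklist()]).
#' @param aligned optional aligned table for the across-sample filter.
#' @param params a [csa_params()].
#' @param file_id label for emitted clusters.
#' @return list of `csa_cluster`.
#' @export
deconvolute_file <- function(scans, peaks, aligned = NULL,
                             params = csa_params(), file_id = "file1") {
  stopifnot(inherits(scans, "scan_table"), is.data.frame(peaks))
  assigned <- logical(nrow(peaks))
  clusters <- list()
  repeat {
    seed_idx <- select_seed(peaks, assigned, params)
    if (is.null(seed_idx)) break
    cand <- group_candidates(peaks, seed_idx, assigned, params)
    if (!is.null(aligned)) {
      cand <- intersample_filter(aligned, peaks, seed_idx, cand,
                                 params$intersample_r_min)
    }
    res <- build_cluster(peaks, seed_idx, cand, scans, params, file_id)
    assigned[res$members] <- TRUE
    if (!is.null(res$cluster)) {
      clusters[[length(clusters) + 1L]] <- res$cluster
    }
  }
  clusters
}

#' Link clusters to known targets
#'
#' Clusters containing a member ion matching a target m/z within
#' `mz_tol_da` and whose apex retention time is within `rt_tol` of the
#' target's gain the target's name in the exported spectrum metadata
#' (`True_positive`).  A target matching several clusters annotates all
#' of them with a warning.
#'
#' @param clusters list of `csa_cluster`.
#' @param targets data.frame with columns `name`, `mz`, `rt`.
#' @param mz_tol_da Da tolerance.
#' @param rt_tol minutes tolerance.
#' @return the annotated cluster list.
#' @export
link_true_positive <- function(clusters, targets, mz_tol_da = 0.01,
                               rt_tol = 0.05) {
  for (t in seq_len(nrow(targets))) {
    hits <- which(vapply(clusters, function(cl) {
      abs(cl$rt_apex - targets$rt[t]) <= rt_tol &&
        any(abs(cl$spectrum$mz - targets$mz[t]) <= mz_tol_da)
    }, logical(1)))
    if (length(hits) > 1) {
      warning("target '", targets$name[t], "' matches ", length(hits),
              " clusters", call. = FALSE)
    }
    for (h in hits) {
      clusters[[h]]$spectrum$metadata$True_positive <- targets$name[t]
    }
  }
  clusters
}

#' Export CSA clusters as spectra
#'
#' @param clusters list of `csa_cluster`.
#' @return list of `fragment_spectrum` (one per cluster, retention time
#'   carried as `precursor_rt`, no precursor m/z).
#' @export
clusters_to_spectra <- function(clusters) {
  lapply(clusters, function(cl) cl$spectrum)
}
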