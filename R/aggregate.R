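#' Aggregate recurring spectra across files into unique variants
#'
#' Greedy single-linkage over the input stream ordered by descending total
#' intensity (ties broken by `(file_id, spectrum_id)`): each spectrum
#' joins the first existing variant whose retention-time center is within
#' `rt_window` and whose representative scores an entropy similarity of at
#' least `entsim_min`; otherwise it founds a new variant.  Because the
#' stream is intensity-ordered, a variant's founder is also its
#' representative (the member with the highest total intensity) and its
#' retention-time center.  Detection frequency counts distinct files.
#'
#' @param spectra list of records, each a list with elements `spectrum`
#'   (a `fragment_spectrum`), `file_id`, `spectrum_id`, and `rt` (minutes;
#'   defaults to the spectrum's `precursor_rt`).
#' @param rt_window minutes (default 0.1).
#' @param entsim_min entropy-similarity threshold (default 0.75).
#' @param fragment_mz_tol Da; peak-combination tolerance inside the
#'   entropy similarity.
#' @return list of `spectrum_variant`: `representative`, `member_refs`
#'   (data.frame `file_id`, `spectrum_id`), `detection_frequency`,
#'   `rt_center`, `n_members`.
#' @export
aggregate_variants <- function(spectra, rt_window = 0.1,
                               entsim_min = 0.75,
                               fragment_mz_tol = 0.01) {
  if (!length(spectra)) return(list())
  recs <- lapply(spectra, function(s) {
    stopifnot(inherits(s$spectrum, "fragment_spectrum"))
    rt <- if (!is.null(s$rt)) s$rt else s$spectrum$precursor_rt
    if (!is.finite(rt)) {
      stop("every spectrum entering aggregation must carry a retention time",
           call. = FALSE)
    }
    list(spectrum = s$spectrum, file_id = as.character(s$file_id),
         spectrum_id = as.character(s$spectrum_id), rt = rt,
         tot = total_intensity(s$spectrum))
  })
  o <- order(-vapply(recs, `[[`, 0, "tot"),
             vapply(recs, `[[`, "", "file_id"),
             vapply(recs, `[[`, "", "spectrum_id"))
  recs <- recs[o]
  variants <- list()
  for (rec in recs) {
    placed <- FALSE
    for (v in seq_along(variants)) {
      if (abs(rec$rt - variants[[v]]$rt_center) > rt_window) next
      sim <- entropy_similarity(variants[[v]]$representative, rec$spectrum,
                                fragment_mz_tol)
      if (sim >= entsim_min) {
        variants[[v]]$member_refs <- rbind(
          variants[[v]]$member_refs,
          data.frame(file_id = rec$file_id, spectrum_id = rec$spectrum_id))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      variants[[length(variants) + 1L]] <- list(
        representative = rec$spectrum,
        member_refs = data.frame(file_id = rec$file_id,
                                 spectrum_id = rec$spectrum_id),
        rt_center = rec$rt
      )
    }
  }
  lapply(variants, function(v) {
    v$detection_frequency <- length(unique(v$member_refs$file_id))
    v$n_members <- nrow(v$member_refs)
    class(v) <- "spectrum_variant"
    v
  })
}

#' @export
print.spectrum_variant <- function(x, ...) {
  cat(sprintf(
    "<spectrum_variant> rt %.3f min, %d members in %d file(s)\n",
    x$rt_center, x$n_members, x$detection_frequency))
  invisible(x)
}

#' Variant frequency table
#'
#' @param variants output of [aggregate_variants()].
#' @return data.frame (`variant_id`, `rt_center`, `n_members`,
#'   `detection_frequency`, `frequency_pct`) where the percentage is over
#'   the distinct files seen in the whole input.
#' @export
variant_frequency_table <- function(variants) {
  all_files <- unique(unlist(lapply(variants, function(v)
    v$member_refs$file_id)))
  nf <- max(1L, length(all_files))
  data.frame(
    variant_id = seq_along(variants),
    rt_center = vapply(variants, `[[`, 0, "rt_center"),
    n_members = vapply(variants, `[[`, 0L, "n_members"),
    detection_frequency = vapply(variants, `[[`, 0L,
                                 "detection_frequency"),
    frequency_pct = 100 * vapply(variants, `[[`, 0L,
                                 "detection_frequency") / nf
  )
}

# union-find for transitive merging
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Batch-consensus spectra from aligned-table ion sets
#'
#' Each cluster is represented as the set of aligned-table row ids of its
#' member ions.  Cluster pairs whose Tanimoto coefficient
#' `|A n B| / |A u B|` reaches `tanimoto_min` are merged transitively;
#' each merged group emits one consensus spectrum containing the ions
#' present in at least `quorum` of the group's clusters, at the median of
#' their apex heights, with m/z looked up from the aligned table.
#'
#' @param cluster_ion_sets list; each element has `rows` (integer
#'   aligned-row ids) and `heights` (numeric, parallel to `rows`).
#'   Elements with no aligned-row mapping are excluded with a warning.
#' @param aligned aligned table data.frame (`row_id`, `mz`, ...).
#' @param tanimoto_min Tanimoto threshold in `(0, 1]`.
#' @param quorum fraction of a group's clusters an ion must appear in
#'   (default 0.5).
#' @return list of consensus `fragment_spectrum`.
#' @export
consensus_from_aligned <- function(cluster_ion_sets, aligned,
                                   tanimoto_min = 0.5, quorum = 0.5) {
  stopifnot(tanimoto_min > 0, tanimoto_min <= 1)
  has_rows <- vapply(cluster_ion_sets, function(cl) length(cl$rows) > 0,
                     logical(1))
  if (any(!has_rows)) {
    warning(sum(!has_rows),
            " cluster(s) had no aligned-row mapping; excluded",
            call. = FALSE)
  }
  sets <- cluster_ion_sets[has_rows]
  n <- length(sets)
  if (!n) return(list())
  parent <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- sets[[i]]$rows; b <- sets[[j]]$rows
      tan <- length(intersect(a, b)) / length(union(a, b))
      if (tan >= tanimoto_min) {
        ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) .uf_find(parent, i), 0L)
  out <- list()
  for (g in split(seq_len(n), roots)) {
    rows_all <- unlist(lapply(sets[g], `[[`, "rows"))
    counts <- table(rows_all)
    keep_rows <- as.integer(names(counts)[counts >= quorum * length(g)])
    if (!length(keep_rows)) next
    med_h <- vapply(keep_rows, function(r) {
      hs <- unlist(lapply(sets[g], function(cl) cl$heights[cl$rows == r]))
      stats::median(hs)
    }, numeric(1))
    mzs <- aligned$mz[match(keep_rows, aligned$row_id)]
    ok <- is.finite(mzs)
    if (!any(ok)) next
    out[[length(out) + 1L]] <- fragment_spectrum(
      mzs[ok], med_h[ok],
      metadata = list(
        Name = sprintf("consensus_%d", length(out) + 1L),
        N_clusters = as.character(length(g))
      )
    )
  }
  out
}
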