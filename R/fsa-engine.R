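#' Search parameters for spectral similarity search
#'
#' Bundles the tunable constants of spectrum conditioning, prefiltering and
#' scoring.  Defaults follow the method's stated values where one exists
#' (1% noise removal, entropy-similarity cutoff 0.75); the remaining
#' defaults are documented package choices.
#'
#' @param resolution_tol Da; adjacent fragments closer than this are merged
#'   into one peak (instrument-resolution consolidation).
#' @param noise_pct percent of the base peak; fragments below this are
#'   removed during conditioning.
#' @param marker_baseline_pct percent of the base peak; peaks at or above
#'   this baseline become characteristic markers cached per library entry.
#' @param marker_min_match_pct percent; minimum fraction of a library
#'   entry's markers that must have a query peak within `fragment_mz_tol`
#'   for the entry to pass the prefilter.
#' @param fragment_mz_tol Da; fragment matching tolerance.
#' @param precursor_mz_tol Da; precursor gate tolerance, or `NA` to disable
#'   (automatically skipped when either spectrum lacks a precursor, as
#'   composite MS1 spectra do).
#' @param entsim_cutoff entropy-similarity cutoff for reported hits.
#' @param neme_max Da; maximum normalized Euclidean mass error, or `NA` to
#'   disable.
#' @param cosine_lib_norm `"all_lib"` (default): the library norm in the
#'   cosine runs over all library fragments, so unmatched library peaks
#'   penalize the score while unmatched experimental peaks are ignored;
#'   `"matched_only"`: both norms run over matched pairs only.
#' @return a `search_params` list.
#' @export
search_params <- function(resolution_tol = 0.01,
                          noise_pct = 1,
                          marker_baseline_pct = 10,
                          marker_min_match_pct = 50,
                          fragment_mz_tol = 0.01,
                          precursor_mz_tol = NA_real_,
                          entsim_cutoff = 0.75,
                          neme_max = NA_real_,
                          cosine_lib_norm = c("all_lib", "matched_only")) {
  cosine_lib_norm <- match.arg(cosine_lib_norm)
  p <- list(
    resolution_tol = as.numeric(resolution_tol),
    noise_pct = as.numeric(noise_pct),
    marker_baseline_pct = as.numeric(marker_baseline_pct),
    marker_min_match_pct = as.numeric(marker_min_match_pct),
    fragment_mz_tol = as.numeric(fragment_mz_tol),
    precursor_mz_tol = as.numeric(precursor_mz_tol),
    entsim_cutoff = as.numeric(entsim_cutoff),
    neme_max = as.numeric(neme_max),
    cosine_lib_norm = cosine_lib_norm
  )
  stopifnot(p$resolution_tol >= 0,
            p$noise_pct >= 0, p$noise_pct < 100,
            p$marker_baseline_pct >= 0, p$marker_baseline_pct <= 100,
            p$marker_min_match_pct >= 0, p$marker_min_match_pct <= 100,
            p$fragment_mz_tol > 0,
            is.na(p$precursor_mz_tol) || p$precursor_mz_tol > 0,
            p$entsim_cutoff > 0, p$entsim_cutoff <= 1,
            is.na(p$neme_max) || p$neme_max >= 0)
  class(p) <- "search_params"
  p
}

#' Merge adjacent fragments within the instrument resolution
#'
#' Maximal runs of peaks whose consecutive m/z gaps are all at most
#' `resolution_tol` collapse into a single peak whose intensity is the run
#' sum and whose m/z is the intensity-weighted mean of the run.
#'
#' @param spectrum a `fragment_spectrum` (peaks already m/z-sorted).
#' @param resolution_tol merge width in Da.
#' @return the resolved `fragment_spectrum`.
#' @export
resolve_adjacent <- function(spectrum, resolution_tol) {
  stopifnot(inherits(spectrum, "fragment_spectrum"))
  n <- length(spectrum$mz)
  if (n < 2 || resolution_tol <= 0) return(spectrum)
  gaps <- diff(spectrum$mz)
  run <- cumsum(c(0L, as.integer(gaps > resolution_tol)))
  ints <- as.numeric(tapply(spectrum$intensity, run, sum))
  wsum <- as.numeric(tapply(spectrum$intensity * spectrum$mz, run, sum))
  plain <- as.numeric(tapply(spectrum$mz, run, mean))
  mzs <- ifelse(ints > 0, wsum / pmax(ints, .Machine$double.xmin), plain)
  spectrum$mz <- mzs
  spectrum$intensity <- ints
  spectrum
}

#' Remove low-intensity noise fragments
#'
#' Drops peaks whose intensity is strictly below `noise_pct` percent of the
#' base (most intense) peak.  A single-peak spectrum always survives.
#'
#' @param spectrum a `fragment_spectrum`.
#' @param noise_pct threshold as a percentage of the base peak (default 1).
#' @return the denoised `fragment_spectrum` (possibly empty).
#' @export
remove_noise <- function(spectrum, noise_pct = 1) {
  stopifnot(inherits(spectrum, "fragment_spectrum"))
  if (!length(spectrum$mz) || noise_pct <= 0) return(spectrum)
  thr <- noise_pct / 100 * max(spectrum$intensity)
  keep <- spectrum$intensity >= thr
  spectrum$mz <- spectrum$mz[keep]
  spectrum$intensity <- spectrum$intensity[keep]
  spectrum
}

#' Characteristic spectra markers
#'
#' Markers are the m/z of peaks at or above `marker_baseline_pct` percent of
#' the base peak.  They are cached per library entry and drive the
#' partial-symmetry prefilter.
#'
#' @param spectrum a conditioned `fragment_spectrum`.
#' @param marker_baseline_pct baseline as a percentage of the base peak.
#' @return numeric vector of marker m/z values.
#' @export
characteristic_markers <- function(spectrum, marker_baseline_pct) {
  stopifnot(inherits(spectrum, "fragment_spectrum"))
  if (!length(spectrum$mz)) return(numeric(0))
  thr <- marker_baseline_pct / 100 * max(spectrum$intensity)
  spectrum$mz[spectrum$intensity >= thr]
}

#' Spectral entropy (Shannon entropy, nats)
#'
#' S = -sum(Ip * ln(Ip)) over intensities normalized to unit sum.
#'
#' @param x a `fragment_spectrum` or a numeric intensity vector.
#' @return entropy in nats; 0 for a single peak, ln(n) for n equal peaks.
#' @export
spectral_entropy <- function(x) {
  ints <- if (inherits(x, "fragment_spectrum")) x$intensity else as.numeric(x)
  tot <- sum(ints)
  if (!length(ints) || tot <= 0) {
    stop("spectral entropy undefined for an empty or all-zero spectrum",
         call. = FALSE)
  }
  p <- ints / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Entropy weight transformation
#'
#' For spectra with entropy S < 3 nats, intensities are raised to the power
#' w = 0.25 * (1 + S) and re-normalized to unit sum; spectra with S >= 3 are
#' left unchanged (w = 1).  This down-weights dominant peaks of low-entropy
#' spectra before the merged-spectrum entropy comparison.
#'
#' @param spectrum a `fragment_spectrum` with at least one positive
#'   intensity.
#' @return the transformed spectrum with intensities normalized to sum 1.
#' @export
weight_transform <- function(spectrum) {
  stopifnot(inherits(spectrum, "fragment_spectrum"))
  spectrum <- normalize_intensity(spectrum)
  s <- spectral_entropy(spectrum)
  if (s >= 3) return(spectrum)
  w <- 0.25 * (1 + s)
  spectrum$intensity <- spectrum$intensity^w
  normalize_intensity(spectrum)
}

#' Match fragments between a library and an experimental spectrum
#'
#' Greedy one-to-one pairing: library peaks are visited in ascending m/z and
#' each claims the closest still-unclaimed experimental peak within
#' `fragment_mz_tol`.  The number of pairs is NP, the matched-peak count
#' used throughout scoring.
#'
#' @param lib,exptl conditioned `fragment_spectrum` objects (library and
#'   experimental roles).
#' @param fragment_mz_tol matching tolerance in Da.
#' @return a data.frame with one row per pair: `lib_idx`, `exptl_idx`,
#'   `mz_lib`, `mz_exptl`, `i_lib`, `i_exptl`.
#' @export
match_fragments <- function(lib, exptl, fragment_mz_tol) {
  stopifnot(inherits(lib, "fragment_spectrum"),
            inherits(exptl, "fragment_spectrum"))
  m <- .greedy_match(lib, exptl, fragment_mz_tol)
  li <- m$li; ei <- m$ei
  data.frame(
    lib_idx = li, exptl_idx = ei,
    mz_lib = lib$mz[li], mz_exptl = exptl$mz[ei],
    i_lib = lib$intensity[li], i_exptl = exptl$intensity[ei]
  )
}

#' Cosine similarity over matched fragments
#'
#' Dot-product similarity computed "only using the library fragments": the
#' numerator runs over matched pairs; unmatched experimental peaks never
#' enter.  With `lib_norm = "all_lib"` every library fragment contributes
#' its squared intensity to the library norm (unmatched ones add zero to
#' the numerator); with `"matched_only"` the library norm is restricted to
#' matched pairs as well.
#'
#' @param lib,exptl the two spectra (used for the full-library norm).
#' @param pairs the pairing from [match_fragments()].
#' @param lib_norm `"all_lib"` or `"matched_only"`.
#' @return cosine similarity in `[0, 1]`; 0 when no fragments match.
#' @export
cosine_similarity <- function(lib, exptl, pairs,
                              lib_norm = c("all_lib", "matched_only")) {
  lib_norm <- match.arg(lib_norm)
  if (!nrow(pairs)) return(0)
  num <- sum(pairs$i_lib * pairs$i_exptl)
  den_lib <- if (lib_norm == "all_lib") sum(lib$intensity^2) else sum(pairs$i_lib^2)
  den_ex <- sum(pairs$i_exptl^2)
  if (den_lib <= 0 || den_ex <= 0) return(0)
  min(1, num / sqrt(den_lib * den_ex))
}

#' Normalized Euclidean mass error (NEME)
#'
#' Root-mean-square of the matched-fragment mass errors:
#' sqrt(sum((M_lib - M_exptl)^2) / NP).
#'
#' @param pairs the pairing from [match_fragments()]; must be non-empty.
#' @return NEME in Da.
#' @export
neme <- function(pairs) {
  if (!nrow(pairs)) {
    stop("NEME is undefined when no fragments match", call. = FALSE)
  }
  sqrt(sum((pairs$mz_lib - pairs$mz_exptl)^2) / nrow(pairs))
}

# allocation-light greedy pairing shared by match_fragments and the
# search hot loop
.greedy_match <- function(lib, exptl, tol) {
  nl <- length(lib$mz)
  ne <- length(exptl$mz)
  li <- integer(nl); ei <- integer(nl); k <- 0L
  claimed <- logical(ne)
  for (i in seq_len(nl)) {
    if (!ne) break
    d <- abs(exptl$mz - lib$mz[i])
    d[claimed] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) {
      claimed[j] <- TRUE
      k <- k + 1L
      li[k] <- i
      ei[k] <- j
    }
  }
  list(li = li[seq_len(k)], ei = ei[seq_len(k)])
}

# 1:1 merge of two unit-normalized spectra: every intensity halved, then
# peaks of the two operands within `tol` of each other combined
# (run-merging with intensity-weighted mean m/z, as in resolve_adjacent).
merge_spectra_halved <- function(a, b, tol) {
  merged <- fragment_spectrum(c(a$mz, b$mz), c(a$intensity, b$intensity) / 2)
  resolve_adjacent(merged, tol)
}

#' Entropy similarity of two spectra
#'
#' Both spectra are normalized and weight-transformed, then 1:1 mixed into
#' a merged spectrum (peaks within `fragment_mz_tol` combined).  The
#' similarity is `1 - (2*S_merged - S_lib - S_exptl) / ln 4`, clipped to
#' `[0, 1]`.  Identical spectra score 1; single peaks at disjoint m/z
#' score 0.
#'
#' @param lib,exptl conditioned `fragment_spectrum` objects.
#' @param fragment_mz_tol peak-combination tolerance in Da.
#' @return entropy similarity in `[0, 1]`.
#' @export
entropy_similarity <- function(lib, exptl, fragment_mz_tol) {
  if (!length(lib$mz) || !length(exptl$mz) ||
      sum(lib$intensity) <= 0 || sum(exptl$intensity) <= 0) {
    return(0)
  }
  lw <- weight_transform(lib)
  ew <- weight_transform(exptl)
  s_lib <- spectral_entropy(lw)
  s_ex <- spectral_entropy(ew)
  s_merged <- spectral_entropy(merge_spectra_halved(lw, ew, fragment_mz_tol))
  sim <- 1 - (2 * s_merged - s_lib - s_ex) / log(4)
  min(1, max(0, sim))
}

#' Prefilter a library entry against a query spectrum
#'
#' A cheap gate evaluated before full scoring.  The entry passes iff
#' (a) the precursor gate passes — skipped when disabled or when either
#' precursor is absent — and (b) at least `marker_min_match_pct` percent of
#' the entry's characteristic markers have a query peak within
#' `fragment_mz_tol`.
#'
#' @param query conditioned query `fragment_spectrum`.
#' @param entry an `fsdb_entry` (see [build_fsdb()]).
#' @param params a [search_params()] object.
#' @return logical.
#' @export
prefilter <- function(query, entry, params) {
  if (!is.na(params$precursor_mz_tol) &&
      is.finite(query$precursor_mz) &&
      is.finite(entry$spectrum$precursor_mz)) {
    if (abs(query$precursor_mz - entry$spectrum$precursor_mz) >
        params$precursor_mz_tol) {
      return(FALSE)
    }
  }
  markers <- entry$markers
  if (!length(markers)) return(TRUE)
  if (!length(query$mz)) return(FALSE)
  hit <- vapply(markers, function(m) {
    any(abs(query$mz - m) <= params$fragment_mz_tol)
  }, logical(1))
  100 * sum(hit) / length(markers) >= params$marker_min_match_pct
}

#' Condition a spectrum for scoring
#'
#' Instrument-resolution consolidation ([resolve_adjacent()]) followed by
#' noise removal ([remove_noise()]), the fixed conditioning order applied
#' to both library entries (at database build) and queries (at search).
#'
#' @param spectrum a `fragment_spectrum`.
#' @param params a [search_params()] object.
#' @return the conditioned `fragment_spectrum`.
#' @export
condition_spectrum <- function(spectrum, params) {
  remove_noise(resolve_adjacent(spectrum, params$resolution_tol),
               params$noise_pct)
}

#' Score one library/experimental spectrum pair
#'
#' Computes the full score set for a conditioned pair: matched-peak count
#' NP, cosine similarity, entropy similarity, NEME and the final
#' `score = cosine * entropy_sim^2`.
#'
#' @param lib,exptl conditioned spectra.
#' @param params a [search_params()] object.
#' @return a one-row data.frame (`np`, `cosine`, `entropy_sim`, `neme`,
#'   `score`); `np = 0` rows carry zero similarities and `NA` NEME.
#' @export
score_pair <- function(lib, exptl, params) {
  as.data.frame(.score_pair_fast(lib, exptl, params))
}

# list-returning scorer for the search hot loop (no data.frame cost)
.score_pair_fast <- function(lib, exptl, params) {
  m <- .greedy_match(lib, exptl, params$fragment_mz_tol)
  np <- length(m$li)
  if (!np) {
    return(list(np = 0L, cosine = 0, entropy_sim = 0,
                neme = NA_real_, score = 0))
  }
  il <- lib$intensity[m$li]; ie <- exptl$intensity[m$ei]
  den_lib <- if (params$cosine_lib_norm == "all_lib") {
    sum(lib$intensity^2)
  } else sum(il^2)
  cs <- sum(il * ie) / sqrt(den_lib * sum(ie^2))
  cs <- min(1, cs)
  es <- entropy_similarity(lib, exptl, params$fragment_mz_tol)
  nm <- sqrt(sum((lib$mz[m$li] - exptl$mz[m$ei])^2) / np)
  list(np = as.integer(np), cosine = cs, entropy_sim = es,
       neme = nm, score = cs * es^2)
}

#' Search a query spectrum against an FSDB
#'
#' Conditions the query, prefilters the library, scores the surviving
#' entries, applies the entropy-similarity cutoff and optional NEME cutoff,
#' and ranks hits by descending score (ties: lower NEME, then library
#' order).
#'
#' @param query a `fragment_spectrum`.
#' @param fsdb an `fsdb` built by [build_fsdb()].
#' @param params a [search_params()] object; defaults to the FSDB's own
#'   build parameters.
#' @param use_prefilter logical; disable to force exhaustive scoring.
#' @return a data.frame of hits: `entry_id`, `source_id`, `name`, `np`,
#'   `cosine`, `entropy_sim`, `neme`, `score`, `rank`.
#' @export
search_spectrum <- function(query, fsdb, params = NULL, use_prefilter = TRUE) {
  stopifnot(inherits(fsdb, "fsdb"))
  if (!length(fsdb$entries)) stop("empty spectral library", call. = FALSE)
  if (is.null(params)) params <- fsdb$build_params
  q <- condition_spectrum(query, params)
  n <- length(fsdb$entries)
  id <- integer(n); np <- integer(n)
  cs <- numeric(n); es <- numeric(n); nm <- numeric(n); sc <- numeric(n)
  src <- character(n); nms <- character(n)
  h <- 0L
  for (k in seq_len(n)) {
    entry <- fsdb$entries[[k]]
    if (use_prefilter && !prefilter(q, entry, params)) next
    s <- .score_pair_fast(entry$spectrum, q, params)
    if (s$np < 1) next
    if (s$entropy_sim < params$entsim_cutoff) next
    if (!is.na(params$neme_max) && s$neme > params$neme_max) next
    h <- h + 1L
    id[h] <- k; np[h] <- s$np; cs[h] <- s$cosine; es[h] <- s$entropy_sim
    nm[h] <- s$neme; sc[h] <- s$score
    src[h] <- entry$source_id
    ename <- entry$spectrum$metadata$Name
    nms[h] <- if (is.null(ename)) NA_character_ else ename
  }
  keep <- seq_len(h)
  out <- data.frame(entry_id = id[keep], source_id = src[keep],
                    name = nms[keep], np = np[keep], cosine = cs[keep],
                    entropy_sim = es[keep], neme = nm[keep],
                    score = sc[keep])
  o <- order(-out$score, out$neme, out$entry_id)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Summarize spectra-search results across a study
#'
#' Aggregates per-sample hit tables into per-(aligned row, library
#' compound) annotation frequencies and median ranks.
#'
#' @param per_sample_results a data.frame with columns `sample_id`,
#'   `row_id` (aligned-table row), `source_id` (library compound) and
#'   `rank`; typically a row-bind of per-sample [search_spectrum()] outputs
#'   tagged with sample and aligned-row ids.
#' @return a data.frame (`row_id`, `source_id`, `frequency`,
#'   `median_rank`) sorted by frequency descending then median rank
#'   ascending.
#' @export
summarize_study <- function(per_sample_results) {
  req <- c("sample_id", "row_id", "source_id", "rank")
  miss <- setdiff(req, names(per_sample_results))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(per_sample_results)) {
    return(data.frame(row_id = integer(0), source_id = character(0),
                      frequency = integer(0), median_rank = numeric(0)))
  }
  key <- interaction(per_sample_results$row_id,
                     per_sample_results$source_id, drop = TRUE)
  agg <- lapply(split(per_sample_results, key), function(d) {
    data.frame(row_id = d$row_id[1],
               source_id = d$source_id[1],
               frequency = length(unique(d$sample_id)),
               median_rank = stats::median(d$rank))
  })
  out <- do.call(rbind, agg)
  out <- out[order(-out$frequency, out$median_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
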