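FSDB_SCHEMA <- "mscsa-fsdb/1"

#' Build a fragmentation-spectra database (FSDB)
#'
#' Each input spectrum is conditioned (instrument-resolution consolidation
#' then noise removal per `params`) and stored together with its
#' pre-computed spectral entropy and characteristic markers, so searches
#' never re-condition library entries.  Spectra left empty by denoising
#' are dropped with a warning; the remaining entries preserve input order.
#'
#' @param spectra list of `fragment_spectrum` (one ionization mode).
#' @param params a [search_params()] object; snapshotted into the database.
#' @param ionization_mode `"positive"` or `"negative"`; libraries are kept
#'   separated by mode.
#' @param source_ids optional character ids per spectrum; defaults to the
#'   metadata `Name`, falling back to `"spectrum_<i>"`.
#' @return an object of class `fsdb` with elements `entries` (each an
#'   `fsdb_entry`: `spectrum`, `entropy`, `markers`, `source_id`),
#'   `ionization_mode`, `build_params`, `schema`.
#' @export
build_fsdb <- function(spectra, params = search_params(),
                       ionization_mode = c("positive", "negative"),
                       source_ids = NULL) {
  ionization_mode <- match.arg(ionization_mode)
  if (inherits(spectra, "fragment_spectrum")) spectra <- list(spectra)
  if (is.null(source_ids)) {
    source_ids <- vapply(seq_along(spectra), function(i) {
      nm <- spectra[[i]]$metadata$Name
      if (is.null(nm) || !nzchar(nm)) paste0("spectrum_", i) else nm
    }, character(1))
  }
  stopifnot(length(source_ids) == length(spectra))
  entries <- list()
  for (i in seq_along(spectra)) {
    sp <- condition_spectrum(spectra[[i]], params)
    if (!length(sp$mz) || sum(sp$intensity) <= 0) {
      warning("dropping spectrum '", source_ids[i],
              "': empty after conditioning", call. = FALSE)
      next
    }
    entries[[length(entries) + 1L]] <- structure(
      list(
        spectrum = sp,
        entropy = spectral_entropy(normalize_intensity(sp)),
        markers = characteristic_markers(sp, params$marker_baseline_pct),
        source_id = source_ids[i]
      ),
      class = "fsdb_entry"
    )
  }
  structure(
    list(entries = entries, ionization_mode = ionization_mode,
         build_params = params, schema = FSDB_SCHEMA),
    class = "fsdb"
  )
}

#' @export
print.fsdb <- function(x, ...) {
  cat("<fsdb> ", length(x$entries), " entries, ", x$ionization_mode,
      " mode (schema ", x$schema, ")\n", sep = "")
  invisible(x)
}

#' Write an FSDB to disk
#'
#' The on-disk layout is a versioned JSON container (schema string,
#' per-entry m/z and intensity arrays, cached entropy, markers, metadata,
#' build-parameter snapshot) rather than an opaque binary, so databases are
#' reusable across languages.  Serialization is deterministic: building
#' twice from the same inputs yields byte-identical files.
#'
#' @param fsdb an `fsdb`.
#' @param path output path (`.fsdb` or `.json`).
#' @return `path`, invisibly.
#' @export
write_fsdb <- function(fsdb, path) {
  stopifnot(inherits(fsdb, "fsdb"))
  entries <- lapply(fsdb$entries, function(e) {
    list(
      source_id = jsonlite::unbox(e$source_id),
      entropy = jsonlite::unbox(e$entropy),
      markers = as.numeric(e$markers),
      mz = e$spectrum$mz,
      intensity = e$spectrum$intensity,
      precursor_mz = jsonlite::unbox(e$spectrum$precursor_mz),
      precursor_rt = jsonlite::unbox(e$spectrum$precursor_rt),
      metadata = lapply(e$spectrum$metadata, function(v)
        jsonlite::unbox(as.character(v)))
    )
  })
  params <- lapply(unclass(fsdb$build_params), jsonlite::unbox)
  obj <- list(
    schema = jsonlite::unbox(fsdb$schema),
    ionization_mode = jsonlite::unbox(fsdb$ionization_mode),
    build_params = params,
    entries = entries
  )
  json <- jsonlite::toJSON(obj, digits = NA, na = "null", null = "null",
                           pretty = FALSE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read an FSDB from disk
#'
#' @param path an FSDB JSON container written by [write_fsdb()].
#' @return an `fsdb`.
#' @export
read_fsdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$schema) || !startsWith(obj$schema, "mscsa-fsdb/")) {
    stop("not an mscsa FSDB container: ", path, call. = FALSE)
  }
  bp <- obj$build_params
  params <- search_params(
    resolution_tol = bp$resolution_tol,
    noise_pct = bp$noise_pct,
    marker_baseline_pct = bp$marker_baseline_pct,
    marker_min_match_pct = bp$marker_min_match_pct,
    fragment_mz_tol = bp$fragment_mz_tol,
    precursor_mz_tol = if (is.null(bp$precursor_mz_tol)) NA_real_
                       else bp$precursor_mz_tol,
    entsim_cutoff = bp$entsim_cutoff,
    neme_max = if (is.null(bp$neme_max)) NA_real_ else bp$neme_max,
    cosine_lib_norm = bp$cosine_lib_norm
  )
  entries <- lapply(obj$entries, function(e) {
    sp <- fragment_spectrum(
      unlist(e$mz), unlist(e$intensity),
      precursor_mz = if (is.null(e$precursor_mz)) NA_real_ else e$precursor_mz,
      precursor_rt = if (is.null(e$precursor_rt)) NA_real_ else e$precursor_rt,
      metadata = lapply(e$metadata, as.character)
    )
    structure(
      list(spectrum = sp, entropy = e$entropy,
           markers = as.numeric(unlist(e$markers)),
           source_id = e$source_id),
      class = "fsdb_entry"
    )
  })
  structure(
    list(entries = entries, ionization_mode = obj$ionization_mode,
         build_params = params, schema = obj$schema),
    class = "fsdb"
  )
}
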