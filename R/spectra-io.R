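# MSP field synonyms folded (case-insensitively) onto canonical keys.
.msp_synonyms <- c(
  "precursormz" = "precursor_mz",
  "precursor_mz" = "precursor_mz",
  "precursor_m/z" = "precursor_mz",
  "precursor m/z" = "precursor_mz",
  "retentiontime" = "precursor_rt",
  "retention_time" = "precursor_rt",
  "rt" = "precursor_rt"
)

.canonical_msp_key <- function(key) {
  k <- tolower(trimws(key))
  if (k %in% names(.msp_synonyms)) .msp_synonyms[[k]] else trimws(key)
}

# Parse "mz int" / "mz<TAB>int" / "mz int charge" peak lines.
.parse_peak_lines <- function(lines) {
  toks <- strsplit(trimws(lines), "[\t ;]+")
  mz <- vapply(toks, function(t) suppressWarnings(as.numeric(t[1])), 0)
  it <- vapply(toks, function(t) {
    if (length(t) < 2) return(NA_real_)
    suppressWarnings(as.numeric(t[2]))
  }, 0)
  ok <- is.finite(mz) & is.finite(it)
  list(mz = mz[ok], intensity = it[ok])
}

.is_peak_line <- function(line) {
  grepl("^\\s*[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?[\t ;]+[0-9]", line)
}

.record_to_spectrum <- function(lines, where) {
  peak_sel <- .is_peak_line(lines)
  meta_lines <- lines[!peak_sel & grepl(":", lines, fixed = TRUE)]
  keys <- sub(":.*$", "", meta_lines)
  vals <- trimws(sub("^[^:]*:", "", meta_lines))
  meta <- list()
  precursor_mz <- NA_real_
  precursor_rt <- NA_real_
  declared <- NA_integer_
  for (i in seq_along(keys)) {
    ck <- .canonical_msp_key(keys[i])
    lk <- tolower(ck)
    if (lk == "precursor_mz") {
      precursor_mz <- suppressWarnings(as.numeric(vals[i]))
    } else if (lk == "precursor_rt") {
      precursor_rt <- suppressWarnings(as.numeric(vals[i]))
    } else if (lk %in% c("num peaks", "numpeaks", "num_peaks")) {
      declared <- suppressWarnings(as.integer(vals[i]))
    } else {
      meta[[ck]] <- vals[i]
    }
  }
  pk <- .parse_peak_lines(lines[peak_sel])
  if (!length(pk$mz)) {
    warning("skipping unparseable record (no peaks) near ", where,
            call. = FALSE)
    return(NULL)
  }
  if (!is.na(declared) && declared != length(pk$mz)) {
    warning("declared peak count (", declared, ") != peaks found (",
            length(pk$mz), ") near ", where, "; keeping actual peaks",
            call. = FALSE)
  }
  fragment_spectrum(pk$mz, pk$intensity,
                    precursor_mz = precursor_mz,
                    precursor_rt = precursor_rt,
                    metadata = meta)
}

#' Read a NIST-style MSP spectral library
#'
#' Records are delimited by `Name:` lines; field names are matched
#' case-insensitively with synonym folding (`PRECURSORMZ`, `PrecursorMZ`,
#' `precursor_m/z` all map to the precursor).  Peak lines accept space,
#' tab or semicolon separators and tolerate a trailing charge/annotation
#' column.  Unparseable records are skipped with a warning.
#'
#' @param path MSP file path.
#' @return list of `fragment_spectrum`.
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*#", raw)]
  starts <- grep("^\\s*name\\s*:", raw, ignore.case = TRUE)
  if (length(starts)) {
    ends <- c(starts[-1] - 1L, length(raw))
    blocks <- lapply(seq_along(starts), function(i) raw[starts[i]:ends[i]])
  } else {
    # headerless fallback: blank-line-delimited blocks
    blank <- !nzchar(trimws(raw))
    grp <- cumsum(c(TRUE, blank[-length(blank)] & !blank[-1]))
    blocks <- split(raw, grp)
  }
  spectra <- list()
  for (i in seq_along(blocks)) {
    block <- blocks[[i]]
    block <- block[nzchar(trimws(block))]
    if (!length(block)) next
    sp <- .record_to_spectrum(block, paste0(basename(path), " record ", i))
    if (!is.null(sp)) spectra[[length(spectra) + 1L]] <- sp
  }
  if (!length(spectra)) {
    stop("no parseable spectra records in ", path, call. = FALSE)
  }
  spectra
}

#' Write spectra to a NIST-style MSP file
#'
#' Metadata keys are emitted as `key: value` lines, m/z with five decimal
#' places, and no precursor line is written for spectra without a
#' precursor (composite MS1 spectra carry none).
#'
#' @param spectra non-empty list of `fragment_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(spectra, path) {
  if (inherits(spectra, "fragment_spectrum")) spectra <- list(spectra)
  if (!length(spectra)) stop("no spectra to write", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    nm <- sp$metadata$Name
    writeLines(paste0("Name: ", if (is.null(nm)) "unknown" else nm), con)
    if (is.finite(sp$precursor_mz)) {
      writeLines(sprintf("PrecursorMZ: %.5f", sp$precursor_mz), con)
    }
    if (is.finite(sp$precursor_rt)) {
      writeLines(sprintf("Retention_time: %.5f", sp$precursor_rt), con)
    }
    for (key in setdiff(names(sp$metadata), "Name")) {
      writeLines(paste0(key, ": ", sp$metadata[[key]]), con)
    }
    writeLines(sprintf("Num Peaks: %d", length(sp$mz)), con)
    if (length(sp$mz)) {
      writeLines(sprintf("%.5f %.6g", sp$mz, sp$intensity), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a Mascot generic format (MGF) file
#'
#' `BEGIN IONS`/`END IONS` blocks; `PEPMASS` maps to the precursor m/z
#' (a second token on the PEPMASS line, the precursor intensity, is
#' ignored), `TITLE` to the spectrum name, `RTINSECONDS` to the retention
#' time in minutes.  A trailing charge column on peak lines is ignored.
#'
#' @param path MGF file path.
#' @return list of `fragment_spectrum`.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  begin <- grep("^\\s*BEGIN IONS\\s*$", raw, ignore.case = TRUE)
  end <- grep("^\\s*END IONS\\s*$", raw, ignore.case = TRUE)
  if (!length(begin) || length(begin) != length(end)) {
    stop("no well-formed BEGIN IONS/END IONS blocks in ", path,
         call. = FALSE)
  }
  spectra <- list()
  for (i in seq_along(begin)) {
    if (end[i] - begin[i] < 2) next
    block <- raw[(begin[i] + 1L):(end[i] - 1L)]
    meta <- list()
    precursor_mz <- NA_real_
    precursor_rt <- NA_real_
    kv <- grepl("=", block, fixed = TRUE) & !.is_peak_line(block)
    for (line in block[kv]) {
      key <- toupper(trimws(sub("=.*$", "", line)))
      val <- trimws(sub("^[^=]*=", "", line))
      if (key == "PEPMASS") {
        precursor_mz <- suppressWarnings(
          as.numeric(strsplit(val, "[\t ]+")[[1]][1]))
      } else if (key == "RTINSECONDS") {
        precursor_rt <- suppressWarnings(as.numeric(val)) / 60
      } else if (key == "RTINMINUTES") {
        precursor_rt <- suppressWarnings(as.numeric(val))
      } else if (key == "TITLE") {
        meta$Name <- val
      } else if (key != "CHARGE") {
        meta[[key]] <- val
      }
    }
    pk <- .parse_peak_lines(block[.is_peak_line(block)])
    if (!length(pk$mz)) {
      warning("skipping MGF block ", i, " of ", basename(path),
              " (no peaks)", call. = FALSE)
      next
    }
    spectra[[length(spectra) + 1L]] <-
      fragment_spectrum(pk$mz, pk$intensity, precursor_mz = precursor_mz,
                        precursor_rt = precursor_rt, metadata = meta)
  }
  if (!length(spectra)) {
    stop("no parseable spectra in ", path, call. = FALSE)
  }
  spectra
}

#' Read a spectral library by extension
#'
#' Dispatches on file extension: `.msp` to [read_msp()], `.mgf` to
#' [read_mgf()], `.fsdb`/`.json` to [read_fsdb()].
#'
#' @param path library path.
#' @return list of `fragment_spectrum`, or an `fsdb` for FSDB files.
#' @export
read_spectra <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    msp = read_msp(path),
    mgf = read_mgf(path),
    fsdb = read_fsdb(path),
    json = read_fsdb(path),
    stop("unsupported spectral file extension: .", ext, call. = FALSE)
  )
}
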