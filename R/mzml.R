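# Minimal centroided-mzML reader/writer.
#
# No general mzML stack is assumed at run time; this reader covers the
# subset the pipeline needs: spectrumList cvParams for ms level
# (MS:1000511), scan start time (MS:1000016, second/minute units),
# centroid/profile flags (MS:1000127/MS:1000128), selected-ion precursor
# m/z (MS:1000744), isolation windows (MS:1000827/28/29), and binary data
# arrays as base64 little-endian 32/64-bit floats, optionally
# zlib-compressed.

.b64_decode <- function(txt) jsonlite::base64_dec(gsub("[\r\n ]", "", txt))

.decode_binary_array <- function(node, ns) {
  acc <- xml2::xml_attr(
    xml2::xml_find_all(node, "./d1:cvParam", ns), "accession")
  bin <- xml2::xml_text(xml2::xml_find_first(node, "./d1:binary", ns))
  kind <- if ("MS:1000514" %in% acc) "mz"
          else if ("MS:1000515" %in% acc) "intensity"
          else return(NULL)
  size <- if ("MS:1000521" %in% acc) 4L else 8L     # 32- vs 64-bit float
  raw <- .b64_decode(bin)
  if ("MS:1000574" %in% acc) raw <- memDecompress(raw, type = "gzip")
  vals <- readBin(raw, "double", n = length(raw) %/% size, size = size,
                  endian = "little")
  list(kind = kind, values = vals)
}

#' Read centroided LC/HRMS scan data from mzML
#'
#' Parses MS1 (and, when present, MS2) spectra into a [scan_table()].
#' Retention times are converted to minutes regardless of the file's unit;
#' profile-mode spectra are rejected with an error advising centroiding.
#'
#' @param path mzML file path.
#' @return a `scan_table`.
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  spectra <- xml2::xml_find_all(doc, "//d1:spectrumList/d1:spectrum", ns)
  if (!length(spectra)) stop("no spectra in ", path, call. = FALSE)
  n <- length(spectra)
  rt <- numeric(n); level <- integer(n)
  prec <- rep(NA_real_, n); iso_lo <- rep(NA_real_, n); iso_hi <- rep(NA_real_, n)
  mzl <- vector("list", n); intl <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    cv <- xml2::xml_find_all(sp, "./d1:cvParam", ns)
    acc <- xml2::xml_attr(cv, "accession")
    val <- xml2::xml_attr(cv, "value")
    if ("MS:1000128" %in% acc) {
      stop("profile-mode spectra detected in ", basename(path),
           "; centroid the data before processing", call. = FALSE)
    }
    level[i] <- if ("MS:1000511" %in% acc) {
      as.integer(val[match("MS:1000511", acc)])
    } else 1L
    scv <- xml2::xml_find_all(sp, ".//d1:scan/d1:cvParam", ns)
    sacc <- xml2::xml_attr(scv, "accession")
    j <- match("MS:1000016", sacc)
    if (!is.na(j)) {
      t <- as.numeric(xml2::xml_attr(scv[[j]], "value"))
      unit <- xml2::xml_attr(scv[[j]], "unitName")
      rt[i] <- if (identical(unit, "second")) t / 60 else t
    }
    pn <- xml2::xml_find_first(
      sp, ".//d1:precursor//d1:selectedIon/d1:cvParam[@accession='MS:1000744']",
      ns)
    if (!inherits(pn, "xml_missing")) {
      prec[i] <- as.numeric(xml2::xml_attr(pn, "value"))
    }
    iso <- xml2::xml_find_all(
      sp, ".//d1:precursor/d1:isolationWindow/d1:cvParam", ns)
    if (length(iso)) {
      iacc <- xml2::xml_attr(iso, "accession")
      ival <- as.numeric(xml2::xml_attr(iso, "value"))
      tgt <- ival[match("MS:1000827", iacc)]
      lo <- ival[match("MS:1000828", iacc)]
      hi <- ival[match("MS:1000829", iacc)]
      if (is.finite(tgt)) {
        iso_lo[i] <- tgt - ifelse(is.finite(lo), lo, 0)
        iso_hi[i] <- tgt + ifelse(is.finite(hi), hi, 0)
      }
    }
    arrs <- xml2::xml_find_all(sp, ".//d1:binaryDataArray", ns)
    mzv <- numeric(0); inv <- numeric(0)
    for (a in arrs) {
      dec <- .decode_binary_array(a, ns)
      if (is.null(dec)) next
      if (dec$kind == "mz") mzv <- dec$values else inv <- dec$values
    }
    mzl[[i]] <- mzv
    intl[[i]] <- inv
  }
  scan_table(rt = rt, ms_level = level, mz = mzl, intensity = intl,
             precursor_mz = prec, iso_lower = iso_lo, iso_upper = iso_hi)
}

.b64_encode_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                endian = "little"))
}

#' Write a scan table to mzML
#'
#' Emits a minimal but standard-conformant mzML document: centroided
#' spectra with 64-bit little-endian uncompressed binary arrays, scan
#' start times in minutes, selected-ion precursor m/z for MS2 scans and
#' isolation windows when present.
#'
#' @param scans a [scan_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(scans, path) {
  stopifnot(inherits(scans, "scan_table"))
  n <- length(scans$rt)
  out <- file(path, "w")
  on.exit(close(out))
  w <- function(...) writeLines(paste0(...), out)
  w('<?xml version="1.0" encoding="utf-8"?>')
  w('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">')
  w('  <run id="run1">')
  w('    <spectrumList count="', n, '">')
  for (i in seq_len(n)) {
    mz64 <- .b64_encode_doubles(scans$mz[[i]])
    in64 <- .b64_encode_doubles(scans$intensity[[i]])
    w('      <spectrum index="', i - 1L, '" id="scan=', i,
      '" defaultArrayLength="', length(scans$mz[[i]]), '">')
    w('        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="',
      scans$ms_level[i], '"/>')
    w('        <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>')
    w('        <scanList count="1"><scan>')
    w('          <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="',
      sprintf("%.8f", scans$rt[i]), '" unitName="minute"/>')
    w('        </scan></scanList>')
    if (scans$ms_level[i] > 1L &&
        (is.finite(scans$precursor_mz[i]) || is.finite(scans$iso_lower[i]))) {
      w('        <precursorList count="1"><precursor>')
      if (is.finite(scans$iso_lower[i]) && is.finite(scans$iso_upper[i])) {
        tgt <- (scans$iso_lower[i] + scans$iso_upper[i]) / 2
        off <- (scans$iso_upper[i] - scans$iso_lower[i]) / 2
        w('          <isolationWindow>')
        w('            <cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="',
          sprintf("%.6f", tgt), '"/>')
        w('            <cvParam cvRef="MS" accession="MS:1000828" name="isolation window lower offset" value="',
          sprintf("%.6f", off), '"/>')
        w('            <cvParam cvRef="MS" accession="MS:1000829" name="isolation window upper offset" value="',
          sprintf("%.6f", off), '"/>')
        w('          </isolationWindow>')
      }
      if (is.finite(scans$precursor_mz[i])) {
        w('          <selectedIonList count="1"><selectedIon>')
        w('            <cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="',
          sprintf("%.6f", scans$precursor_mz[i]), '"/>')
        w('          </selectedIon></selectedIonList>')
      }
      w('        </precursor></precursorList>')
    }
    w('        <binaryDataArrayList count="2">')
    w('          <binaryDataArray encodedLength="', nchar(mz64), '">')
    w('            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>')
    w('            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>')
    w('            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>')
    w('            <binary>', mz64, '</binary>')
    w('          </binaryDataArray>')
    w('          <binaryDataArray encodedLength="', nchar(in64), '">')
    w('            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>')
    w('            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>')
    w('            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>')
    w('            <binary>', in64, '</binary>')
    w('          </binaryDataArray>')
    w('        </binaryDataArrayList>')
    w('      </spectrum>')
  }
  w('    </spectrumList>')
  w('  </run>')
  w('</mzML>')
  invisible(path)
}
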