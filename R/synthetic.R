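# Mass difference between a monoisotopic peak and its +1 carbon
# isotopologue (Da, singly charged).
C13_DELTA <- 1.00336

#' Define a synthetic compound
#'
#' A compound is a set of co-eluting ions (the in-source fragment /
#' adduct cluster a real metabolite produces) sharing one Gaussian
#' elution profile.
#'
#' @param name compound label.
#' @param ions data.frame with columns `mz` (Da, pairwise distinct),
#'   `relative_abundance` in `(0, 1]`, and optional logical `has_13C`.
#' @param rt_apex elution apex in minutes.
#' @param peak_sigma Gaussian width in minutes (default 0.05, a ~12 s
#'   base-width peak typical of UHPLC gradients).
#' @param max_height apex intensity of the most abundant ion.
#' @param tailing exponential-tailing factor (0 = symmetric; positive
#'   values skew the profile right, stressing the height-fraction trim).
#' @param fragments optional data.frame (`mz`, `relative_abundance`,
#'   optional logical `flat`) describing MS2 fragments for DDA/DIA
#'   fixtures; `flat` fragments elute with no chromatographic profile
#'   (acquisition noise).
#' @return a `synthetic_compound`.
#' @export
synthetic_compound <- function(name, ions, rt_apex, peak_sigma = 0.05,
                               max_height = 1e6, tailing = 0,
                               fragments = NULL) {
  stopifnot(is.data.frame(ions), all(c("mz", "relative_abundance") %in%
                                       names(ions)))
  if (anyDuplicated(ions$mz)) stop("ion m/z must be pairwise distinct",
                                   call. = FALSE)
  stopifnot(all(ions$relative_abundance > 0),
            all(ions$relative_abundance <= 1))
  if (!"has_13C" %in% names(ions)) ions$has_13C <- FALSE
  structure(
    list(name = name, ions = ions, rt_apex = rt_apex,
         peak_sigma = peak_sigma, max_height = max_height,
         tailing = tailing, fragments = fragments),
    class = "synthetic_compound"
  )
}

# Gaussian (optionally exponentially tailed) elution profile.
.elution_profile <- function(t, apex, sigma, tailing = 0) {
  g <- exp(-(t - apex)^2 / (2 * sigma^2))
  if (tailing > 0) {
    right <- t > apex
    g[right] <- exp(-(t[right] - apex)^2 /
                      (2 * (sigma * (1 + tailing))^2))
  }
  g
}

#' Generate a ground-truthed MS1 scan table and peak list
#'
#' Each compound ion elutes as a Gaussian centered on the compound apex
#' with apex intensity `max_height * relative_abundance`; ions flagged
#' `has_13C` get a +1.00336 Da partner at 10% abundance.  Optional
#' log-normal multiplicative intensity noise and uniformly placed
#' single-ion noise peaks complete the noise model.  The peak list is
#' derived from the injected truth (bounds at apex +/- 3 sigma), and the
#' ground truth attributes every peak to exactly one compound or to
#' noise.
#'
#' @param compounds list of [synthetic_compound()].
#' @param rt_range `c(start, end)` minutes.
#' @param scan_interval seconds between MS1 scans (default 1).
#' @param noise list: `intensity_cv` (log-normal coefficient of variation
#'   of multiplicative intensity noise, default 0), `n_noise_peaks`
#'   (count of random singleton ions, default 0), `noise_height` range of
#'   their apex heights.
#' @param seed integer; the generator is fully reproducible from
#'   `(parameters, seed)`.
#' @return list with `scans` (a [scan_table()]), `peaks` (peak-list
#'   data.frame), and `truth` (data.frame `peak_id`, `compound`).
#' @export
gen_scan_table <- function(compounds, rt_range = c(0, 10),
                           scan_interval = 1,
                           noise = list(), seed = 1) {
  noise <- utils::modifyList(
    list(intensity_cv = 0, n_noise_peaks = 0,
         noise_height = c(1e4, 1e5), snr = 10),
    noise)
  apices <- vapply(compounds, `[[`, 0, "rt_apex")
  if (any(apices <= rt_range[1] | apices >= rt_range[2])) {
    stop("compound apices must lie inside rt_range", call. = FALSE)
  }
  set.seed(seed)
  rts <- seq(rt_range[1], rt_range[2], by = scan_interval / 60)
  ns <- length(rts)
  # ion registry: one row per emitted chromatographic ion (12C or noise)
  reg <- list()
  for (cp in compounds) {
    for (k in seq_len(nrow(cp$ions))) {
      reg[[length(reg) + 1L]] <- data.frame(
        mz = cp$ions$mz[k],
        apex = cp$rt_apex, sigma = cp$peak_sigma,
        height = cp$max_height * cp$ions$relative_abundance[k],
        tailing = cp$tailing,
        has_13C = isTRUE(cp$ions$has_13C[k]),
        compound = cp$name, snr = 100,
        stringsAsFactors = FALSE)
    }
  }
  if (noise$n_noise_peaks > 0) {
    span <- diff(rt_range)
    for (k in seq_len(noise$n_noise_peaks)) {
      reg[[length(reg) + 1L]] <- data.frame(
        mz = stats::runif(1, 80, 950),
        apex = stats::runif(1, rt_range[1] + 0.05 * span,
                            rt_range[2] - 0.05 * span),
        sigma = stats::runif(1, 0.03, 0.08),
        height = stats::runif(1, noise$noise_height[1],
                              noise$noise_height[2]),
        tailing = 0, has_13C = FALSE, compound = "noise",
        snr = noise$snr, stringsAsFactors = FALSE)
    }
  }
  reg <- do.call(rbind, reg)
  reg$peak_id <- seq_len(nrow(reg))
  mzl <- vector("list", ns); intl <- vector("list", ns)
  profs <- lapply(seq_len(nrow(reg)), function(i) {
    h <- reg$height[i] *
      .elution_profile(rts, reg$apex[i], reg$sigma[i], reg$tailing[i])
    if (noise$intensity_cv > 0) {
      sdlog <- sqrt(log(1 + noise$intensity_cv^2))
      h <- h * stats::rlnorm(ns, -sdlog^2 / 2, sdlog)
    }
    h
  })
  floor_int <- 1
  for (s in seq_len(ns)) {
    mzv <- numeric(0); inv <- numeric(0)
    for (i in seq_len(nrow(reg))) {
      v <- profs[[i]][s]
      if (v <= floor_int) next
      mzv <- c(mzv, reg$mz[i]); inv <- c(inv, v)
      if (reg$has_13C[i]) {
        mzv <- c(mzv, reg$mz[i] + C13_DELTA)
        inv <- c(inv, 0.1 * v)
      }
    }
    o <- order(mzv)
    mzl[[s]] <- mzv[o]; intl[[s]] <- inv[o]
  }
  scans <- scan_table(rt = rts, ms_level = rep(1L, ns),
                      mz = mzl, intensity = intl)
  peaks <- data.frame(
    peak_id = reg$peak_id,
    mz_12C = reg$mz,
    mz_13C = ifelse(reg$has_13C, reg$mz + C13_DELTA, NA_real_),
    rt_apex = reg$apex,
    rt_start = pmax(rt_range[1], reg$apex - 3 * reg$sigma),
    rt_end = pmin(rt_range[2], reg$apex + 3 * reg$sigma * (1 + reg$tailing)),
    height = reg$height,
    snr = reg$snr
  )
  truth <- data.frame(peak_id = reg$peak_id, compound = reg$compound,
                      stringsAsFactors = FALSE)
  list(scans = scans, peaks = peaks, truth = truth)
}

#' Generate a random well-separated compound set
#'
#' Compounds with 3-8 ions each, guaranteed carbon-12 m/z spans above
#' `min_span`, apices spaced at least `min_rt_gap` apart — the stated
#' "well-separated" regime under which deconvolution recovery is exact.
#'
#' @param n_compounds count.
#' @param rt_range minutes.
#' @param min_rt_gap minimum apex spacing (default 0.1 min).
#' @param min_span minimum carbon-12 m/z span per compound (default 10,
#'   comfortably above the 8-Da cluster filter).
#' @param seed integer.
#' @return list of [synthetic_compound()].
#' @export
gen_compound_set <- function(n_compounds, rt_range = c(0.5, 9.5),
                             min_rt_gap = 0.1, min_span = 10, seed = 1) {
  set.seed(seed)
  span <- diff(rt_range)
  need <- n_compounds * min_rt_gap
  if (need > 0.9 * span) {
    stop("rt_range too narrow for ", n_compounds,
         " compounds at the requested spacing", call. = FALSE)
  }
  # jittered regular spacing guarantees the minimum gap
  base <- seq(rt_range[1], rt_range[2], length.out = n_compounds + 2)
  base <- base[2:(n_compounds + 1)]
  jit_amp <- pmax(0, (diff(base[1:2]) - min_rt_gap) / 2 - 1e-3)
  apices <- base + stats::runif(n_compounds, -jit_amp, jit_amp)
  lapply(seq_len(n_compounds), function(i) {
    n_ions <- sample(3:8, 1)
    lo <- stats::runif(1, 100, 700)
    mzs <- sort(c(lo, lo + min_span + stats::runif(1, 0, 40),
                  stats::runif(n_ions - 2, lo, lo + min_span + 40)))
    ab <- sort(stats::runif(n_ions, 0.15, 1), decreasing = TRUE)
    synthetic_compound(
      name = sprintf("cmpd_%03d", i),
      ions = data.frame(mz = mzs, relative_abundance = ab,
                        has_13C = c(TRUE, rep(FALSE, n_ions - 1))),
      rt_apex = apices[i],
      peak_sigma = stats::runif(1, 0.04, 0.06),
      max_height = 10^stats::runif(1, 5.5, 7)
    )
  })
}

#' Generate an MS/MS fixture (DDA or DIA)
#'
#' Starts from the MS1 world of [gen_scan_table()] and interleaves MS2
#' scans.  DDA: `n_rep` MS2 scans per compound around its apex, with the
#' selected precursor set to the compound's first ion.  DIA: one wide
#' isolation-window MS2 scan after every MS1 scan (SWATH/MSe style).
#' Fragment intensities co-vary with the precursor's elution profile;
#' fragments flagged `flat` keep a constant intensity across the run —
#' the acquisition noise that denoising must remove.
#'
#' @param compounds list of [synthetic_compound()] with `fragments` set.
#' @param acquisition `"DDA"` or `"DIA"`.
#' @param rt_range,scan_interval,noise,seed as in [gen_scan_table()].
#' @param n_rep DDA repeat MS2 scans per precursor (default 3).
#' @param frag_height apex intensity of a relative-abundance-1 fragment.
#' @return list with `scans`, `peaks`, `truth` (as [gen_scan_table()]).
#' @export
gen_msms_fixture <- function(compounds, acquisition = c("DDA", "DIA"),
                             rt_range = c(0, 10), scan_interval = 1,
                             noise = list(), seed = 1, n_rep = 3,
                             frag_height = 1e5) {
  acquisition <- match.arg(acquisition)
  ms1 <- gen_scan_table(compounds, rt_range, scan_interval, noise, seed)
  sc <- ms1$scans
  rt <- sc$rt; lvl <- sc$ms_level; mzl <- sc$mz; intl <- sc$intensity
  prec <- sc$precursor_mz; ilo <- sc$iso_lower; ihi <- sc$iso_upper
  frag_spec_at <- function(cp, t) {
    fr <- cp$fragments
    flat <- if ("flat" %in% names(fr)) fr$flat else rep(FALSE, nrow(fr))
    prof <- .elution_profile(t, cp$rt_apex, cp$peak_sigma, cp$tailing)
    int <- ifelse(flat, 0.4 * frag_height,
                  frag_height * fr$relative_abundance * prof)
    keep <- int > 1
    list(mz = fr$mz[keep], int = int[keep])
  }
  add_scan <- function(t, mzv, inv, p = NA_real_, lo = NA_real_,
                       hi = NA_real_) {
    o <- order(mzv)
    rt <<- c(rt, t); lvl <<- c(lvl, 2L)
    mzl <<- c(mzl, list(mzv[o])); intl <<- c(intl, list(inv[o]))
    prec <<- c(prec, p); ilo <<- c(ilo, lo); ihi <<- c(ihi, hi)
  }
  if (acquisition == "DDA") {
    for (cp in compounds) {
      if (is.null(cp$fragments)) next
      # repeat scans spread across the chromatographic peak (one sigma
      # apart) so genuine fragments show a clear elution profile
      offs <- seq(-(n_rep - 1) / 2, (n_rep - 1) / 2) * cp$peak_sigma
      for (dt in offs) {
        t <- cp$rt_apex + dt
        fs <- frag_spec_at(cp, t)
        if (!length(fs$mz)) next
        add_scan(t, fs$mz, fs$int, p = cp$ions$mz[1])
      }
    }
  } else {
    half <- scan_interval / 120
    for (s in which(sc$ms_level == 1L)) {
      t <- sc$rt[s] + half
      mzv <- numeric(0); inv <- numeric(0)
      for (cp in compounds) {
        if (is.null(cp$fragments)) next
        fs <- frag_spec_at(cp, t)
        mzv <- c(mzv, fs$mz); inv <- c(inv, fs$int)
      }
      if (!length(mzv)) next
      add_scan(t, mzv, inv, lo = 50, hi = 1000)
    }
  }
  o <- order(rt, lvl)
  list(
    scans = scan_table(rt = rt[o], ms_level = lvl[o], mz = mzl[o],
                       intensity = intl[o], precursor_mz = prec[o],
                       iso_lower = ilo[o], iso_upper = ihi[o]),
    peaks = ms1$peaks,
    truth = ms1$truth
  )
}

#' Generate a reference spectral library from synthetic compounds
#'
#' One spectrum per compound built from its ions (or MS2 fragments when
#' present), with optional mass jitter and log-normal intensity jitter to
#' exercise mass-error and entropy-similarity cutoffs.
#'
#' @param compounds list of [synthetic_compound()].
#' @param mz_jitter standard deviation of Gaussian m/z perturbation (Da).
#' @param intensity_cv log-normal intensity perturbation CV.
#' @param use_fragments take peaks from `fragments` instead of `ions`.
#' @param seed integer.
#' @return list of `fragment_spectrum`.
#' @export
gen_library <- function(compounds, mz_jitter = 0, intensity_cv = 0,
                        use_fragments = FALSE, seed = 1) {
  set.seed(seed)
  lapply(compounds, function(cp) {
    src <- if (use_fragments && !is.null(cp$fragments)) cp$fragments
           else cp$ions
    mz <- src$mz
    int <- src$relative_abundance * 1000
    if (mz_jitter > 0) mz <- mz + stats::rnorm(length(mz), 0, mz_jitter)
    if (intensity_cv > 0) {
      sdlog <- sqrt(log(1 + intensity_cv^2))
      int <- int * stats::rlnorm(length(int), -sdlog^2 / 2, sdlog)
    }
    fragment_spectrum(mz, int, precursor_rt = cp$rt_apex,
                      metadata = list(Name = cp$name))
  })
}

#' Generate an aligned peak-height table
#'
#' Rows mirror the peak list; heights across samples follow one shared
#' log-normal per-sample loading factor per compound (so ions of the
#' same compound co-vary across samples), while noise peaks draw
#' independent factors.  Zeros are introduced at `dropout` rate to mimic
#' missed detections.
#'
#' @param peaks,truth output of [gen_scan_table()].
#' @param n_samples sample count.
#' @param sample_cv log-normal CV of the per-sample loading factors
#'   (default 0.5, typical biological variation).
#' @param dropout fraction of cells zeroed at random.
#' @param seed integer.
#' @return aligned data.frame (`row_id`, `mz`, `rt`, `S1..Sn`).
#' @export
gen_aligned_table <- function(peaks, truth, n_samples = 20,
                              sample_cv = 0.5, dropout = 0, seed = 1) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + sample_cv^2))
  cmpds <- unique(truth$compound)
  factors <- matrix(stats::rlnorm(length(cmpds) * n_samples, 0, sdlog),
                    nrow = length(cmpds),
                    dimnames = list(cmpds, NULL))
  mat <- matrix(0, nrow = nrow(peaks), ncol = n_samples)
  for (i in seq_len(nrow(peaks))) {
    cp <- truth$compound[truth$peak_id == peaks$peak_id[i]]
    f <- if (cp == "noise") stats::rlnorm(n_samples, 0, sdlog)
         else factors[cp, ]
    mat[i, ] <- peaks$height[i] * f
  }
  if (dropout > 0) {
    mat[matrix(stats::runif(length(mat)) < dropout, nrow = nrow(mat))] <- 0
  }
  out <- data.frame(row_id = peaks$peak_id, mz = peaks$mz_12C,
                    rt = peaks$rt_apex)
  colnames(mat) <- paste0("S", seq_len(n_samples))
  cbind(out, as.data.frame(mat))
}

#' Write a peak list or aligned table as tab-separated text
#'
#' @param df data.frame from this module.
#' @param path output path (`.tsv`).
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
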