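# Shared fixture builders.  All randomness uses the caller's RNG state;
# tests set their own seeds.

# random spectrum with peaks spread over the mass range; min_gap keeps
# within-spectrum peaks from merging during conditioning
random_spectrum <- function(n = sample(3:15, 1), mz_min = 50,
                            mz_max = 1000, min_gap = 0.05) {
  mz <- sort(runif(n, mz_min, mz_max))
  while (n > 1 && any(diff(mz) < min_gap)) {
    mz <- sort(runif(n, mz_min, mz_max))
  }
  fragment_spectrum(mz, runif(n, 1, 1000))
}

# gaussian EIC constructed directly (no scan table involved)
gaussian_eic <- function(apex = 4.3, sigma = 0.05, height = 1e6,
                         halfwidth = 3, dt = 1 / 60, mz = 200) {
  rt <- seq(apex - halfwidth * sigma, apex + halfwidth * sigma, by = dt)
  structure(list(mz = mz, rt = rt,
                 intensity = height * exp(-(rt - apex)^2 / (2 * sigma^2)),
                 smoothed = FALSE),
            class = "eic")
}

# tiny deterministic MSP text fixture
write_msp_fixture <- function(path) {
  writeLines(c(
    "Name: alpha",
    "PrecursorMZ: 209.09200",
    "InChIKey: AAAA-BBBB",
    "Num Peaks: 3",
    "94.06500 10",
    "146.06000 55.5",
    "192.06500 100",
    "",
    "Name: beta",
    "Num Peaks: 2",
    "100.00000\t20",
    "300.10000\t80"
  ), path)
  path
}

# --- naive reimplementation of the scoring chain -------------------------
# Independent oracle: explicit loops, no shared code with the package.

naive_pairs <- function(lib, ex, tol) {
  claimed <- rep(FALSE, length(ex$mz))
  out <- NULL
  for (i in seq_along(lib$mz)) {
    best <- 0; bestd <- Inf
    for (j in seq_along(ex$mz)) {
      if (claimed[j]) next
      d <- abs(ex$mz[j] - lib$mz[i])
      if (d < bestd) { bestd <- d; best <- j }
    }
    if (best > 0 && bestd <= tol) {
      claimed[best] <- TRUE
      out <- rbind(out, c(i, best))
    }
  }
  out
}

naive_entropy <- function(ints) {
  tot <- 0
  for (v in ints) tot <- tot + v
  s <- 0
  for (v in ints) if (v > 0) { p <- v / tot; s <- s - p * log(p) }
  s
}

naive_weighted <- function(mz, ints) {
  tot <- sum(ints); ints <- ints / tot
  s <- naive_entropy(ints)
  if (s < 3) {
    w <- 0.25 * (1 + s)
    ints <- ints^w
    ints <- ints / sum(ints)
  }
  list(mz = mz, ints = ints)
}

naive_merge_entropy <- function(a, b, tol) {
  mz <- c(a$mz, b$mz); ints <- c(a$ints, b$ints) / 2
  o <- order(mz); mz <- mz[o]; ints <- ints[o]
  gmz <- c(); gint <- c()
  cur_m <- mz[1] * ints[1]; cur_i <- ints[1]; last <- mz[1]
  for (k in seq_along(mz)[-1]) {
    if (mz[k] - last <= tol) {
      cur_m <- cur_m + mz[k] * ints[k]; cur_i <- cur_i + ints[k]
    } else {
      gmz <- c(gmz, cur_m / cur_i); gint <- c(gint, cur_i)
      cur_m <- mz[k] * ints[k]; cur_i <- ints[k]
    }
    last <- mz[k]
  }
  gint <- c(gint, cur_i)
  naive_entropy(gint)
}

# full naive score set for two raw (already conditioned) spectra
naive_scores <- function(lib, ex, tol) {
  pr <- naive_pairs(lib, ex, tol)
  np <- if (is.null(pr)) 0L else nrow(pr)
  if (np == 0L) {
    return(list(np = 0L, cosine = 0, entropy_sim = 0, neme = NA_real_,
                score = 0))
  }
  num <- 0; dl <- 0; de <- 0; se <- 0
  for (k in seq_len(np)) {
    num <- num + lib$intensity[pr[k, 1]] * ex$intensity[pr[k, 2]]
    de <- de + ex$intensity[pr[k, 2]]^2
    se <- se + (lib$mz[pr[k, 1]] - ex$mz[pr[k, 2]])^2
  }
  for (v in lib$intensity) dl <- dl + v^2
  cosine <- num / sqrt(dl * de)
  lw <- naive_weighted(lib$mz, lib$intensity)
  ew <- naive_weighted(ex$mz, ex$intensity)
  s_l <- naive_entropy(lw$ints)
  s_e <- naive_entropy(ew$ints)
  s_m <- naive_merge_entropy(lw, ew, tol)
  es <- 1 - (2 * s_m - s_l - s_e) / log(4)
  es <- min(1, max(0, es))
  list(np = np, cosine = min(1, cosine), entropy_sim = es,
       neme = sqrt(se / np), score = min(1, cosine) * es^2)
}

# cluster-membership precision/recall/F1 against generator ground truth
membership_metrics <- function(clusters, truth) {
  truth_sets <- split(truth$peak_id, truth$compound)
  truth_sets <- truth_sets[names(truth_sets) != "noise"]
  tp <- 0; fp <- 0
  for (cl in clusters) {
    ids <- cl$member_peak_ids
    best <- 0
    for (ts in truth_sets) best <- max(best, length(intersect(ids, ts)))
    tp <- tp + best
    fp <- fp + length(ids) - best
  }
  total_true <- sum(lengths(truth_sets))
  precision <- if (tp + fp > 0) tp / (tp + fp) else 1
  recall <- if (total_true > 0) tp / total_true else 1
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1)
}
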