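make_peaks <- function(height, snr = rep(10, length(height)),
                       rt = seq_along(height)) {
  data.frame(peak_id = seq_along(height), mz_12C = 100 + seq_along(height),
             mz_13C = NA_real_, rt_apex = rt, rt_start = rt - 0.1,
             rt_end = rt + 0.1, height = height, snr = snr)
}

test_that("select_seed picks tallest eligible unassigned peak", {
  pk <- make_peaks(c(10, 5, 3))
  p <- csa_params(seed_snr_min = 5)
  expect_equal(select_seed(pk, c(FALSE, FALSE, FALSE), p), 1)
  expect_equal(select_seed(pk, c(TRUE, FALSE, FALSE), p), 2)
  pk$snr <- c(1, 1, 1)
  expect_null(select_seed(pk, c(FALSE, FALSE, FALSE), p))
  # height tie breaks to lower peak_id
  pk2 <- make_peaks(c(5, 5))
  expect_equal(select_seed(pk2, c(FALSE, FALSE), csa_params()), 1)
})

test_that("group_candidates uses a closed window and skips assigned", {
  pk <- data.frame(peak_id = 1:6, mz_12C = 101:106, mz_13C = NA_real_,
                   rt_apex = c(5, 5.005, 5.01, 4.99, 5.5, 4.5),
                   rt_start = 4.9, rt_end = 5.1,
                   height = 1:6, snr = 10)
  p <- csa_params(rt_group_window = 0.01)
  got <- group_candidates(pk, 1, rep(FALSE, 6), p)
  expect_setequal(got, c(2, 3, 4))   # boundary |drt| == window included
  got2 <- group_candidates(pk, 1, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE), p)
  expect_setequal(got2, c(3, 4))
})

test_that("profile_correlation matches Gaussian closed-form expectations", {
  a <- smooth_eic(gaussian_eic(apex = 4.3))
  expect_equal(profile_correlation(a, a), 1.0)
  b <- a
  b$intensity <- b$intensity * 3
  expect_equal(profile_correlation(a, b), 1.0)

  # apices 4 sigma apart on a shared grid: not correlatable at 0.98
  rt <- seq(4.0, 4.6, by = 1 / 60)
  mk <- function(apex) {
    smooth_eic(structure(list(
      mz = 1, rt = rt,
      intensity = 1e6 * exp(-(rt - apex)^2 / (2 * 0.05^2)),
      smoothed = FALSE), class = "eic"))
  }
  r <- profile_correlation(mk(4.2), mk(4.4), 0.5)
  expect_lt(r, 0.98)

  bad <- mk(4.2); bad$rt <- bad$rt + 0.001
  expect_error(profile_correlation(mk(4.2), bad), "grid")
  raw <- gaussian_eic()
  expect_error(profile_correlation(raw, raw), "smoothed")
})

test_that("intersample_filter keeps correlated, rejects permuted, abstains when thin", {
  set.seed(21)
  n_samp <- 200
  sv <- rlnorm(n_samp, 10, 0.5)
  aligned <- data.frame(row_id = 1:3, mz = c(100, 101, 102),
                        rt = c(5, 5, 5))
  aligned <- cbind(aligned, rbind(sv, sv * 2, sample(sv)))
  names(aligned)[4:(3 + n_samp)] <- paste0("S", 1:n_samp)
  pk <- data.frame(peak_id = 1:3, mz_12C = c(100, 101, 102),
                   mz_13C = NA_real_, rt_apex = 5, rt_start = 4.9,
                   rt_end = 5.1, height = 1, snr = 10)
  kept <- intersample_filter(aligned, pk, 1, c(2, 3), r_min = 0.5)
  expect_true(2 %in% kept)     # proportional vector retained
  expect_false(3 %in% kept)    # permuted vector rejected

  # < 5 shared samples: retained by default
  aligned2 <- aligned[, 1:8]
  aligned2[1, 6:8] <- 0
  kept2 <- intersample_filter(aligned2, pk, 1, c(2, 3), r_min = 0.5)
  expect_setequal(kept2, c(2, 3))
})

test_that("build_cluster enforces span and ion-count filters", {
  cps <- list(synthetic_compound(
    "big", data.frame(mz = c(150, 180, 210, 240, 270),
                      relative_abundance = c(1, 0.8, 0.6, 0.4, 0.2)),
    rt_apex = 3))
  fx <- gen_scan_table(cps, rt_range = c(2, 4), seed = 2)
  res <- build_cluster(fx$peaks, 1, 2:5, fx$scans, csa_params())
  expect_false(is.null(res$cluster))
  expect_length(res$cluster$member_peak_ids, 5)
  expect_equal(res$cluster$member_r[1], 1)
  expect_true(all(res$cluster$member_r >= 0.98))

  # span 5 Da < 8 Da: rejected even though ions co-elute
  cps2 <- list(synthetic_compound(
    "narrow", data.frame(mz = c(150, 155), relative_abundance = c(1, 0.5)),
    rt_apex = 3))
  fx2 <- gen_scan_table(cps2, rt_range = c(2, 4), seed = 2)
  res2 <- build_cluster(fx2$peaks, 1, 2, fx2$scans, csa_params())
  expect_null(res2$cluster)
  expect_setequal(res2$members, c(1, 2))  # both still assigned

  # a seed whose only partner is its own carbon-13 isotopologue
  cps3 <- list(synthetic_compound(
    "iso", data.frame(mz = 150, relative_abundance = 1, has_13C = TRUE),
    rt_apex = 3))
  fx3 <- gen_scan_table(cps3, rt_range = c(2, 4), seed = 2)
  expect_length(deconvolute_file(fx3$scans, fx3$peaks), 0)
})

test_that("carbon-13 partners are appended but never drive the filters", {
  cps <- list(synthetic_compound(
    "c13", data.frame(mz = c(150, 190, 230),
                      relative_abundance = c(1, 0.6, 0.3),
                      has_13C = c(TRUE, TRUE, FALSE)),
    rt_apex = 3))
  fx <- gen_scan_table(cps, rt_range = c(2, 4), seed = 7)
  cl <- deconvolute_file(fx$scans, fx$peaks)
  expect_length(cl, 1)
  sp <- cl[[1]]$spectrum
  expect_length(cl[[1]]$member_peak_ids, 3)
  # spectrum carries the two isotopologues on top of the three members
  expect_equal(n_peaks(sp), 5)
  expect_true(all(abs(c(151.00336, 191.00336) -
                        sp$mz[c(2, 4)]) < 1e-6))
})

test_that("deconvolution recovers disjoint compounds exactly and is idempotent", {
  cps <- gen_compound_set(3, seed = 31)
  fx <- gen_scan_table(cps, seed = 31)
  cl1 <- deconvolute_file(fx$scans, fx$peaks)
  expect_length(cl1, 3)
  m <- membership_metrics(cl1, fx$truth)
  expect_equal(m$f1, 1.0)
  cl2 <- deconvolute_file(fx$scans, fx$peaks)
  expect_identical(lapply(cl1, `[[`, "member_peak_ids"),
                   lapply(cl2, `[[`, "member_peak_ids"))
})

test_that("isolated singleton ions yield zero clusters", {
  cps <- lapply(1:4, function(i) {
    synthetic_compound(paste0("s", i),
                       data.frame(mz = 100 + 37 * i,
                                  relative_abundance = 1),
                       rt_apex = 1 + i)
  })
  fx <- gen_scan_table(cps, rt_range = c(0, 6), seed = 3)
  expect_length(deconvolute_file(fx$scans, fx$peaks), 0)
})

test_that("emitted cluster sets are order-invariant and pairwise disjoint", {
  cps <- gen_compound_set(4, seed = 8)
  fx <- gen_scan_table(cps, seed = 8,
                       noise = list(n_noise_peaks = 10))
  cl <- deconvolute_file(fx$scans, fx$peaks)
  all_ids <- unlist(lapply(cl, `[[`, "member_peak_ids"))
  expect_equal(anyDuplicated(all_ids), 0)

  set.seed(1)
  perm <- sample(nrow(fx$peaks))
  pk2 <- fx$peaks[perm, ]
  rownames(pk2) <- NULL
  cl2 <- deconvolute_file(fx$scans, pk2)
  key <- function(cls) {
    sets <- lapply(cls, function(x) sort(x$member_peak_ids))
    sets[order(vapply(sets, min, 0))]
  }
  expect_identical(key(cl), key(cl2))
})

test_that("raising pearson_min never adds members", {
  cps <- gen_compound_set(3, seed = 77)
  fx <- gen_scan_table(cps, seed = 77,
                       noise = list(intensity_cv = 0.05))
  loose <- deconvolute_file(fx$scans, fx$peaks,
                            params = csa_params(pearson_min = 0.9))
  strict <- deconvolute_file(fx$scans, fx$peaks,
                             params = csa_params(pearson_min = 0.99))
  loose_ids <- unlist(lapply(loose, `[[`, "member_peak_ids"))
  strict_ids <- unlist(lapply(strict, `[[`, "member_peak_ids"))
  expect_true(all(strict_ids %in% loose_ids))
})

test_that("link_true_positive annotates matching clusters only", {
  cps <- gen_compound_set(2, seed = 12)
  fx <- gen_scan_table(cps, seed = 12)
  cl <- deconvolute_file(fx$scans, fx$peaks)
  target_mz <- cps[[1]]$ions$mz[1]
  targets <- data.frame(name = c("hit", "far"),
                        mz = c(target_mz, target_mz),
                        rt = c(cps[[1]]$rt_apex, cps[[1]]$rt_apex + 1))
  out <- link_true_positive(cl, targets, mz_tol_da = 0.01, rt_tol = 0.05)
  annotated <- vapply(out, function(x)
    identical(x$spectrum$metadata$True_positive, "hit"), logical(1))
  expect_equal(sum(annotated), 1)
})
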