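test_that("mzML round trip preserves scans, levels, precursors, windows", {
  ions <- data.frame(mz = 209.092, relative_abundance = 1)
  frags <- data.frame(mz = c(146.06, 94.065), relative_abundance = c(1, 0.4))
  cp <- synthetic_compound("c1", ions, rt_apex = 2, fragments = frags)
  fx <- gen_msms_fixture(list(cp), "DIA", rt_range = c(1.5, 2.5), seed = 3)
  f <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(fx$scans, f)
  back <- read_scans(f)
  expect_equal(length(back$rt), length(fx$scans$rt))
  expect_false(is.unsorted(back$rt))
  expect_equal(back$ms_level, fx$scans$ms_level)
  expect_equal(back$rt, fx$scans$rt, tolerance = 1e-7)
  expect_identical(back$mz, fx$scans$mz)
  expect_identical(back$intensity, fx$scans$intensity)
  expect_equal(back$iso_lower, fx$scans$iso_lower, tolerance = 1e-6)
})

test_that("seconds-based retention times are converted to minutes", {
  f <- withr::local_tempfile(fileext = ".mzML")
  sc <- scan_table(rt = c(1, 2), ms_level = c(1L, 1L),
                   mz = list(100, 100), intensity = list(5, 5))
  write_mzml(sc, f)
  txt <- readLines(f)
  txt <- sub('value="1.00000000" unitName="minute"',
             'value="60.0" unitName="second"', txt, fixed = TRUE)
  writeLines(txt, f)
  back <- read_mzml(f)
  expect_equal(back$rt[1], 1)
})

test_that("profile-mode data is rejected with centroiding advice", {
  f <- withr::local_tempfile(fileext = ".mzML")
  sc <- scan_table(rt = 1, ms_level = 1L, mz = list(100),
                   intensity = list(5))
  write_mzml(sc, f)
  txt <- readLines(f)
  txt <- sub('accession="MS:1000127" name="centroid spectrum"',
             'accession="MS:1000128" name="profile spectrum"', txt,
             fixed = TRUE)
  writeLines(txt, f)
  expect_error(read_mzml(f), "centroid")
})

test_that("read_peaklist validates schema and drops invariant violations", {
  df <- data.frame(peak_id = 1:3, mz_12C = c(100, 200, 300),
                   mz_13C = c(101.003, NA, 302),
                   rt_apex = c(1, 2, 3), rt_start = c(0.9, 2.5, 2.9),
                   rt_end = c(1.1, 2.1, 3.1), height = c(10, 10, 10),
                   snr = c(5, 5, 5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_table_tsv(df, f)
  # row 2: rt_start > rt_apex; row 3: isotope spacing 2 Da out of range
  expect_warning(pk <- read_peaklist(f), "violate")
  expect_equal(pk$peak_id, 1L)

  df2 <- df[, setdiff(names(df), "height")]
  write_table_tsv(df2, f)
  expect_error(read_peaklist(f), "height")
})

test_that("extract_eic recovers injected apex, sums centroids, is linear", {
  cp <- synthetic_compound(
    "c1", data.frame(mz = 200, relative_abundance = 1),
    rt_apex = 3, max_height = 1e6)
  fx <- gen_scan_table(list(cp), rt_range = c(2, 4), seed = 1)
  eic <- extract_eic(fx$scans, 200, rt_window = c(2.5, 3.5))
  expect_equal(max(eic$intensity), 1e6, tolerance = 1e-6)
  expect_equal(eic$rt[which.max(eic$intensity)], 3, tolerance = 1 / 60)

  none <- extract_eic(fx$scans, 555)
  expect_true(all(none$intensity == 0))

  # two centroids inside tolerance are summed
  sc <- scan_table(rt = 1, ms_level = 1L,
                   mz = list(c(200.000, 200.001)),
                   intensity = list(c(10, 5)))
  expect_equal(extract_eic(sc, 200.0005, mz_tol = 0.01,
                           tol_unit = "da")$intensity, 15)

  # linearity in intensity
  sc3 <- fx$scans
  sc3$intensity <- lapply(sc3$intensity, function(v) 3 * v)
  e1 <- extract_eic(fx$scans, 200)
  e3 <- extract_eic(sc3, 200)
  expect_equal(e3$intensity, 3 * e1$intensity)

  expect_error(extract_eic(fx$scans, 200, rt_window = c(3, 3)), "window")
})

test_that("smooth_eic is near-identity on a clean Gaussian at 1 Hz", {
  e <- gaussian_eic()
  s <- smooth_eic(e)
  truth <- 1e6 * exp(-(s$rt - 4.3)^2 / (2 * 0.05^2))
  expect_lt(max(abs(s$intensity - truth) / truth), 0.02)
  expect_true(s$smoothed)
  # interval preserved, no negatives
  expect_equal(range(s$rt), range(e$rt))
  expect_true(all(s$intensity >= 0))
})

test_that("smooth_eic maps a constant to a constant and rejects short EICs", {
  e <- structure(list(mz = 1, rt = seq(0, 1, by = 0.05),
                      intensity = rep(7, 21), smoothed = FALSE),
                 class = "eic")
  s <- smooth_eic(e)
  expect_equal(s$intensity, rep(7, 100), tolerance = 1e-8)
  short <- structure(list(mz = 1, rt = 1:4 / 10, intensity = rep(1, 4),
                          smoothed = FALSE), class = "eic")
  expect_error(smooth_eic(short), "fewer than 5")
})

test_that("smoothing improves correlation with the noiseless profile", {
  set.seed(99)
  e <- gaussian_eic()
  clean <- e$intensity
  truth_grid <- function(s) 1e6 * exp(-(s$rt - 4.3)^2 / (2 * 0.05^2))
  gain <- replicate(40, {
    noisy <- e
    noisy$intensity <- clean * rlnorm(length(clean), 0, 0.05)
    s <- smooth_eic(noisy)
    cor(s$intensity, truth_grid(s)) - cor(noisy$intensity, clean)
  })
  expect_gt(mean(gain), 0)
  expect_gt(mean(gain > 0), 0.6)
})
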