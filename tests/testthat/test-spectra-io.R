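test_that("read_msp parses records, synonyms and separators", {
  f <- write_msp_fixture(withr::local_tempfile(fileext = ".msp"))
  sp <- read_msp(f)
  expect_length(sp, 2)
  expect_equal(n_peaks(sp[[1]]), 3)
  expect_equal(n_peaks(sp[[2]]), 2)
  expect_equal(sp[[1]]$precursor_mz, 209.092)
  expect_equal(sp[[1]]$metadata$Name, "alpha")
  expect_equal(sp[[1]]$metadata$InChIKey, "AAAA-BBBB")
  expect_true(is.na(sp[[2]]$precursor_mz))

  expect_error(read_msp(file.path(tempdir(), "nope.msp")), "not found")
  bad <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: empty", "Num Peaks: 0"), bad)
  expect_error(suppressWarnings(read_msp(bad)), "parseable")
})

test_that("declared/actual peak-count mismatch keeps actual peaks", {
  f <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: x", "Num Peaks: 5",
               "100.0 1", "200.0 2"), f)
  expect_warning(sp <- read_msp(f), "declared peak count")
  expect_equal(n_peaks(sp[[1]]), 2)
})

test_that("write_msp emits NIST-style records and omits absent precursors", {
  sp <- fragment_spectrum(c(100, 200, 300), c(1, 2, 3),
                          metadata = list(Name = "t"))
  f <- withr::local_tempfile(fileext = ".msp")
  write_msp(list(sp), f)
  txt <- readLines(f)
  expect_true(any(grepl("^Num Peaks: 3$", txt)))
  expect_false(any(grepl("PrecursorMZ", txt)))
  expect_error(write_msp(list(), f), "no spectra")

  with_prec <- fragment_spectrum(100, 1, precursor_mz = 300.1)
  write_msp(list(with_prec), f)
  expect_true(any(grepl("PrecursorMZ: 300.10000", readLines(f), fixed = TRUE)))
})

test_that("MSP round trip is the identity on parsed content", {
  f <- write_msp_fixture(withr::local_tempfile(fileext = ".msp"))
  orig <- read_msp(f)
  f2 <- withr::local_tempfile(fileext = ".msp")
  write_msp(orig, f2)
  back <- read_msp(f2)
  expect_length(back, length(orig))
  for (i in seq_along(orig)) {
    expect_equal(back[[i]]$mz, orig[[i]]$mz, tolerance = 1e-6)
    expect_equal(back[[i]]$intensity, orig[[i]]$intensity, tolerance = 1e-6)
    expect_equal(back[[i]]$precursor_mz, orig[[i]]$precursor_mz)
    expect_equal(back[[i]]$metadata$Name, orig[[i]]$metadata$Name)
  }
})

test_that("read_mgf handles PEPMASS, TITLE, charge columns and round-trips", {
  f <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS",
    "TITLE=spec one",
    "PEPMASS=300.1 12345",
    "CHARGE=1+",
    "100.0 10 1+",
    "200.0 20",
    "END IONS"
  ), f)
  sp <- read_mgf(f)
  expect_length(sp, 1)
  expect_equal(sp[[1]]$precursor_mz, 300.1)
  expect_equal(sp[[1]]$metadata$Name, "spec one")
  expect_equal(sp[[1]]$mz, c(100, 200))
  expect_equal(sp[[1]]$intensity, c(10, 20))

  f2 <- withr::local_tempfile(fileext = ".msp")
  write_msp(sp, f2)
  back <- read_msp(f2)
  expect_equal(back[[1]]$mz, sp[[1]]$mz)
  expect_equal(back[[1]]$precursor_mz, 300.1)
})

test_that("FSDB caches recomputable entropies and markers", {
  set.seed(11)
  spectra <- replicate(100, random_spectrum(), simplify = FALSE)
  params <- search_params()
  db <- build_fsdb(spectra, params)
  expect_s3_class(db, "fsdb")
  expect_length(db$entries, 100)
  for (e in db$entries) {
    recomputed <- spectral_entropy(e$spectrum$intensity /
                                     sum(e$spectrum$intensity))
    expect_lt(abs(e$entropy - recomputed), 1e-12)
    expect_true(all(e$markers %in% e$spectrum$mz))
  }
  # closed-form entries
  one <- build_fsdb(list(fragment_spectrum(100, 5)), params)
  expect_equal(one$entries[[1]]$entropy, 0)
  two <- build_fsdb(list(fragment_spectrum(c(100, 200), c(7, 7))), params)
  expect_equal(two$entries[[1]]$entropy, log(2))
})

test_that("empty-after-denoising spectra are dropped with a warning", {
  ok <- fragment_spectrum(c(100, 200), c(5, 500))
  zero <- fragment_spectrum(c(100, 150), c(0, 0))
  expect_warning(db <- build_fsdb(list(ok, zero), search_params()),
                 "empty after conditioning")
  expect_length(db$entries, 1)
})

test_that("FSDB serialization round-trips and is byte-deterministic", {
  set.seed(5)
  spectra <- replicate(20, random_spectrum(), simplify = FALSE)
  db <- build_fsdb(spectra, search_params(), ionization_mode = "negative")
  f1 <- withr::local_tempfile(fileext = ".fsdb")
  f2 <- withr::local_tempfile(fileext = ".fsdb")
  write_fsdb(db, f1)
  write_fsdb(build_fsdb(spectra, search_params(),
                        ionization_mode = "negative"), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_fsdb(f1)
  expect_equal(back$ionization_mode, "negative")
  expect_length(back$entries, length(db$entries))
  for (i in seq_along(db$entries)) {
    expect_equal(back$entries[[i]]$spectrum$mz, db$entries[[i]]$spectrum$mz)
    expect_equal(back$entries[[i]]$entropy, db$entries[[i]]$entropy)
    expect_equal(back$entries[[i]]$markers, db$entries[[i]]$markers)
  }
})
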