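test_that("resolve_adjacent merges runs with intensity-weighted means", {
  sp <- fragment_spectrum(c(100.000, 100.005), c(2, 1))
  r <- resolve_adjacent(sp, 0.01)
  expect_equal(r$mz, 100.001667, tolerance = 1e-6)
  expect_equal(r$intensity, 3)

  apart <- fragment_spectrum(c(100, 100.5, 101), c(1, 2, 3))
  expect_equal(resolve_adjacent(apart, 0.01)$mz, apart$mz)

  chain <- fragment_spectrum(c(100, 100.008, 100.016), c(1, 1, 1))
  expect_equal(n_peaks(resolve_adjacent(chain, 0.01)), 1)
})

test_that("remove_noise thresholds at a percent of the base peak", {
  sp <- fragment_spectrum(c(100, 200, 300), c(1000, 10, 5))
  out <- remove_noise(sp, 1)
  expect_equal(out$mz, c(100, 200))   # 5 < 10 removed; 10 >= 10 kept
  expect_equal(remove_noise(sp, 0.1)$mz, sp$mz)
  single <- fragment_spectrum(100, 0.001)
  expect_equal(n_peaks(remove_noise(single, 1)), 1)
})

test_that("characteristic markers follow the baseline percentage", {
  sp <- fragment_spectrum(c(100, 200, 300), c(100, 40, 5))
  expect_length(characteristic_markers(sp, 0), 3)
  expect_equal(characteristic_markers(sp, 100), 100)
  expect_length(characteristic_markers(sp, 10), 2)
})

test_that("spectral entropy closed forms and direct sums", {
  expect_equal(spectral_entropy(fragment_spectrum(100, 5)), 0)
  n <- 7
  eq <- fragment_spectrum(100 + 1:n, rep(3, n))
  expect_equal(spectral_entropy(eq), log(n))
  expect_equal(spectral_entropy(fragment_spectrum(c(1, 2), c(3, 1))),
               -(0.75 * log(0.75) + 0.25 * log(0.25)))
})

test_that("weight transform branches on S = 3 and re-normalizes", {
  n <- 25   # ln 25 ~ 3.22 >= 3: identity branch
  hi <- fragment_spectrum(100 + 1:n, rep(1, n))
  out <- weight_transform(hi)
  expect_equal(out$intensity, rep(1 / n, n))

  single <- weight_transform(fragment_spectrum(100, 42))
  expect_equal(single$intensity, 1)

  sp <- fragment_spectrum(c(100, 200), c(0.75, 0.25))
  s <- spectral_entropy(sp)
  w <- 0.25 * (1 + s)
  expected <- c(0.75^w, 0.25^w) / sum(c(0.75^w, 0.25^w))
  expect_equal(weight_transform(sp)$intensity, expected, tolerance = 1e-12)
})

test_that("match_fragments pairs greedily one-to-one", {
  a <- fragment_spectrum(c(100, 200, 300), c(1, 1, 1))
  expect_equal(nrow(match_fragments(a, a, 0.01)), 3)
  b <- fragment_spectrum(c(150, 250), c(1, 1))
  expect_equal(nrow(match_fragments(a, b, 0.01)), 0)
  # two experimental peaks within tol of one library peak: nearest wins
  lib <- fragment_spectrum(100.000, 1)
  ex <- fragment_spectrum(c(99.996, 100.002), c(5, 7))
  pr <- match_fragments(lib, ex, 0.01)
  expect_equal(pr$mz_exptl, 100.002)
})

test_that("cosine similarity follows the library-fragment restriction", {
  a <- fragment_spectrum(c(100, 200), c(1, 1))
  pr <- match_fragments(a, a, 0.01)
  expect_equal(cosine_similarity(a, a, pr), 1)
  ex <- fragment_spectrum(c(100, 200), c(1, 0.5))
  expect_equal(cosine_similarity(a, ex, match_fragments(a, ex, 0.01)),
               1.5 / sqrt(2 * 1.25), tolerance = 1e-12)
  # scale invariance
  ex3 <- fragment_spectrum(ex$mz, ex$intensity * 17)
  expect_equal(cosine_similarity(a, ex3, match_fragments(a, ex3, 0.01)),
               cosine_similarity(a, ex, match_fragments(a, ex, 0.01)),
               tolerance = 1e-12)
  # unmatched library peaks penalize "all_lib" but not "matched_only"
  lib2 <- fragment_spectrum(c(100, 200, 300), c(1, 1, 1))
  ex2 <- fragment_spectrum(c(100, 200), c(1, 1))
  pr2 <- match_fragments(lib2, ex2, 0.01)
  expect_lt(cosine_similarity(lib2, ex2, pr2, "all_lib"), 1)
  expect_equal(cosine_similarity(lib2, ex2, pr2, "matched_only"), 1)
})

test_that("entropy similarity closed forms, symmetry, bounds", {
  a <- fragment_spectrum(c(100, 150, 200), c(5, 25, 100))
  expect_equal(entropy_similarity(a, a, 0.01), 1)
  s1 <- fragment_spectrum(100, 1)
  s2 <- fragment_spectrum(300, 1)
  expect_equal(entropy_similarity(s1, s2, 0.01), 0)
  set.seed(3)
  for (k in 1:20) {
    x <- random_spectrum(); y <- random_spectrum()
    sxy <- entropy_similarity(x, y, 0.01)
    expect_equal(sxy, entropy_similarity(y, x, 0.01), tolerance = 1e-12)
    expect_gte(sxy, 0); expect_lte(sxy, 1)
  }
})

test_that("NEME direct arithmetic", {
  pr <- data.frame(mz_lib = c(100, 200), mz_exptl = c(100.003, 200.004))
  expect_equal(neme(pr), sqrt(12.5e-6), tolerance = 1e-8)
  same <- data.frame(mz_lib = 100, mz_exptl = 100)
  expect_equal(neme(same), 0)
  expect_error(neme(data.frame(mz_lib = numeric(0),
                               mz_exptl = numeric(0))), "undefined")
})

test_that("prefilter gates on precursor and marker percentage", {
  params <- search_params(precursor_mz_tol = 0.01,
                          marker_baseline_pct = 10,
                          marker_min_match_pct = 75)
  db <- build_fsdb(list(fragment_spectrum(
    c(100, 150, 200, 250), c(100, 90, 80, 70),
    precursor_mz = 300)), params)
  entry <- db$entries[[1]]
  self <- condition_spectrum(entry$spectrum, params)
  expect_true(prefilter(self, entry, params))

  off_prec <- fragment_spectrum(c(100, 150, 200, 250), c(1, 1, 1, 1),
                                precursor_mz = 100.0)
  expect_false(prefilter(off_prec, entry, params))

  # 2 of 4 markers matched: fails at 75%, passes at 50%
  half <- fragment_spectrum(c(100, 150), c(1, 1), precursor_mz = 300)
  expect_false(prefilter(half, entry, params))
  params50 <- search_params(precursor_mz_tol = 0.01,
                            marker_baseline_pct = 10,
                            marker_min_match_pct = 50)
  expect_true(prefilter(half, entry, params50))
})

test_that("search ranks self-hit first with perfect scores", {
  set.seed(10)
  spectra <- replicate(30, random_spectrum(), simplify = FALSE)
  db <- build_fsdb(spectra, search_params())
  q <- spectra[[7]]
  hits <- search_spectrum(q, db)
  expect_equal(hits$entry_id[1], 7)
  expect_equal(hits$score[1], 1, tolerance = 1e-12)
  expect_equal(hits$neme[1], 0)
  expect_equal(hits$rank, seq_len(nrow(hits)))
  # score identity on every hit
  expect_true(all(abs(hits$score - hits$cosine * hits$entropy_sim^2)
                  < 1e-12))
})

test_that("search returns nothing against a disjoint library and errors empty", {
  db <- build_fsdb(list(fragment_spectrum(c(800, 900), c(1, 1))),
                   search_params())
  q <- fragment_spectrum(c(100, 200), c(1, 1))
  expect_equal(nrow(search_spectrum(q, db)), 0)
  empty <- structure(list(entries = list(), ionization_mode = "positive",
                          build_params = search_params(),
                          schema = "mscsa-fsdb/1"), class = "fsdb")
  expect_error(search_spectrum(q, empty), "empty")
})

test_that("summarize_study aggregates frequency and median rank", {
  res <- rbind(
    data.frame(sample_id = paste0("s", 1:10), row_id = 1,
               source_id = "A", rank = 1),
    data.frame(sample_id = paste0("s", 1:3), row_id = 2,
               source_id = "B", rank = c(1, 2, 4)))
  out <- summarize_study(res)
  expect_equal(out$frequency[out$source_id == "A"], 10)
  expect_equal(out$median_rank[out$source_id == "A"], 1)
  expect_equal(out$median_rank[out$source_id == "B"], 2)
  expect_equal(out$source_id, c("A", "B"))  # frequency-descending
  expect_error(summarize_study(data.frame(sample_id = 1)), "missing")
})

test_that("engine matches the naive oracle on random pairs", {
  set.seed(123)
  params <- search_params()
  for (k in 1:200) {
    lib <- condition_spectrum(random_spectrum(), params)
    ex <- if (k %% 3 == 0) {
      # perturbed copy: guarantees matches
      fragment_spectrum(lib$mz + rnorm(length(lib$mz), 0, 0.002),
                        lib$intensity * rlnorm(length(lib$mz), 0, 0.2))
    } else {
      condition_spectrum(random_spectrum(), params)
    }
    got <- score_pair(lib, ex, params)
    want <- naive_scores(lib, ex, params$fragment_mz_tol)
    expect_equal(got$np, want$np)
    expect_lt(abs(got$cosine - want$cosine), 1e-10)
    expect_lt(abs(got$entropy_sim - want$entropy_sim), 1e-10)
    if (got$np > 0) expect_lt(abs(got$neme - want$neme), 1e-10)
    expect_lt(abs(got$score - want$score), 1e-10)
  }
})
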