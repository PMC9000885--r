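test_that("spectrum construction enforces its invariants", {
  sp <- spec2(c(150, 100), c(10, 20), precursor = 200)
  expect_equal(sp$peaks$mz, c(100, 150))  # sorted on construction
  expect_error(ms_spectrum("x", 200, data.frame(mz = 250, intensity = 1)),
               "above precursor")
  expect_error(ms_spectrum("x", 200, data.frame(mz = -1, intensity = 1)))
  expect_equal(n_peaks(ms_spectrum("e", 100, NULL)), 0L)
})

test_that("normalization is idempotent and scale-invariant", {
  sp <- spec2(c(100, 200), c(50, 25), precursor = 250)
  n1 <- normalize_spectrum(sp)
  expect_equal(n1$peaks$intensity, c(100, 50))
  expect_equal(normalize_spectrum(n1)$peaks$intensity, n1$peaks$intensity)
  scaled <- sp; scaled$peaks$intensity <- sp$peaks$intensity * 7.3
  expect_equal(normalize_spectrum(scaled)$peaks$intensity,
               n1$peaks$intensity)
  single <- spec2(100, 3, precursor = 150)
  expect_equal(normalize_spectrum(single)$peaks$intensity, 100)
  zero <- spec2(c(100, 110), c(0, 0), precursor = 150)
  expect_error(normalize_spectrum(zero), "positive intensity")
})

test_that("peak matching is greedy, one-to-one, inclusive at the tolerance", {
  a <- spec2(c(100, 150, 200), c(10, 20, 30), precursor = 250)
  m <- match_peaks(a, a, 10)
  expect_equal(nrow(m), 3L)
  expect_equal(m$mz_a, m$mz_b)
  # 11 mDa apart at 10 mDa tolerance: unmatched
  b <- spec2(100.011, 10, precursor = 250)
  a1 <- spec2(100.000, 10, precursor = 250)
  expect_equal(nrow(match_peaks(a1, b, 10)), 0L)
  # exactly 10 mDa: matched (inclusive)
  b2 <- spec2(100.010, 10, precursor = 250)
  expect_equal(nrow(match_peaks(a1, b2, 10)), 1L)
  # greedy: single peak matches the more intense of two in-window peaks
  a2 <- spec2(100.000, 50, precursor = 250)
  b3 <- spec2(c(100.004, 100.006), c(10, 40), precursor = 250)
  m3 <- match_peaks(a2, b3, 10)
  expect_equal(m3$mz_b, 100.006)
  # pair count bounded and symmetric
  set.seed(3)
  for (i in 1:10) {
    x <- random_spectrum(6); y <- random_spectrum(9)
    mxy <- match_peaks(x, y, 10); myx <- match_peaks(y, x, 10)
    expect_lte(nrow(mxy), 6L)
    expect_equal(nrow(mxy), nrow(myx))
  }
})

test_that("MSP round trip is lossless and validates records", {
  lib <- build_quasi_library()
  recs <- lib$records[1:3]
  path <- withr::local_tempfile(fileext = ".msp")
  write_msp(recs, path)
  back <- read_msp(path)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_identical(back[[i]]$name, recs[[i]]$name)
    expect_identical(format_formula(back[[i]]$formula),
                     format_formula(recs[[i]]$formula))
    expect_identical(back[[i]]$provenance, recs[[i]]$provenance)
    expect_equal(back[[i]]$spectrum$peaks$mz, recs[[i]]$spectrum$peaks$mz,
                 tolerance = 1e-6)
    expect_equal(back[[i]]$spectrum$peaks$intensity,
                 recs[[i]]$spectrum$peaks$intensity, tolerance = 1e-4)
    expect_equal(back[[i]]$spectrum$rt, recs[[i]]$spectrum$rt,
                 tolerance = 1e-4)
  }
  # corrupt the peak count: parse error naming the record
  lines <- readLines(path)
  lines[grep("^Num Peaks", lines)[1]] <-
    paste0("Num Peaks: ", n_peaks(recs[[1]]$spectrum) + 1L)
  bad <- withr::local_tempfile(fileext = ".msp")
  writeLines(lines, bad)
  expect_error(read_msp(bad), recs[[1]]$name)
})

test_that("MGF round trip is lossless and converts RT units", {
  sps <- list(spec2(c(100.1234, 150.5), c(55.5, 1), id = "q1", precursor = 200),
              spec2(120, 10, id = "q2", precursor = 260))
  sps[[1]]$rt <- 1.0
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sps, path)
  back <- read_mgf(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$peaks$mz, sps[[1]]$peaks$mz, tolerance = 1e-6)
  expect_equal(back[[1]]$rt, 1.0, tolerance = 1e-6)
  expect_true(is.na(back[[2]]$rt))
  # RTINSECONDS=60 reads as 1 minute
  writeLines(c("BEGIN IONS", "TITLE=x", "PEPMASS=200", "RTINSECONDS=60",
               "100.0 1.0", "END IONS"), path)
  expect_equal(read_mgf(path)[[1]]$rt, 1.0)
  # empty block: zero peaks with a warning
  writeLines(c("BEGIN IONS", "TITLE=y", "PEPMASS=200", "END IONS"), path)
  expect_warning(empty <- read_mgf(path), "no peaks")
  expect_equal(n_peaks(empty[[1]]), 0L)
})
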