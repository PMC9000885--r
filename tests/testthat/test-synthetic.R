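test_that("the fixture library has the stated 39-compound composition", {
  lib <- build_quasi_library()
  expect_length(lib$records, 39L)
  subs <- vapply(lib$records, function(r) r$subclass, character(1))
  expect_length(unique(subs), 12L)
  counts <- table(subs)
  expect_equal(counts[["flavone"]], 4L)
  expect_equal(counts[["flavonol"]], 6L)
  expect_equal(counts[["isoflavone"]], 9L)
  expect_equal(counts[["aurone"]], 1L)
  expect_equal(counts[["flavanone"]], 6L)
  expect_equal(counts[["chalcone"]], 2L)
  expect_equal(counts[["flavanol"]], 2L)
  expect_equal(counts[["neoflavonoid_I"]], 4L)
  expect_equal(counts[["neoflavonoid_II"]], 1L)
  expect_equal(counts[["neoflavonoid_III"]], 1L)
  expect_equal(counts[["neoflavonoid_IV"]], 2L)
  expect_equal(counts[["neoflavonoid_VIII"]], 1L)
  # the purchased standards travel by name with reference provenance
  refs <- vapply(lib$records, function(r) r$provenance, character(1))
  expect_equal(sum(refs == "reference"), 18L)
  ref_names <- vapply(lib$records[refs == "reference"],
                      function(r) r$name, character(1))
  expect_true(all(c("baicalein", "apigenin", "quercetin", "daidzein",
                    "formononetin", "naringenin", "taxifolin",
                    "dihydromyricetin") %in% ref_names))
  # reference formulas for the named standards
  by_name <- setNames(lib$records, vapply(lib$records, `[[`, "", "name"))
  expect_identical(format_formula(by_name[["daidzein"]]$formula), "C15H10O4")
  expect_identical(format_formula(by_name[["formononetin"]]$formula), "C16H12O4")
  expect_identical(format_formula(by_name[["quercetin"]]$formula), "C15H10O7")
  expect_identical(format_formula(by_name[["taxifolin"]]$formula), "C15H12O7")
})

test_that("the noise-free simulator is the identity on theoretical spectra", {
  t <- daidzein_template()
  cfg <- simulation_config(mz_jitter_mda = 0, n_decoys = 0,
                           intensity_noise = 0, rt_jitter_min = 0, seed = 1)
  sim <- simulate_spectrum(t, cfg)
  th <- theoretical_spectrum(t)
  expect_equal(sim$peaks$mz, th$peaks$mz, tolerance = 1e-12)
  expect_equal(sim$peaks$intensity, th$peaks$intensity, tolerance = 1e-12)
  expect_equal(sim$precursor_mz, th$precursor_mz, tolerance = 1e-12)
})

test_that("simulation is deterministic given the seed", {
  t <- daidzein_template()
  cfg <- simulation_config(seed = 123)
  s1 <- simulate_spectrum(t, cfg)
  s2 <- simulate_spectrum(t, cfg)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$precursor_mz, s2$precursor_mz)
  expect_error(simulation_config(), "seed is mandatory")
})

test_that("3-mDa jitter keeps diagnostic peaks inside 10 mDa almost surely", {
  t <- daidzein_template()
  th <- theoretical_spectrum(t)
  cfg <- simulation_config(mz_jitter_mda = 3, n_decoys = 0,
                           intensity_noise = 0, seed = 99)
  set.seed(cfg$seed)
  n_tot <- 0L; n_in <- 0L
  for (i in 1:1000) {
    sim <- flavotier:::.simulate_spectrum_impl(t, cfg)
    d <- abs(sim$peaks$mz - th$peaks$mz)
    n_tot <- n_tot + length(d)
    n_in <- n_in + sum(d <= 0.010)
  }
  expect_gte(n_in / n_tot, 0.99)
})

test_that("dataset simulation respects the designed evidence splits", {
  cfg <- simulation_config(seed = 7)
  ds <- simulate_dataset(40, c("1" = 0.1, "2a" = 0.4, "2b" = 0.3, "3" = 0.2),
                         cfg)
  expect_length(ds$queries, 40L)
  expect_equal(nrow(ds$ground_truth), 40L)
  gt <- ds$ground_truth
  std_names <- vapply(ds$standards, function(r) r$name, character(1))
  lib_names <- vapply(ds$library, function(r) r$name, character(1))
  cand_names <- vapply(ds$candidates, function(t) t$name, character(1))
  for (k in seq_len(nrow(gt))) {
    tn <- gt$template[k]
    switch(gt$designed_level[k],
      "1" = expect_true(tn %in% std_names),
      "2a" = {
        expect_false(tn %in% std_names)
        expect_true(tn %in% lib_names)
      },
      "2b" = {
        expect_false(tn %in% lib_names)
        expect_true(tn %in% cand_names)
      },
      "3" = {
        expect_false(tn %in% std_names)
        expect_false(tn %in% lib_names)
        expect_false(tn %in% cand_names)
      })
  }
  # all-2a mix: every generator in the library, none in standards
  ds2 <- simulate_dataset(10, c("2a" = 1), simulation_config(seed = 8))
  expect_length(ds2$standards, 0L)
  expect_true(all(ds2$ground_truth$template %in%
                  vapply(ds2$library, function(r) r$name, character(1))))
  # fixed seed reproduces the ground truth
  ds3 <- simulate_dataset(40, c("1" = 0.1, "2a" = 0.4, "2b" = 0.3, "3" = 0.2),
                          simulation_config(seed = 7))
  expect_identical(ds$ground_truth, ds3$ground_truth)
  expect_error(simulate_dataset(2, c("1" = .25, "2a" = .25, "2b" = .25,
                                     "3" = .25),
                                simulation_config(seed = 1)),
               "smaller than the number of designed levels")
})
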