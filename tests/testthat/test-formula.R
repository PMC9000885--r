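test_that("monoisotopic masses reproduce standard values", {
  expect_equal(monoisotopic_mass("H2O"), 18.0106, tolerance = 1e-4)
  expect_equal(monoisotopic_mass("CO"), 27.9949, tolerance = 1e-4)
  expect_equal(monoisotopic_mass("C16H12O4"), 268.0736, tolerance = 1e-4)
  expect_error(parse_formula("C2X5"), "unknown element")
})

test_that("formula parsing and Hill formatting round-trip", {
  for (s in c("C16H12O4", "H2O", "CO", "C8H7", "CH4", "C15H10NaO4")) {
    expect_identical(format_formula(parse_formula(s)), s)
  }
  expect_true(is_zero_formula(parse_formula("")))
  expect_identical(format_formula(chem_formula()), "")
})

test_that("formula arithmetic: addition commutes, diff guards negatives", {
  set.seed(1)
  for (i in 1:20) {
    f1 <- random_formula(); f2 <- random_formula()
    expect_true(formula_add(f1, f2) == formula_add(f2, f1))
    expect_equal(monoisotopic_mass(formula_add(f1, f2)),
                 monoisotopic_mass(f1) + monoisotopic_mass(f2),
                 tolerance = 1e-9)
  }
  big <- parse_formula("C15H12O4"); small <- parse_formula("C7H4O4")
  expect_true(is_subformula(small, big))
  expect_identical(format_formula(formula_diff(big, small)), "C8H8")
  expect_false(is_subformula(parse_formula("C8H8"), parse_formula("C7H4O4")))
  expect_error(formula_diff(small, big), "not contained")
  # zero formula is the identity and self-difference
  f <- parse_formula("C6H6")
  expect_true(is_subformula(f, f))
  expect_true(is_zero_formula(formula_diff(f, f)))
  expect_true(formula_add(f, chem_formula()) == f)
})

test_that("ion m/z applies adduct and electron-mass corrections", {
  expect_equal(ion_mz("C16H12O4", "[M+H]+"), 269.0808, tolerance = 5e-5)
  expect_equal(ion_mz("C14H9O4", "cation"), 241.0495, tolerance = 5e-5)
  expect_equal(ion_mz("C13H9O3", "cation"), 213.0546, tolerance = 5e-5)
  # proton-offset invariant over random neutrals
  set.seed(2)
  for (i in 1:20) {
    f <- formula_add(random_formula(), chem_formula(H = 1L))
    expect_equal(ion_mz(f, "[M+H]+") - monoisotopic_mass(f), 1.007276,
                 tolerance = 1e-6)
  }
  expect_equal(ion_mz(ion_spec("C15H10O4", "[2M+H]+")),
               2 * monoisotopic_mass("C15H10O4") + 1.007276,
               tolerance = 1e-6)
  expect_error(ion_spec("C6H6", "[M+K]+"), "unsupported adduct")
})

test_that("ion strings parse bit-exactly", {
  i1 <- parse_ion("[C16H13O4]+")
  expect_identical(i1$adduct, "cation")
  expect_identical(format(i1), "[C16H13O4]+")
  i2 <- parse_ion("[M+Na]+", neutral = "C15H10O4")
  expect_identical(format(i2), "[M+Na]+")
  expect_error(parse_ion("[M+H]+"), "neutral formula")
  expect_error(parse_ion("M+H"), "cannot parse")
})

test_that("mass errors follow the observed-minus-theoretical convention", {
  e <- mass_error(269.0806, 269.0808)
  expect_equal(e$mda, -0.2, tolerance = 1e-6)
  e2 <- mass_error(269.0794, 269.0808)
  expect_equal(e2$mda, -1.4, tolerance = 1e-6)
  expect_equal(mass_error(100, 100)$mda, 0)
  expect_equal(mass_error(100, 100)$ppm, 0)
})

test_that("RDBE counts rings plus double bonds for CHO(Na) formulas", {
  expect_equal(rdbe("CH4"), 0)
  expect_equal(rdbe("C6H6"), 4)
  expect_equal(rdbe("C15H10O4"), 11)
  expect_equal(rdbe("C15H9O4Na"), 11)  # Na counted like H
})

test_that("decomposition finds the expected top candidates", {
  d <- decompose_mass(269.0808, "[M+H]+", 5, c(C = 30, H = 40, O = 10))
  expect_identical(d$formula[1], "C16H12O4")
  d2 <- decompose_mass(18.0106, "neutral", 5, c(C = 5, H = 10, O = 3))
  expect_identical(d2$formula[1], "H2O")
  d3 <- decompose_mass(103.0542, "cation", 5, c(C = 20, H = 30, O = 8))
  expect_true("C8H7" %in% d3$formula)
  # empty result is a valid return
  d4 <- decompose_mass(1.5, "neutral", 1, c(C = 3, H = 3, O = 3))
  expect_equal(nrow(d4), 0L)
})

test_that("decomposition agrees with the brute-force oracle", {
  set.seed(7)
  targets <- runif(50, 80, 320)
  for (tg in targets) {
    got <- decompose_mass(tg, "[M+H]+", 5, c(C = 20, H = 30, O = 8))
    expect_identical(sort(got$formula), brute_force_decompose(tg, 5, 20, 30, 8))
    # every candidate re-evaluates inside the tolerance
    if (nrow(got) > 0) {
      remz <- vapply(got$formula, function(f) ion_mz(f, "[M+H]+"), numeric(1))
      expect_true(all(abs(remz - tg) <= 5e-3 + 1e-12))
    }
  }
})
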