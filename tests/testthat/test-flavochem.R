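test_that("the registry holds 12 skeletons with conserving cleavages", {
  reg <- skeleton_registry()
  expect_length(reg, 12L)
  expect_setequal(names(reg), subclass_ids())
  for (id in names(reg)) {
    sk <- reg[[id]]
    for (lab in names(sk$cleavages)) {
      cl <- sk$cleavages[[lab]]
      expect_true(formula_add(parse_formula(cl$part_a),
                              parse_formula(cl$part_b)) ==
                  sk$scaffold_formula,
                  label = paste(id, lab, "conservation"))
    }
  }
})

test_that("compound formulas are scaffold plus substituent deltas", {
  expect_identical(format_formula(compound_formula(daidzein_template())),
                   "C15H10O4")
  api <- compound_template("apigenin", "flavone",
                           ringA = c(oh = 2), ringB = c(oh = 1))
  expect_identical(format_formula(compound_formula(api)), "C15H10O5")
  bare <- compound_template("flavone", "flavone")
  expect_identical(format_formula(compound_formula(bare)), "C15H10O2")
  expect_error(compound_template("x", "not-a-skeleton"), "unknown skeleton")
  expect_error(compound_template("x", "flavone", ringA = c(xx = 1)),
               "unknown substituent")
})

test_that("RDA fragments reproduce the printed diagnostic ions", {
  d <- rda_fragment_ions(daidzein_template(), "1,3")
  expect_identical(d$cation, c("C7H5O3", "C8H7O"))
  expect_equal(d$mz, c(137.0233, 119.0491), tolerance = 5e-5)
  # the 2-decimal rounding matches the printed pair exactly
  expect_identical(sprintf("%.2f", d$mz), c("137.02", "119.05"))

  f <- rda_fragment_ions(dihydroxyflavanone_template(), "1,3")
  expect_equal(f$mz[f$part == "a"], 153.0182, tolerance = 5e-5)
  expect_identical(f$neutral_part[f$part == "b"], "C8H8")
  expect_equal(f$mz[f$part == "b"], 103.0542, tolerance = 5e-5)

  expect_error(rda_fragment_ions(daidzein_template(), "9,9"), "valid labels")
})

test_that("cleavage parts always sum to the compound formula", {
  lib <- build_quasi_library()
  for (t in lib$templates) {
    reg <- skeleton_registry()[[t$skeleton]]
    for (lab in names(reg$cleavages)) {
      parts <- flavotier:::.cleavage_parts(t, lab)
      expect_true(formula_add(parts$a$formula, parts$b$formula) ==
                  compound_formula(t),
                  label = paste(t$name, lab, "decorated conservation"))
    }
  }
})

test_that("moving a hydroxyl between rings shifts the RDA pair by one O", {
  tA <- compound_template("a", "isoflavone", ringA = c(oh = 1))
  tB <- compound_template("b", "isoflavone", ringB = c(oh = 1))
  fa <- rda_fragment_ions(tA, "1,3"); fb <- rda_fragment_ions(tB, "1,3")
  o <- 15.9949
  expect_equal(fb$mz[fb$part == "a"], fa$mz[fa$part == "a"] - o,
               tolerance = 1e-4)
  expect_equal(fb$mz[fb$part == "b"], fa$mz[fa$part == "b"] + o,
               tolerance = 1e-4)
})

test_that("loss series walks the CO ladder and prunes infeasible branches", {
  s <- loss_series("C15H9O5", list("CO"), depth = 2)
  expect_equal(sort(s$mz, decreasing = TRUE),
               c(269.0444, 241.0495, 213.0546), tolerance = 5e-5)
  expect_identical(s$label[s$n_losses == 2], "[M-2CO+H]+")
  s0 <- loss_series("C15H9O5", list("CO"), depth = 0)
  expect_equal(nrow(s0), 1L)
  # H2O loss from an oxygen-poor cation prunes silently
  s2 <- loss_series("C7H5O", list("H2O", "CO"), depth = 2)
  expect_false(any(grepl("2H2O", s2$label)))
})

test_that("theoretical spectra obey the subclass base-peak conventions", {
  # flavanone: 1,3A base peak carrying >= 40% of fragment intensity
  fl <- theoretical_spectrum(dihydroxyflavanone_template())
  ions <- fl$metadata$ions
  base <- ions[ions$role == "base", ]
  expect_equal(base_peak_mz(fl), base$mz, tolerance = 1e-9)
  frag <- fl$peaks$intensity[abs(fl$peaks$mz - fl$precursor_mz) > 1e-6]
  expect_gte(max(fl$peaks$intensity) / sum(frag), 0.4)

  # flavonol: 1,3A base peak and a water-loss ion present
  fo <- theoretical_spectrum(
    compound_template("galangin", "flavonol", ringA = c(oh = 2)))
  expect_true(any(fo$metadata$ions$label == "[M-H2O+H]+"))
  expect_identical(fo$metadata$ions$label[
    which.min(abs(fo$metadata$ions$mz - base_peak_mz(fo)))], "[1,3A+H]+")

  # aurone: radical 1,3B base peak
  au <- theoretical_spectrum(
    compound_template("a", "aurone", ringA = c(oh = 1), ringB = c(oh = 1)))
  bi <- au$metadata$ions[au$metadata$ions$role == "base", ]
  expect_identical(bi$parity, "radical")
  expect_equal(base_peak_mz(au), bi$mz, tolerance = 1e-9)

  # every emitted ion is a subformula of the precursor cation
  lib <- build_quasi_library()
  for (t in lib$templates[c("daidzein", "quercetin", "taxifolin",
                            "medicarpin-like")]) {
    sp <- theoretical_spectrum(t)
    prec <- formula_add(compound_formula(t), chem_formula(H = 1L))
    for (f in sp$metadata$ions$cation)
      expect_true(is_subformula(parse_formula(f), prec),
                  label = paste(t$name, f))
  }
})

test_that("complementary pairs are recognized across all three branches", {
  # apigenin 1,3 pair: H-transfer branch
  expect_true(complementary_pair_check(153.0182, 119.0491, 271.0601, 10))
  expect_false(complementary_pair_check(100, 100, 300, 10))
  # radical split branch (aurone-type pair)
  expect_true(complementary_pair_check(137.0233, 134.0362, 271.0601, 10))
  # H-transfer with an identical peak passed twice
  expect_true(complementary_pair_check(100, 100, 2 * 100 - 1.0078, 10))
  # methyl-loss branch
  expect_true(complementary_pair_check(120, 100, 220 - 1.0078 + 15.0235, 10))
})
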