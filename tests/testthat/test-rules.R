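test_that("a noise-free theoretical spectrum verifies against its template", {
  t <- daidzein_template()
  v <- verify_annotation(theoretical_spectrum(t), t, 10)
  expect_true(v$pass)
  expect_equal(v$explained_fraction, 1.0, tolerance = 1e-12)
  expect_error(verify_annotation(ms_spectrum("e", 100, NULL), t), "empty")
})

test_that("a same-mass template of the wrong subclass fails verification", {
  # daidzein (isoflavone, C15H10O4) against a flavanone template: the
  # flavanone 1,3 ions and base-share condition cannot be satisfied
  dz_spec <- theoretical_spectrum(daidzein_template())
  fl <- compound_template("flavanone-c15h10o4-imposter", "flavanone",
                          ringA = c(oh = 1), ringB = c(oh = 1))
  # formulas differ by H2 so the decorated ions cannot all line up
  v <- verify_annotation(dz_spec, fl, 10)
  expect_false(v$pass)
})

test_that("the flavanone 40% base-share condition is enforced", {
  t <- dihydroxyflavanone_template()
  sp <- theoretical_spectrum(t)
  v <- verify_annotation(sp, t, 10)
  expect_true(v$pass)
  expect_gte(v$base_share, 0.4)
  # dilute the base ion below 40% of fragment intensity: rule must fail
  sp2 <- sp
  base_i <- which.max(sp2$peaks$intensity)
  sp2$peaks$intensity[base_i] <- 35   # other fragments sum to ~90
  v2 <- verify_annotation(sp2, t, 10)
  expect_false(v2$pass)
  expect_false(v2$share_ok)
})

test_that("noise-free classification recovers all 39 fixture subclasses", {
  lib <- build_quasi_library()
  for (t in lib$templates) {
    cls <- classify_spectrum(theoretical_spectrum(t), compound_formula(t), 10)
    expect_gt(nrow(cls$ranking), 0, label = t$name)
    expect_identical(subclass_equivalence(cls$ranking$subclass[1]),
                     subclass_equivalence(t$skeleton), label = t$name)
  }
})

test_that("flavanones and chalcones tie as one equivalence class", {
  t <- compound_template("liquiritigenin", "flavanone",
                         ringA = c(oh = 1), ringB = c(oh = 1))
  cls <- classify_spectrum(theoretical_spectrum(t), compound_formula(t), 10)
  top2 <- cls$ranking[1:2, ]
  expect_setequal(top2$subclass, c("flavanone", "chalcone"))
  expect_equal(top2$explained_intensity[1], top2$explained_intensity[2],
               tolerance = 1e-12)
  expect_identical(unique(subclass_equivalence(top2$subclass)),
                   "flavanone/chalcone")
})

test_that("pure decoy spectra yield an empty ranking with reasons", {
  sp <- ms_spectrum("decoys", ion_mz("C15H10O4", "[M+H]+"),
                    data.frame(mz = c(81.111, 97.222, 123.333),
                               intensity = c(10, 20, 30)))
  cls <- classify_spectrum(sp, "C15H10O4", 10)
  expect_equal(nrow(cls$ranking), 0L)
  expect_gt(nrow(cls$failures), 0L)
})

test_that("decoy peaks never flip a mandatory-diagnostic fail to a pass", {
  dz_spec <- theoretical_spectrum(daidzein_template())
  wrong <- compound_template("wrong-flavonol", "flavonol",
                             ringA = c(oh = 1))
  set.seed(9)
  v0 <- verify_annotation(dz_spec, wrong, 10)
  expect_false(v0$mandatory_ok)
  for (i in 1:20) {
    sp2 <- dz_spec
    decoys <- data.frame(mz = runif(5, 60, 180), intensity = rep(5, 5))
    # keep decoys away from the expected diagnostic windows
    ions <- flavotier:::.diagnostic_ions(wrong)
    decoys <- decoys[vapply(decoys$mz, function(m)
      all(abs(ions$mz - m) > 0.05), logical(1)), , drop = FALSE]
    sp2$peaks <- rbind(sp2$peaks, decoys)
    sp2 <- ms_spectrum(sp2$id, sp2$precursor_mz, sp2$peaks)
    v <- verify_annotation(sp2, wrong, 10)
    expect_false(v$mandatory_ok)
    expect_lte(v$explained_fraction, v0$explained_fraction + 1e-12)
  }
})
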