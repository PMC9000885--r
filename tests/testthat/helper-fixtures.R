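# Shared builders for the test suite. All fixtures are generated in code.

spec2 <- function(mz, intensity, id = "s", precursor = max(mz) + 1) {
  ms_spectrum(id, precursor, data.frame(mz = mz, intensity = intensity))
}

daidzein_template <- function() {
  compound_template("daidzein", "isoflavone",
                    ringA = c(oh = 1), ringB = c(oh = 1))
}

dihydroxyflavanone_template <- function() {
  compound_template("5,7-dihydroxyflavanone", "flavanone", ringA = c(oh = 2))
}

# Independent brute-force oracle for CHO formula decomposition: a plain
# triple loop with no shared code with decompose_mass().
brute_force_decompose <- function(target, tol_mda, cmax, hmax, omax,
                                  proton = 1.00782503207 - 5.48579909e-4) {
  em <- c(C = 12, H = 1.00782503207, O = 15.99491461956)
  hits <- character()
  for (C in 0:cmax) for (H in 0:hmax) for (O in 0:omax) {
    if (C + H + O == 0) next
    mz <- C * em["C"] + H * em["H"] + O * em["O"] + proton
    if (abs(mz - target) * 1000 > tol_mda) next
    deg <- C - H / 2 + 1
    if (deg < 0 || deg > 25 || H > 2 * C + 2) next
    hits <- c(hits, paste0(
      if (C > 0) paste0("C", if (C > 1) C else "") else "",
      if (H > 0) paste0("H", if (H > 1) H else "") else "",
      if (O > 0) paste0("O", if (O > 1) O else "") else ""))
  }
  sort(hits)
}

random_formula <- function() {
  chem_formula(C = sample(0:20, 1), H = sample(0:30, 1), O = sample(0:8, 1))
}

random_spectrum <- function(n = 8, id = "r") {
  mz <- sort(runif(n, 60, 290))
  ms_spectrum(id, 300, data.frame(mz = mz, intensity = runif(n, 1, 100)))
}
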