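# Subclass rule engine: the result-validation stage. A rule passes when all
# mandatory diagnostic ions of the template match peaks, the designated base
# ion is the spectrum's base peak, and (where the subclass convention states
# one) the base ion carries the required share of total fragment intensity.

.nearest_peak <- function(peaks, mz, tol_mda) {
  if (nrow(peaks) == 0L) return(NA_integer_)
  d <- abs(peaks$mz - mz)
  i <- which.min(d)
  if (d[i] <= tol_mda / 1000 + 1e-9) i else NA_integer_
}

#' Verify a spectrum against a compound template's subclass rule
#'
#' Matches the template's expected diagnostic ions against the (normalized)
#' spectrum and evaluates the subclass rule: every mandatory ion must match a
#' peak, the base-peak ion must be the most intense peak, and any
#' fragment-intensity share condition must hold. The explained-intensity
#' fraction (matched peak intensity over total) is reported for ranking and
#' does not gate the verdict.
#'
#' @param spectrum an [ms_spectrum()] with at least one peak.
#' @param t a [compound_template()].
#' @param tol_mda match tolerance in mDa.
#' @return A `rule_verdict`: list with `subclass`, `template`, `pass`,
#'   `mandatory_ok`, `base_ok`, `share_ok`, `explained_fraction`, `reason`
#'   and a per-diagnostic `details` data.frame.
#' @export
verify_annotation <- function(spectrum, t, tol_mda = 10) {
  if (n_peaks(spectrum) == 0L)
    stop("verify_annotation: empty spectrum")
  sp <- normalize_spectrum(spectrum)
  peaks <- sp$peaks
  ions <- .diagnostic_ions(t)
  sk <- skeleton_registry()[[t$skeleton]]
  rule <- sk$rule

  # an annotation whose molecular formula contradicts the precursor m/z
  # cannot be verified, whatever its fragments happen to hit
  prec_th <- ion_mz(compound_formula(t), "[M+H]+")
  if (abs(prec_th - sp$precursor_mz) > tol_mda / 1000 + 1e-9) {
    details <- data.frame(
      label = ions$label, expected_mz = ions$mz, role = ions$role,
      matched = FALSE, observed_mz = NA_real_, error_mda = NA_real_,
      observed_intensity = NA_real_, stringsAsFactors = FALSE)
    return(structure(list(
      subclass = t$skeleton, template = t, pass = FALSE,
      mandatory_ok = FALSE, base_ok = FALSE, share_ok = FALSE,
      base_share = NA_real_, explained_fraction = 0,
      reason = sprintf("precursor mismatch: template [M+H]+ %.4f vs %.4f",
                       prec_th, sp$precursor_mz),
      details = details), class = "rule_verdict"))
  }

  idx <- vapply(ions$mz, function(m) .nearest_peak(peaks, m, tol_mda),
                integer(1))
  details <- data.frame(
    label = ions$label, expected_mz = ions$mz, role = ions$role,
    matched = !is.na(idx),
    observed_mz = ifelse(is.na(idx), NA_real_, peaks$mz[idx]),
    error_mda = ifelse(is.na(idx), NA_real_,
                       1000 * (peaks$mz[idx] - ions$mz)),
    observed_intensity = ifelse(is.na(idx), NA_real_, peaks$intensity[idx]),
    stringsAsFactors = FALSE)

  mandatory_ok <- all(details$matched[details$role == "mandatory"])

  base_i <- which(ions$role == "base")
  base_ok <- TRUE
  if (length(base_i) == 1L) {
    bp <- base_peak_mz(sp)
    base_ok <- details$matched[base_i] &&
      abs(bp - details$observed_mz[base_i]) < 1e-9
  }

  share_ok <- TRUE
  share <- NA_real_
  if (!is.null(rule$base_share_min) && length(base_i) == 1L) {
    # fragment intensity excludes the precursor peak
    prec_idx <- .nearest_peak(peaks, sp$precursor_mz, tol_mda)
    frag_int <- peaks$intensity
    if (!is.na(prec_idx)) frag_int <- frag_int[-prec_idx]
    share <- if (details$matched[base_i] && sum(frag_int) > 0)
      details$observed_intensity[base_i] / sum(frag_int) else 0
    share_ok <- share >= rule$base_share_min
  }

  explained <- sum(peaks$intensity[unique(idx[!is.na(idx)])]) /
    sum(peaks$intensity)

  pass <- mandatory_ok && base_ok && share_ok
  reason <- if (pass) "pass" else paste(c(
    if (!mandatory_ok) paste0(
      "missing mandatory ion(s): ",
      paste(details$label[details$role == "mandatory" & !details$matched],
            collapse = ", ")),
    if (!base_ok) paste0("base-peak condition failed (expected ",
                         ions$label[base_i], ")"),
    if (!share_ok) sprintf("base ion share %.2f below %.2f", share,
                           rule$base_share_min)),
    collapse = "; ")

  structure(list(subclass = t$skeleton, template = t, pass = pass,
                 mandatory_ok = mandatory_ok, base_ok = base_ok,
                 share_ok = share_ok, base_share = share,
                 explained_fraction = explained, reason = reason,
                 details = details),
            class = "rule_verdict")
}

#' @export
print.rule_verdict <- function(x, ...) {
  cat(sprintf("<rule_verdict> %s (%s): %s  explained %.2f\n", x$subclass,
              x$template$name, if (x$pass) "PASS" else "FAIL",
              x$explained_fraction))
  if (!x$pass) cat("  ", x$reason, "\n")
  invisible(x)
}

# Enumerate substituent placements of a neutral formula on a skeleton:
# the formula excess over the scaffold must decompose as a*OH + b*OMe + c*Me,
# distributed over rings A and B with at most max_o O-bearing substituents
# per ring.
.enumerate_placements <- function(formula, skeleton, max_o = 3L) {
  sk <- skeleton_registry()[[skeleton]]
  dv <- .as_formula_vec(formula) - .as_formula_vec(sk$scaffold_formula)
  if (any(dv < 0) || dv[4] != 0L) return(list())
  dC <- dv[1]; dH <- dv[2]; dO <- dv[3]
  if (dH != 2 * dC) return(list())     # OMe and Me each add exactly 2 H
  out <- list()
  for (b in 0:min(dC, dO)) {           # b methoxyls
    cc <- dC - b                       # c methyls
    a <- dO - b                        # a hydroxyls
    if (a < 0) next
    for (aA in 0:a) for (bA in 0:b) for (cA in 0:cc) {
      if (aA + bA > max_o || (a - aA) + (b - bA) > max_o) next
      ringA <- c(oh = aA, ome = bA, me = cA)
      ringB <- c(oh = a - aA, ome = b - bA, me = cc - cA)
      out[[length(out) + 1L]] <- list(ringA = ringA[ringA > 0],
                                      ringB = ringB[ringB > 0])
    }
  }
  out
}

#' Classify a spectrum into flavonoid subclasses
#'
#' For each of the 12 subclasses, enumerates substituent placements
#' consistent with the precursor formula (hydroxyl/methoxyl/methyl over rings
#' A and B, at most 3 O-bearing substituents per ring), verifies each against
#' the spectrum and keeps the best verdict. Passing subclasses are ranked by
#' explained-intensity fraction; flavanones and chalcones have identical
#' cleavage conventions and appear as a tied pair when both pass.
#'
#' @param spectrum an [ms_spectrum()].
#' @param precursor_formula neutral formula consistent with the precursor
#'   m/z within `tol_mda` (checked).
#' @param tol_mda match tolerance in mDa.
#' @return List with `ranking` (data.frame: subclass, explained_intensity,
#'   template name; passing subclasses only, best first) and `failures`
#'   (data.frame: subclass, reason).
#' @export
classify_spectrum <- function(spectrum, precursor_formula, tol_mda = 10) {
  if (is.character(precursor_formula))
    precursor_formula <- parse_formula(precursor_formula)
  th <- ion_mz(precursor_formula, "[M+H]+")
  if (abs(th - spectrum$precursor_mz) > tol_mda / 1000)
    stop(sprintf(
      "precursor formula %s ([M+H]+ %.4f) inconsistent with precursor m/z %.4f",
      format_formula(precursor_formula), th, spectrum$precursor_mz))
  rank_rows <- list(); fail_rows <- list()
  for (sub in subclass_ids()) {
    placements <- .enumerate_placements(precursor_formula, sub)
    if (length(placements) == 0L) {
      fail_rows[[sub]] <- data.frame(
        subclass = sub, reason = "formula incompatible with scaffold",
        stringsAsFactors = FALSE)
      next
    }
    best <- NULL
    for (pl in placements) {
      t <- compound_template(paste0(sub, "-candidate"), sub,
                             ringA = pl$ringA, ringB = pl$ringB)
      v <- verify_annotation(spectrum, t, tol_mda)
      if (is.null(best) ||
          (v$pass && !best$pass) ||
          (v$pass == best$pass &&
           v$explained_fraction > best$explained_fraction))
        best <- v
    }
    if (best$pass) {
      rank_rows[[sub]] <- data.frame(
        subclass = sub, explained_intensity = best$explained_fraction,
        template = best$template$name, stringsAsFactors = FALSE)
    } else {
      fail_rows[[sub]] <- data.frame(subclass = sub, reason = best$reason,
                                     stringsAsFactors = FALSE)
    }
  }
  ranking <- if (length(rank_rows))
    do.call(rbind, rank_rows) else
    data.frame(subclass = character(), explained_intensity = numeric(),
               template = character(), stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$explained_intensity, ranking$subclass), ,
                     drop = FALSE]
  rownames(ranking) <- NULL
  failures <- if (length(fail_rows)) do.call(rbind, fail_rows) else
    data.frame(subclass = character(), reason = character())
  rownames(failures) <- NULL
  list(ranking = ranking, failures = failures)
}

#' Collapse a subclass to its MS/MS-distinguishability class
#'
#' Flavanones and chalcones produce the same diagnostic fragments under the
#' encoded conventions and cannot be told apart by MS/MS alone; both map to
#' `"flavanone/chalcone"`.
#'
#' @param subclass subclass id(s).
#' @return Character vector of equivalence-class labels.
#' @export
subclass_equivalence <- function(subclass) {
  ifelse(subclass %in% c("flavanone", "chalcone"), "flavanone/chalcone",
         subclass)
}
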