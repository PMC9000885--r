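#' Construct an MS/MS spectrum
#'
#' A spectrum is a precursor description plus a peak table. Peaks are kept
#' sorted by ascending m/z. Fragment m/z above `precursor_mz + 0.5` is
#' rejected (guard against isotope spillover past the precursor).
#'
#' @param id identifier string.
#' @param precursor_mz precursor m/z (Th).
#' @param peaks data.frame (or 2-column matrix) with columns `mz` and
#'   `intensity`; may have zero rows.
#' @param adduct adduct label, default `"[M+H]+"`.
#' @param rt retention time in minutes, or `NA` when unknown.
#' @param metadata named list of free-form metadata.
#' @return Object of class `ms_spectrum`.
#' @export
ms_spectrum <- function(id, precursor_mz, peaks,
                        adduct = "[M+H]+", rt = NA_real_,
                        metadata = list()) {
  if (is.matrix(peaks)) peaks <- data.frame(mz = peaks[, 1], intensity = peaks[, 2])
  if (is.null(peaks) || nrow(peaks) == 0L) {
    peaks <- data.frame(mz = numeric(), intensity = numeric())
  } else {
    stopifnot(all(c("mz", "intensity") %in% names(peaks)))
    peaks <- data.frame(mz = as.numeric(peaks$mz),
                        intensity = as.numeric(peaks$intensity))
    if (any(!is.finite(peaks$mz)) || any(!is.finite(peaks$intensity)))
      stop("spectrum '", id, "': non-finite peak values")
    if (any(peaks$mz <= 0) || any(peaks$intensity < 0))
      stop("spectrum '", id, "': peak m/z must be > 0 and intensity >= 0")
    if (any(peaks$mz > precursor_mz + 0.5))
      stop("spectrum '", id, "': peak m/z above precursor + 0.5")
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  stopifnot(is.numeric(precursor_mz), precursor_mz > 0)
  structure(list(id = as.character(id), precursor_mz = precursor_mz,
                 adduct = adduct, rt = rt, mode = "positive",
                 peaks = peaks, metadata = metadata),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum> %s  precursor %.4f %s  %d peaks%s\n",
              x$id, x$precursor_mz, x$adduct, nrow(x$peaks),
              if (is.na(x$rt)) "" else sprintf("  RT %.2f min", x$rt)))
  invisible(x)
}

#' Number of peaks in a spectrum
#' @param x an [ms_spectrum()].
#' @export
n_peaks <- function(x) nrow(x$peaks)

#' Normalize a spectrum to relative intensities
#'
#' Scales intensities so the base peak is 100. Idempotent and
#' scale-invariant; peak order is preserved.
#'
#' @param spectrum an [ms_spectrum()] with at least one nonzero-intensity peak.
#' @return The spectrum with relative intensities.
#' @export
normalize_spectrum <- function(spectrum) {
  p <- spectrum$peaks
  if (nrow(p) == 0L || all(p$intensity == 0))
    stop("cannot normalize spectrum '", spectrum$id,
         "': no peak with positive intensity")
  spectrum$peaks$intensity <- 100 * p$intensity / max(p$intensity)
  spectrum
}

#' Base peak of a spectrum
#'
#' @param spectrum an [ms_spectrum()].
#' @return m/z of the most intense peak (first by m/z on exact ties).
#' @export
base_peak_mz <- function(spectrum) {
  p <- spectrum$peaks
  if (nrow(p) == 0L) return(NA_real_)
  p$mz[which.max(p$intensity)]
}

#' Match peaks between two spectra
#'
#' Greedy one-to-one assignment: candidate pairs within `tol_mda` are taken in
#' order of decreasing intensity product (ties broken by smaller m/z
#' difference, then by m/z), each peak used at most once. The tolerance is
#' absolute mDa and inclusive.
#'
#' @param a,b [ms_spectrum()] objects.
#' @param tol_mda match tolerance in mDa (> 0), default 10.
#' @return data.frame with columns `idx_a`, `idx_b`, `mz_a`, `mz_b`,
#'   `intensity_a`, `intensity_b`, `delta_mda`.
#' @export
match_peaks <- function(a, b, tol_mda = 10) {
  stopifnot(tol_mda > 0)
  pa <- a$peaks; pb <- b$peaks
  empty <- data.frame(idx_a = integer(), idx_b = integer(),
                      mz_a = numeric(), mz_b = numeric(),
                      intensity_a = numeric(), intensity_b = numeric(),
                      delta_mda = numeric())
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(empty)
  tol <- tol_mda / 1000 + 1e-9   # inclusive boundary, robust to fp rounding
  cand <- expand.grid(idx_a = seq_len(nrow(pa)), idx_b = seq_len(nrow(pb)))
  d <- abs(pa$mz[cand$idx_a] - pb$mz[cand$idx_b])
  cand <- cand[d <= tol, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  prod <- pa$intensity[cand$idx_a] * pb$intensity[cand$idx_b]
  dd <- abs(pa$mz[cand$idx_a] - pb$mz[cand$idx_b])
  cand <- cand[order(-prod, dd, pa$mz[cand$idx_a]), , drop = FALSE]
  used_a <- logical(nrow(pa)); used_b <- logical(nrow(pb))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ia <- cand$idx_a[i]; ib <- cand$idx_b[i]
    if (!used_a[ia] && !used_b[ib]) {
      keep[i] <- TRUE; used_a[ia] <- TRUE; used_b[ib] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(
    idx_a = cand$idx_a, idx_b = cand$idx_b,
    mz_a = pa$mz[cand$idx_a], mz_b = pb$mz[cand$idx_b],
    intensity_a = pa$intensity[cand$idx_a],
    intensity_b = pb$intensity[cand$idx_b],
    delta_mda = 1000 * (pa$mz[cand$idx_a] - pb$mz[cand$idx_b])
  )
  out <- out[order(out$mz_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Library record: a spectrum with compound identity
#'
#' @param spectrum an [ms_spectrum()].
#' @param name compound name.
#' @param formula neutral formula ([chem_formula()] or Hill string); mandatory
#'   for reference and quasi-reference provenance.
#' @param subclass optional flavonoid subclass label.
#' @param provenance one of `"reference"`, `"quasi-reference-2a"`,
#'   `"quasi-reference-mzCloud"`, `"synthetic"`.
#' @return Object of class `library_record`.
#' @export
library_record <- function(spectrum, name, formula = NULL, subclass = NA_character_,
                           provenance = "synthetic") {
  provs <- c("reference", "quasi-reference-2a", "quasi-reference-mzCloud",
             "synthetic")
  if (!provenance %in% provs)
    stop("unknown provenance '", provenance, "'")
  if (is.character(formula)) formula <- parse_formula(formula)
  if (is.null(formula) && provenance != "synthetic")
    stop("library record '", name, "': formula required for ", provenance,
         " provenance")
  structure(list(spectrum = spectrum, name = name, formula = formula,
                 subclass = subclass, provenance = provenance),
            class = "library_record")
}

#' @export
print.library_record <- function(x, ...) {
  cat(sprintf("<library_record> %s (%s, %s)\n", x$name,
              if (is.null(x$formula)) "?" else format_formula(x$formula),
              x$provenance))
  print(x$spectrum)
  invisible(x)
}
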