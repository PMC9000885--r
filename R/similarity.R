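# Level-2a spectral similarity. Scores live on [0, 1] internally and are
# reported as percentages, matching the 0-100 scale on which the library
# search cutoff (80) is expressed.

.similarity_score <- function(value, method) {
  value <- min(max(value, 0), 1)  # clamp fp noise at the boundaries
  structure(list(value = value, percent = 100 * value, method = method),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("<similarity_score> %s: %.2f%%\n", x$method, x$percent))
  invisible(x)
}

#' Normalized dot-product (cosine) spectral similarity
#'
#' Peaks are aligned with [match_peaks()]; the score is the normalized dot
#' product over the full peak vectors, with unmatched peaks contributing zero
#' to the numerator:
#' sum(Ia * Ib over matched pairs) / sqrt(sum(Ia^2) * sum(Ib^2)).
#' Raw intensities are used (no m/z weighting); the score is invariant to
#' global intensity scaling of either spectrum.
#'
#' @param a,b non-empty [ms_spectrum()] objects.
#' @param tol_mda peak match tolerance in mDa.
#' @return A `similarity_score` with fields `value`, `percent`, `method`.
#' @export
cosine_score <- function(a, b, tol_mda = 10) {
  if (n_peaks(a) == 0L || n_peaks(b) == 0L)
    stop("cosine_score: empty spectrum")
  m <- match_peaks(a, b, tol_mda)
  num <- sum(m$intensity_a * m$intensity_b)
  den <- sqrt(sum(a$peaks$intensity^2) * sum(b$peaks$intensity^2))
  .similarity_score(if (den == 0) 0 else num / den, "dot_product")
}

.shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Spectral-entropy similarity
#'
#' Intensities of each spectrum are normalized to sum 1; with S the Shannon
#' entropy (natural log) and the merged spectrum the peak-aligned average of
#' the two, the score is `1 - (2 * S_merged - S_a - S_b) / log(4)`. Identical
#' spectra score 1; single peaks at disjoint m/z score 0.
#'
#' @inheritParams cosine_score
#' @return A `similarity_score`.
#' @export
entropy_score <- function(a, b, tol_mda = 10) {
  if (n_peaks(a) == 0L || n_peaks(b) == 0L)
    stop("entropy_score: empty spectrum")
  pa <- a$peaks$intensity / sum(a$peaks$intensity)
  pb <- b$peaks$intensity / sum(b$peaks$intensity)
  m <- match_peaks(a, b, tol_mda)
  merged <- c(
    (pa[m$idx_a] + pb[m$idx_b]) / 2,                     # aligned peaks
    pa[setdiff(seq_along(pa), m$idx_a)] / 2,             # only in a
    pb[setdiff(seq_along(pb), m$idx_b)] / 2)             # only in b
  s_a <- .shannon(pa); s_b <- .shannon(pb); s_m <- .shannon(merged)
  .similarity_score(1 - (2 * s_m - s_a - s_b) / log(4), "entropy")
}

#' Library-hit decision against a percentage cutoff
#'
#' The comparison is inclusive: a score exactly at the cutoff is a hit
#' ("cutoff, 80" is read as a pass mark).
#'
#' @param score a `similarity_score` (or numeric percent).
#' @param cutoff_percent cutoff in `[0, 100]`, default 80.
#' @return Logical scalar.
#' @export
is_hit <- function(score, cutoff_percent = 80) {
  stopifnot(cutoff_percent >= 0, cutoff_percent <= 100)
  pct <- if (inherits(score, "similarity_score")) score$percent else score
  pct >= cutoff_percent
}
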