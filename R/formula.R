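#' @importFrom stats rnorm runif setNames
#' @importFrom utils modifyList write.table read.table
NULL

# Monoisotopic masses (Da), CODATA-consistent values used throughout the
# package. The table is deliberately small: positive-mode flavonoid work
# only ever needs C, H, O and the sodium adduct.
.ELEMENT_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  O  = 15.99491461956,
  Na = 22.9897692809
)

#' Mass of the electron in Dalton
#'
#' Singly charged cations are lighter than their neutral atom inventory by one
#' electron mass; all m/z values in the package subtract it.
#' @export
ELECTRON_MASS <- 5.48579909e-4

# Proton mass = H atom minus its electron; what a protonating adduct adds.
.PROTON_MASS <- 1.00782503207 - 5.48579909e-4

#' Monoisotopic element mass table
#'
#' @return Named numeric vector of monoisotopic masses (Da) for the supported
#'   elements (C, H, O, Na).
#' @export
element_masses <- function() .ELEMENT_MASS

#' Construct an elemental formula
#'
#' A `chem_formula` is a named integer vector of non-negative element counts
#' over C, H, O and Na. The all-zero formula is a valid object: it is the
#' identity of [formula_add()] and the self-difference of any formula, which
#' keeps fragmentation-tree roots and zero losses representable.
#'
#' @param C,H,O,Na non-negative integer element counts.
#' @return Object of class `chem_formula`.
#' @examples
#' chem_formula(C = 16, H = 12, O = 4)  # formononetin
#' @export
chem_formula <- function(C = 0L, H = 0L, O = 0L, Na = 0L) {
  counts <- c(C = C, H = H, O = O, Na = Na)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("element counts must be non-negative integers")
  structure(as.integer(counts), names = names(.ELEMENT_MASS),
            class = "chem_formula")
}

.as_formula_vec <- function(f) {
  if (!inherits(f, "chem_formula")) stop("expected a chem_formula")
  as.integer(f)
}

#' Parse a Hill-order formula string
#'
#' Accepts strings such as `"C16H12O4"`, `"H2O"`, `"CO"` or `"C7H5O3"`.
#' Element symbols outside C/H/O/Na are a hard error.
#'
#' @param x character scalar.
#' @return A [chem_formula()].
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- gsub("\\s", "", x)
  if (s == "" || s == "0") return(chem_formula())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s, perl = TRUE)[[1]]
  pieces <- regmatches(s, list(m))[[1]]
  if (sum(nchar(pieces)) != nchar(s))
    stop("cannot parse formula string: ", x)
  counts <- c(C = 0L, H = 0L, O = 0L, Na = 0L)
  for (p in pieces) {
    sym <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (n == "") 1L else as.integer(n)
    if (!sym %in% names(counts))
      stop("unknown element symbol '", sym, "' in formula ", x)
    counts[sym] <- counts[sym] + n
  }
  chem_formula(C = counts[["C"]], H = counts[["H"]],
               O = counts[["O"]], Na = counts[["Na"]])
}

#' Format a formula in Hill order
#'
#' @param f a [chem_formula()].
#' @return Character scalar, e.g. `"C16H12O4"`; the zero formula formats as
#'   `""`.
#' @export
format_formula <- function(f) {
  v <- .as_formula_vec(f)
  names(v) <- names(.ELEMENT_MASS)
  ord <- c("C", "H", "Na", "O")  # Hill: C, H, then alphabetical
  out <- ""
  for (el in ord) {
    n <- v[[el]]
    if (n == 0L) next
    out <- paste0(out, el, if (n > 1L) n else "")
  }
  out
}

#' @export
format.chem_formula <- function(x, ...) format_formula(x)

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.chem_formula` <- function(e1, e2) {
  all(.as_formula_vec(e1) == .as_formula_vec(e2))
}

#' Formula arithmetic
#'
#' `formula_add()` sums element counts; `formula_diff()` subtracts and errors
#' if any count would go negative; `is_subformula()` tests element-wise
#' containment (every formula is a subformula of itself).
#'
#' @param a,b,small,big [chem_formula()] objects.
#' @return `formula_add`/`formula_diff`: a `chem_formula`; `is_subformula`:
#'   logical scalar.
#' @export
formula_add <- function(a, b) {
  v <- .as_formula_vec(a) + .as_formula_vec(b)
  chem_formula(C = v[1], H = v[2], O = v[3], Na = v[4])
}

#' @rdname formula_add
#' @export
formula_diff <- function(big, small) {
  v <- .as_formula_vec(big) - .as_formula_vec(small)
  if (any(v < 0))
    stop("formula_diff: ", format_formula(small), " is not contained in ",
         format_formula(big))
  chem_formula(C = v[1], H = v[2], O = v[3], Na = v[4])
}

#' @rdname formula_add
#' @export
is_subformula <- function(small, big) {
  all(.as_formula_vec(small) <= .as_formula_vec(big))
}

#' @rdname formula_add
#' @export
is_zero_formula <- function(a) all(.as_formula_vec(a) == 0L)

#' Monoisotopic mass of a formula
#'
#' @param f a [chem_formula()] or Hill string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("H2O"))  # 18.0106
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  sum(.as_formula_vec(f) * .ELEMENT_MASS)
}

#' Rings plus double-bond equivalents
#'
#' RDBE = C − H/2 + 1 for CHO formulas; Na is counted like H (monovalent).
#' Used as a chemical-plausibility filter in [decompose_mass()].
#'
#' @param f a [chem_formula()] or Hill string.
#' @return Numeric RDBE (may be half-integral for radical compositions).
#' @export
rdbe <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  v <- .as_formula_vec(f)
  v[1] - (v[2] + v[4]) / 2 + 1
}

# ---- ions --------------------------------------------------------------

.ADDUCTS <- c("[M+H]+", "[M+Na]+", "[2M+H]+", "cation")

#' Specify a singly charged positive ion
#'
#' The supported adducts are the positive-mode set `[M+H]+`, `[M+Na]+` and the
#' proton-bound dimer `[2M+H]+`, plus `"cation"` for a cation written as-is
#' (e.g. `[C16H13O4]+`, where the formula already includes the extra proton).
#' All ions carry charge +1.
#'
#' @param formula neutral formula (`chem_formula` or string); for
#'   `adduct = "cation"` the formula of the cation itself.
#' @param adduct one of `"[M+H]+"`, `"[M+Na]+"`, `"[2M+H]+"`, `"cation"`.
#' @return Object of class `ion_spec`.
#' @export
ion_spec <- function(formula, adduct = "[M+H]+") {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (!adduct %in% .ADDUCTS)
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(.ADDUCTS, collapse = ", "))
  structure(list(formula = formula, adduct = adduct, charge = 1L),
            class = "ion_spec")
}

#' Parse an ion string
#'
#' Understands `"[M+H]+"`, `"[M+Na]+"`, `"[2M+H]+"` (which need a separate
#' neutral formula) and cation-as-written strings such as `"[C16H13O4]+"`.
#'
#' @param x ion string.
#' @param neutral neutral formula, required for the M-based adducts.
#' @return An [ion_spec()].
#' @export
parse_ion <- function(x, neutral = NULL) {
  x <- gsub("\\s", "", x)
  if (x %in% c("[M+H]+", "[M+Na]+", "[2M+H]+")) {
    if (is.null(neutral))
      stop("adduct ion '", x, "' needs the neutral formula")
    return(ion_spec(neutral, x))
  }
  m <- regmatches(x, regexec("^\\[([A-Za-z0-9]+)\\]\\+$", x))[[1]]
  if (length(m) == 2L) return(ion_spec(parse_formula(m[2]), "cation"))
  stop("cannot parse ion string: ", x)
}

#' @export
format.ion_spec <- function(x, ...) {
  if (x$adduct == "cation")
    paste0("[", format_formula(x$formula), "]+")
  else x$adduct
}

#' Theoretical m/z of a singly charged positive ion
#'
#' For the M-based adducts the adduct mass is added to the neutral mass and
#' one electron mass subtracted; for cation-as-written the electron mass is
#' subtracted from the formula mass directly. This electron correction is what
#' makes the printed flavonoid fragment values (e.g. 241.0495, 213.0546)
#' reproduce to four decimals.
#'
#' @param ion an [ion_spec()], or a formula together with `adduct`.
#' @param adduct adduct string when `ion` is a bare formula.
#' @return m/z in Thomson.
#' @examples
#' ion_mz("C16H12O4", "[M+H]+")   # 269.0808
#' ion_mz("C8H7", "cation")       # 103.0542
#' @export
ion_mz <- function(ion, adduct = "[M+H]+") {
  if (!inherits(ion, "ion_spec")) ion <- ion_spec(ion, adduct)
  m <- monoisotopic_mass(ion$formula)
  switch(ion$adduct,
    "[M+H]+"  = m + .PROTON_MASS,
    "[M+Na]+" = m + .ELEMENT_MASS[["Na"]] - ELECTRON_MASS,
    "[2M+H]+" = 2 * m + .PROTON_MASS,
    "cation"  = m - ELECTRON_MASS
  )
}

#' Cation formula of an adduct ion
#'
#' Element inventory of the ion itself (neutral plus adduct atoms); used when
#' fragments must be subformulas of the precursor cation.
#'
#' @param ion an [ion_spec()].
#' @return A [chem_formula()].
#' @export
ion_formula <- function(ion) {
  stopifnot(inherits(ion, "ion_spec"))
  f <- ion$formula
  switch(ion$adduct,
    "[M+H]+"  = formula_add(f, chem_formula(H = 1L)),
    "[M+Na]+" = formula_add(f, chem_formula(Na = 1L)),
    "[2M+H]+" = formula_add(formula_add(f, f), chem_formula(H = 1L)),
    "cation"  = f
  )
}

#' Mass error between observed and theoretical m/z
#'
#' Sign convention is observed minus theoretical; ppm is computed against the
#' theoretical value.
#'
#' @param observed,theoretical positive m/z values.
#' @return List with `mda` (milli-Dalton) and `ppm` components.
#' @examples
#' mass_error(269.0806, 269.0808)  # -0.2 mDa
#' @export
mass_error <- function(observed, theoretical) {
  stopifnot(observed > 0, theoretical > 0)
  list(mda = 1000 * (observed - theoretical),
       ppm = 1e6 * (observed - theoretical) / theoretical)
}

# ---- formula decomposition ---------------------------------------------

#' Decompose an observed m/z into CHO formulas
#'
#' Exhaustively enumerates C/H/O compositions within `bounds`, keeps those
#' whose ion m/z (under `adduct`) lies within `tol_mda` of `target`, and
#' filters to chemically sane candidates: RDBE in `[0, 25]` and H no more than
#' 2C + 2. Results are sorted by absolute mass error, ties broken by fewer
#' oxygens. An empty result is a valid return.
#'
#' @param target observed m/z (Th).
#' @param adduct one of the supported adduct strings, `"cation"`, or
#'   `"neutral"` to decompose a neutral mass.
#' @param tol_mda tolerance in mDa (> 0).
#' @param bounds named list / vector with maximal counts `C`, `H`, `O`.
#' @return data.frame with columns `formula`, `mz`, `error_mda`, `rdbe`.
#' @export
decompose_mass <- function(target, adduct = "[M+H]+", tol_mda = 5,
                           bounds = c(C = 30, H = 40, O = 10)) {
  stopifnot(tol_mda > 0, target > 0)
  bounds <- unlist(bounds)[c("C", "H", "O")]
  if (any(is.na(bounds)) || any(!is.finite(bounds)))
    stop("bounds must give finite maxima for C, H and O")
  grid <- expand.grid(C = 0:bounds[["C"]], H = 0:bounds[["H"]],
                      O = 0:bounds[["O"]])
  mass <- grid$C * .ELEMENT_MASS[["C"]] + grid$H * .ELEMENT_MASS[["H"]] +
    grid$O * .ELEMENT_MASS[["O"]]
  mz <- switch(adduct,
    "neutral" = mass,
    "[M+H]+"  = mass + .PROTON_MASS,
    "[M+Na]+" = mass + .ELEMENT_MASS[["Na"]] - ELECTRON_MASS,
    "[2M+H]+" = 2 * mass + .PROTON_MASS,
    "cation"  = mass - ELECTRON_MASS,
    stop("unsupported adduct '", adduct, "'")
  )
  err <- 1000 * (mz - target)
  deg <- grid$C - grid$H / 2 + 1
  keep <- abs(err) <= tol_mda & deg >= 0 & deg <= 25 &
    grid$H <= 2 * grid$C + 2 & (grid$C + grid$H + grid$O) > 0
  if (!any(keep)) {
    return(data.frame(formula = character(), mz = numeric(),
                      error_mda = numeric(), rdbe = numeric(),
                      stringsAsFactors = FALSE))
  }
  grid <- grid[keep, , drop = FALSE]
  out <- data.frame(
    formula = vapply(seq_len(nrow(grid)), function(i) {
      format_formula(chem_formula(C = grid$C[i], H = grid$H[i], O = grid$O[i]))
    }, character(1)),
    mz = mz[keep],
    error_mda = err[keep],
    rdbe = deg[keep],
    stringsAsFactors = FALSE
  )
  ord <- order(abs(out$error_mda), grid$O)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
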