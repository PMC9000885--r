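# Flavonoid chemistry core. Cleavage templates are explicit per-skeleton
# data (the subclass rules are defined pictorially in the literature, and the
# neoflavonoid bond labels have no general algorithmic definition); a
# conservation check part_a + part_b == scaffold guards the transcription.

.registry_env <- new.env(parent = emptyenv())

.SUB_DELTA <- list(
  oh  = c(C = 0L, H = 0L, O = 1L),  # hydroxyl replaces ring H: +O
  ome = c(C = 1L, H = 2L, O = 1L),  # methoxyl: +CH2O
  me  = c(C = 1L, H = 2L, O = 0L)   # methyl: +CH2
)

.SUBCLASSES <- c("flavone", "flavonol", "isoflavone", "flavanone", "chalcone",
                 "flavanol", "aurone", "neoflavonoid_I", "neoflavonoid_II",
                 "neoflavonoid_III", "neoflavonoid_IV", "neoflavonoid_VIII")

#' Load the flavonoid skeleton registry
#'
#' Reads the packaged skeleton/cleavage/rule definitions, validates them
#' (exactly 12 subclasses; every cleavage's part_a + part_b equals the
#' scaffold exactly; rule ions reference registered labels) and caches the
#' result for the session.
#'
#' @param path optional path to an alternative registry file.
#' @return Named list of skeleton definitions (invisibly cached).
#' @export
skeleton_registry <- function(path = NULL) {
  cache_key <- if (is.null(path)) "default" else path
  if (!is.null(.registry_env[[cache_key]])) return(.registry_env[[cache_key]])
  if (is.null(path))
    path <- system.file("extdata", "flavonoid_skeletons.yaml",
                        package = "flavotier", mustWork = TRUE)
  reg <- yaml::read_yaml(path)$skeletons
  if (!setequal(names(reg), .SUBCLASSES))
    stop("registry must define exactly the 12 flavonoid subclasses")
  for (id in names(reg)) {
    sk <- reg[[id]]
    scaffold <- parse_formula(sk$scaffold)
    reg[[id]]$scaffold_formula <- scaffold
    for (lab in names(sk$cleavages)) {
      cl <- sk$cleavages[[lab]]
      pa <- parse_formula(cl$part_a); pb <- parse_formula(cl$part_b)
      if (!(formula_add(pa, pb) == scaffold))
        stop("skeleton '", id, "' cleavage '", lab,
             "': part_a + part_b != scaffold (conservation violated)")
      if (!is_subformula(pa, scaffold) || !is_subformula(pb, scaffold))
        stop("skeleton '", id, "' cleavage '", lab,
             "': parts must be subformulas of the scaffold")
    }
    if (anyDuplicated(names(sk$cleavages)))
      stop("skeleton '", id, "': duplicate cleavage labels")
    for (ion in sk$ions) {
      if (identical(ion$kind, "fragment") &&
          !ion$cleavage %in% names(sk$cleavages))
        stop("skeleton '", id, "': ion ", ion$label,
             " references unregistered cleavage '", ion$cleavage, "'")
    }
  }
  .registry_env[[cache_key]] <- reg
  reg
}

#' Flavonoid subclass identifiers
#' @return Character vector of the 12 registered subclass ids.
#' @export
subclass_ids <- function() .SUBCLASSES

.sub_counts <- function(x) {
  out <- c(oh = 0L, ome = 0L, me = 0L)
  if (length(x) == 0L) return(out)
  x <- unlist(x)
  bad <- setdiff(names(x), names(out))
  if (length(bad)) stop("unknown substituent(s): ", paste(bad, collapse = ", "))
  out[names(x)] <- as.integer(x)
  if (any(out < 0)) stop("substituent counts must be non-negative")
  out
}

#' Define a flavonoid compound template
#'
#' A template is a subclass skeleton plus a substituent multiset per ring
#' region. Supported substituents: `oh` (hydroxyl, +O), `ome` (methoxyl,
#' +CH2O), `me` (methyl, +CH2).
#'
#' @param name compound name.
#' @param skeleton subclass id (see [subclass_ids()]).
#' @param ringA,ringB,ringC named counts, e.g. `c(oh = 2, ome = 1)`.
#' @param provenance provenance tag passed through to library records.
#' @return Object of class `compound_template`.
#' @examples
#' compound_template("daidzein", "isoflavone", ringA = c(oh = 1), ringB = c(oh = 1))
#' @export
compound_template <- function(name, skeleton, ringA = NULL, ringB = NULL,
                              ringC = NULL, provenance = "synthetic") {
  reg <- skeleton_registry()
  if (!skeleton %in% names(reg))
    stop("unknown skeleton '", skeleton, "'; registered: ",
         paste(names(reg), collapse = ", "))
  structure(list(name = name, skeleton = skeleton,
                 subs = list(ringA = .sub_counts(ringA),
                             ringB = .sub_counts(ringB),
                             ringC = .sub_counts(ringC)),
                 provenance = provenance),
            class = "compound_template")
}

#' @export
print.compound_template <- function(x, ...) {
  cat(sprintf("<compound_template> %s (%s, %s)\n", x$name, x$skeleton,
              format_formula(compound_formula(x))))
  invisible(x)
}

.delta_formula <- function(counts) {
  v <- c(C = 0L, H = 0L, O = 0L)
  for (s in names(counts))
    v <- v + counts[[s]] * .SUB_DELTA[[s]]
  chem_formula(C = v[["C"]], H = v[["H"]], O = v[["O"]])
}

.template_delta <- function(t, regions) {
  d <- chem_formula()
  for (r in regions) d <- formula_add(d, .delta_formula(t$subs[[r]]))
  d
}

.has_ome <- function(t) sum(vapply(t$subs, function(s) s[["ome"]], 0L)) > 0L

#' Neutral molecular formula of a compound template
#'
#' Scaffold formula plus the substituent deltas.
#'
#' @param t a [compound_template()].
#' @return A [chem_formula()].
#' @export
compound_formula <- function(t) {
  sk <- skeleton_registry()[[t$skeleton]]
  formula_add(sk$scaffold_formula,
              .template_delta(t, c("ringA", "ringB", "ringC")))
}

# Decorated neutral part formulas for one cleavage of a template: ring
# substituents follow the part that retains their ring.
.cleavage_parts <- function(t, label) {
  sk <- skeleton_registry()[[t$skeleton]]
  cl <- sk$cleavages[[label]]
  if (is.null(cl))
    stop("cleavage '", label, "' not defined for skeleton '", t$skeleton,
         "'; valid labels: ", paste(names(sk$cleavages), collapse = ", "))
  regions_a <- unlist(cl$rings_a)
  regions_b <- setdiff(c("ringA", "ringB", "ringC"), regions_a)
  list(
    a = list(name = cl$name_a,
             formula = formula_add(parse_formula(cl$part_a),
                                   .template_delta(t, regions_a))),
    b = list(name = cl$name_b,
             formula = formula_add(parse_formula(cl$part_b),
                                   .template_delta(t, regions_b)))
  )
}

.apply_h_offset <- function(f, h) {
  v <- .as_formula_vec(f)
  v[2] <- v[2] + as.integer(h)
  if (v[2] < 0) return(NULL)
  chem_formula(C = v[1], H = v[2], O = v[3], Na = v[4])
}

.try_losses <- function(f, losses) {
  for (l in losses) {
    lf <- if (is.character(l)) parse_formula(l) else l
    if (!is_subformula(lf, f)) return(NULL)
    f <- formula_diff(f, lf)
  }
  f
}

#' Retro-Diels-Alder fragment ions for one cleavage
#'
#' Computes the decorated fragment ions of a cleavage: ring-A substituents
#' decorate the A-side part, ring-B substituents the B-side part, ring-C
#' substituents the part recorded per template. Ion forms (hydrogen-transfer
#' offset and electron parity) follow the skeleton's diagnostic-ion
#' conventions; parts without a convention default to the even-electron
#' `[part+H]+` form.
#'
#' @param t a [compound_template()].
#' @param label cleavage label registered for the template's skeleton.
#' @return data.frame with columns `cleavage`, `part`, `part_name`,
#'   `neutral_part`, `ion_label`, `cation`, `mz`, `parity`.
#' @examples
#' d <- compound_template("daidzein", "isoflavone", ringA = c(oh = 1), ringB = c(oh = 1))
#' rda_fragment_ions(d, "1,3")  # 137.0233 and 119.0491
#' @export
rda_fragment_ions <- function(t, label) {
  sk <- skeleton_registry()[[t$skeleton]]
  parts <- .cleavage_parts(t, label)
  # ion-form conventions from the skeleton's plain fragment ions
  conv <- list(a = NULL, b = NULL)
  for (ion in sk$ions) {
    if (identical(ion$kind, "fragment") && identical(ion$cleavage, label) &&
        is.null(ion$losses) && is.null(ion$gains))
      if (is.null(conv[[ion$part]])) conv[[ion$part]] <- ion
  }
  rows <- lapply(c("a", "b"), function(p) {
    h <- if (!is.null(conv[[p]])) conv[[p]]$h else 1L
    parity <- if (!is.null(conv[[p]]) && identical(conv[[p]]$parity, "radical"))
      "radical" else "even"
    cat_f <- .apply_h_offset(parts[[p]]$formula, h)
    if (is.null(cat_f)) return(NULL)
    lab <- if (parity == "radical")
      paste0("[", parts[[p]]$name, "]+.")
    else paste0("[", parts[[p]]$name, "+H]+")
    data.frame(cleavage = label, part = p, part_name = parts[[p]]$name,
               neutral_part = format_formula(parts[[p]]$formula),
               ion_label = lab, cation = format_formula(cat_f),
               mz = ion_mz(cat_f, "cation"), parity = parity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.compose_loss_label <- function(base, loss_multiset) {
  if (length(loss_multiset) == 0L) return(base)
  tab <- table(loss_multiset)
  chunk <- paste0(vapply(names(tab), function(l) {
    n <- tab[[l]]
    paste0("-", if (n > 1L) n else "", l)
  }, character(1)), collapse = "")
  if (grepl("\\+H\\]\\+$", base))
    sub("\\+H\\]\\+$", paste0(chunk, "+H]+"), base)
  else if (grepl("\\]\\+\\.$", base))
    sub("\\]\\+\\.$", paste0(chunk, "]+."), base)
  else paste0(base, chunk)
}

#' Neutral-loss series from an ion
#'
#' Enumerates all loss multisets up to `depth` applications of the given
#' neutral losses, pruning combinations that would drive an element count
#' negative. Labels compose, e.g. `"[M-2CO+H]+"`.
#'
#' @param cation starting cation formula ([chem_formula()] or Hill string).
#' @param losses list of neutral loss formulas (strings or `chem_formula`).
#' @param depth maximum number of sequential losses (>= 0).
#' @param label label of the starting ion, default `"[M+H]+"`.
#' @return data.frame with `label`, `cation`, `mz`, `n_losses`.
#' @examples
#' loss_series("C15H9O5", list("CO"), depth = 2)  # 269.0444, 241.0495, 213.0546
#' @export
loss_series <- function(cation, losses, depth = 1L, label = "[M+H]+") {
  stopifnot(depth >= 0)
  if (is.character(cation)) cation <- parse_formula(cation)
  losses <- lapply(losses, function(l) if (is.character(l)) parse_formula(l) else l)
  loss_names <- vapply(losses, format_formula, character(1))
  acc <- list(list(f = cation, ms = character(0)))
  out <- list(list(f = cation, ms = character(0)))
  if (depth > 0) for (d in seq_len(depth)) {
    nxt <- list()
    for (node in acc) {
      for (i in seq_along(losses)) {
        # enforce canonical (sorted) multiset growth to avoid duplicates
        if (length(node$ms) > 0L && loss_names[i] < node$ms[length(node$ms)])
          next
        f2 <- .try_losses(node$f, losses[i])
        if (is.null(f2) || is_zero_formula(f2)) next
        nxt[[length(nxt) + 1L]] <- list(f = f2, ms = c(node$ms, loss_names[i]))
      }
    }
    out <- c(out, nxt)
    acc <- nxt
    if (length(acc) == 0L) break
  }
  data.frame(
    label = vapply(out, function(n) .compose_loss_label(label, n$ms), character(1)),
    cation = vapply(out, function(n) format_formula(n$f), character(1)),
    mz = vapply(out, function(n) ion_mz(n$f, "cation"), numeric(1)),
    n_losses = vapply(out, function(n) length(n$ms), integer(1)),
    stringsAsFactors = FALSE)
}

# Compute the full diagnostic ion table for a template: one row per
# registry ion entry that survives decoration and loss pruning.
.diagnostic_ions <- function(t) {
  sk <- skeleton_registry()[[t$skeleton]]
  M <- compound_formula(t)
  prec_cat <- formula_add(M, chem_formula(H = 1L))
  rows <- list()
  for (ion in sk$ions) {
    if (isTRUE(ion$requires_ome) && !.has_ome(t)) next
    cat_f <- switch(ion$kind,
      precursor = prec_cat,
      fragment = {
        parts <- .cleavage_parts(t, ion$cleavage)
        .apply_h_offset(parts[[ion$part]]$formula,
                        if (is.null(ion$h)) 1L else ion$h)
      },
      ring_b_loss = {
        loss <- formula_add(parse_formula("C6H6"), .template_delta(t, "ringB"))
        .try_losses(prec_cat, list(loss))
      },
      stop("unknown ion kind '", ion$kind, "'"))
    if (is.null(cat_f)) next
    if (!is.null(ion$gains))
      for (g in ion$gains) cat_f <- formula_add(cat_f, parse_formula(g))
    if (!is.null(ion$losses)) {
      cat_f <- .try_losses(cat_f, lapply(ion$losses, parse_formula))
      if (is.null(cat_f)) next
    }
    if (is_zero_formula(cat_f)) next
    rows[[length(rows) + 1L]] <- data.frame(
      label = ion$label, cation = format_formula(cat_f),
      mz = ion_mz(cat_f, "cation"),
      tier = ion$tier, role = ion$role,
      parity = if (identical(ion$parity, "radical")) "radical" else "even",
      is_precursor = identical(ion$kind, "precursor") && is.null(ion$losses),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Theoretical diagnostic spectrum of a compound template
#'
#' Emits the protonated precursor plus the subclass's diagnostic cleavage and
#' neutral-loss ions with deterministic relative intensities (base-peak ion
#' 100, strong ions 60, minor ions 20-40; the flavanone/chalcone convention
#' places at least 40% of the summed fragment intensity on the 1,3 A-ring
#' ion). Peaks that coincide in m/z are merged keeping the highest tier.
#'
#' @param t a [compound_template()].
#' @return An [ms_spectrum()] whose `metadata$ions` table carries the ion
#'   annotations (label, cation formula, tier, role, parity).
#' @export
theoretical_spectrum <- function(t) {
  ions <- .diagnostic_ions(t)
  prec_mz <- ion_mz(compound_formula(t), "[M+H]+")
  # merge ions landing on the same m/z (e.g. decorated parts that coincide)
  ions <- ions[order(-ions$tier), , drop = FALSE]
  keep <- !duplicated(round(ions$mz, 4))
  merged <- ions[keep, , drop = FALSE]
  sp <- ms_spectrum(
    id = t$name, precursor_mz = prec_mz, adduct = "[M+H]+",
    peaks = data.frame(mz = merged$mz, intensity = merged$tier),
    metadata = list(ions = merged[order(merged$mz), , drop = FALSE],
                    template = t))
  normalize_spectrum(sp)
}

#' Complementary fragment pair test
#'
#' Two peaks are complementary when their m/z sum matches the precursor m/z
#' plus one of three offsets: +1.00728 for an H-transfer pair of
#' even-electron ions, 0 for a radical/even split, or +1.00728 - 15.0235 for
#' a pair observed after methyl-radical loss from a methoxylated precursor.
#'
#' @param mz1,mz2 fragment peak m/z values.
#' @param precursor_mz precursor m/z.
#' @param tol_mda tolerance in mDa.
#' @return Logical scalar.
#' @export
complementary_pair_check <- function(mz1, mz2, precursor_mz, tol_mda = 10) {
  stopifnot(tol_mda > 0)
  offsets <- c(h_transfer = 1.00782503207,
               radical_split = 0,
               after_methyl_loss = 1.00782503207 - 15.02347509621)
  any(abs(mz1 + mz2 - precursor_mz - offsets) <= tol_mda / 1000)
}
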