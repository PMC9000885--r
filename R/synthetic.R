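# Synthetic stand-in for instrument data: the 39-compound (quasi-)reference
# fixture library and a seeded HCD-like spectrum simulator with ground truth
# for every pipeline tier.

# The fixture set: 4 flavones, 6 flavonols, 9 isoflavones, 1 aurone,
# 6 flavanones, 2 chalcones, 2 flavanols (dihydroflavonols), 4 neoflavonoids
# I, 1 neoflavonoid II, 1 neoflavonoid III, 2 neoflavonoids IV and
# 1 neoflavonoid VIII. The 18 purchased standards are carried by name
# (provenance "reference"); the remaining entries are representative
# templates of the stated subclass, tagged quasi-reference. The compound in
# slot F23 keeps its source name but is a representative pentamethoxy
# template of its (flavanone) slot.
.FIXTURES <- list(
  list("F01", "baicalein",                  "flavone",    ringA = c(oh = 3),          ringB = NULL,              prov = "reference"),
  list("F02", "apigenin",                   "flavone",    ringA = c(oh = 2),          ringB = c(oh = 1),         prov = "reference"),
  list("F03", "wogonin",                    "flavone",    ringA = c(oh = 2, ome = 1), ringB = NULL,              prov = "reference"),
  list("F04", "acacetin",                   "flavone",    ringA = c(oh = 2),          ringB = c(ome = 1),        prov = "reference"),
  list("F05", "galangin",                   "flavonol",   ringA = c(oh = 2),          ringB = NULL,              prov = "reference"),
  list("F06", "quercetin",                  "flavonol",   ringA = c(oh = 2),          ringB = c(oh = 2),         prov = "reference"),
  list("F07", "isorhamnetin",               "flavonol",   ringA = c(oh = 2),          ringB = c(oh = 1, ome = 1), prov = "reference"),
  list("F08", "kaempferol",                 "flavonol",   ringA = c(oh = 2),          ringB = c(oh = 1),         prov = "quasi-reference-mzCloud"),
  list("F09", "rhamnetin-like",             "flavonol",   ringA = c(oh = 1, ome = 1), ringB = c(oh = 2),         prov = "quasi-reference-2a"),
  list("F10", "7-hydroxyflavonol",          "flavonol",   ringA = c(oh = 1),          ringB = NULL,              prov = "quasi-reference-2a"),
  list("F11", "glycitein",                  "isoflavone", ringA = c(oh = 1, ome = 1), ringB = c(oh = 1),         prov = "reference"),
  list("F12", "genistein",                  "isoflavone", ringA = c(oh = 2),          ringB = c(oh = 1),         prov = "reference"),
  list("F13", "calycosin",                  "isoflavone", ringA = c(oh = 1),          ringB = c(oh = 1, ome = 1), prov = "reference"),
  list("F14", "daidzein",                   "isoflavone", ringA = c(oh = 1),          ringB = c(oh = 1),         prov = "reference"),
  list("F15", "formononetin",               "isoflavone", ringA = c(oh = 1),          ringB = c(ome = 1),        prov = "reference"),
  list("F16", "biochanin A",                "isoflavone", ringA = c(oh = 2),          ringB = c(ome = 1),        prov = "quasi-reference-mzCloud"),
  list("F17", "afrormosin-like",            "isoflavone", ringA = c(oh = 1, ome = 1), ringB = c(ome = 1),        prov = "quasi-reference-2a"),
  list("F18", "orobol-like",                "isoflavone", ringA = c(oh = 2),          ringB = c(oh = 2),         prov = "quasi-reference-2a"),
  list("F19", "dimethoxy-isoflavonol-like", "isoflavone", ringA = c(oh = 1),          ringB = c(ome = 2),        prov = "quasi-reference-2a"),
  list("F20", "isoliquiritigenin",          "chalcone",   ringA = c(oh = 1),          ringB = c(oh = 1),         prov = "reference"),
  list("F21", "pinocembrin-like",           "flavanone",  ringA = c(oh = 2),          ringB = NULL,              prov = "quasi-reference-2a"),
  list("F22", "naringenin",                 "flavanone",  ringA = c(oh = 2),          ringB = c(oh = 1),         prov = "reference"),
  list("F23", "tangeretin",                 "flavanone",  ringA = c(ome = 3),         ringB = c(ome = 2),        prov = "reference"),
  list("F24", "liquiritigenin",             "flavanone",  ringA = c(oh = 1),          ringB = c(oh = 1),         prov = "reference"),
  list("F25", "sakuranetin-like",           "flavanone",  ringA = c(oh = 1, ome = 1), ringB = c(oh = 1),         prov = "quasi-reference-2a"),
  list("F26", "hesperetin-like",            "flavanone",  ringA = c(oh = 2),          ringB = c(oh = 1, ome = 1), prov = "quasi-reference-mzCloud"),
  list("F27", "butein-like",                "chalcone",   ringA = c(oh = 1),          ringB = c(oh = 2),         prov = "quasi-reference-2a"),
  list("F28", "taxifolin",                  "flavanol",   ringA = c(oh = 2),          ringB = c(oh = 2),         prov = "reference"),
  list("F29", "dihydromyricetin",           "flavanol",   ringA = c(oh = 2),          ringB = c(oh = 3),         prov = "reference"),
  list("F30", "medicarpin-like",            "neoflavonoid_I",    ringA = c(ome = 1),         ringB = c(oh = 1),  prov = "quasi-reference-mzCloud"),
  list("F31", "maackiain-like",             "neoflavonoid_I",    ringA = c(oh = 1),          ringB = c(oh = 1, ome = 1), prov = "quasi-reference-2a"),
  list("F32", "homopterocarpin-like",       "neoflavonoid_I",    ringA = c(ome = 1),         ringB = c(ome = 1), prov = "quasi-reference-2a"),
  list("F33", "demethylmedicarpin-like",    "neoflavonoid_I",    ringA = c(oh = 1),          ringB = c(oh = 1),  prov = "quasi-reference-2a"),
  list("F34", "coumestan-diol (representative)", "neoflavonoid_II", ringA = NULL,          ringB = NULL, ringC = c(oh = 2), prov = "quasi-reference-mzCloud"),
  list("F35", "sulfuretin-like",            "aurone",            ringA = c(oh = 1),          ringB = c(oh = 1),  prov = "quasi-reference-mzCloud"),
  list("F36", "hydroxy-neoflavene (representative)", "neoflavonoid_III", ringA = c(oh = 1), ringB = c(oh = 1),  prov = "quasi-reference-2a"),
  list("F37", "dalbergione-like",           "neoflavonoid_IV",   ringA = c(ome = 1),         ringB = c(oh = 1),  prov = "quasi-reference-mzCloud"),
  list("F38", "methoxydalbergione-like",    "neoflavonoid_IV",   ringA = c(oh = 1, ome = 1), ringB = c(ome = 1), prov = "quasi-reference-2a"),
  list("F39", "pterocarpene-lactone (representative)", "neoflavonoid_VIII", ringA = c(oh = 1), ringB = NULL,    prov = "quasi-reference-mzCloud")
)

.EXPECTED_COMPOSITION <- c(
  flavone = 4L, flavonol = 6L, isoflavone = 9L, aurone = 1L, flavanone = 6L,
  chalcone = 2L, flavanol = 2L, neoflavonoid_I = 4L, neoflavonoid_II = 1L,
  neoflavonoid_III = 1L, neoflavonoid_IV = 2L, neoflavonoid_VIII = 1L)

#' Build the 39-compound quasi-reference fixture library
#'
#' Constructs the fixture set of 39 (quasi-)reference compounds across the 12
#' subclasses (4 flavones, 6 flavonols, 9 isoflavones, 1 aurone, 6
#' flavanones, 2 chalcones, 2 flavanols, 4 neoflavonoids I, 1 neoflavonoid
#' II, 1 neoflavonoid III, 2 neoflavonoids IV, 1 neoflavonoid VIII). Spectra
#' are the noise-free theoretical diagnostic spectra; retention times sit on
#' a deterministic spaced grid. The composition is re-checked at build time
#' so fixture edits cannot silently change it.
#'
#' @return List with `records` (39 [library_record()]s), `templates` (named
#'   list of [compound_template()]s) and `rt` (named retention times, min).
#' @export
build_quasi_library <- function() {
  templates <- list(); records <- list(); rts <- numeric()
  for (i in seq_along(.FIXTURES)) {
    fx <- .FIXTURES[[i]]
    t <- compound_template(fx[[2]], fx[[3]], ringA = fx$ringA,
                           ringB = fx$ringB, ringC = fx$ringC,
                           provenance = fx$prov)
    sp <- theoretical_spectrum(t)
    sp$rt <- 2 + 0.6 * (i - 1)   # spaced grid, well beyond the 0.05-min window
    rec <- library_record(sp, name = t$name,
                          formula = compound_formula(t),
                          subclass = t$skeleton, provenance = fx$prov)
    templates[[t$name]] <- t
    records[[length(records) + 1L]] <- rec
    rts[t$name] <- sp$rt
  }
  comp <- table(vapply(records, function(r) r$subclass, character(1)))
  if (length(records) != 39L ||
      !identical(sort(names(comp)), sort(names(.EXPECTED_COMPOSITION))) ||
      any(comp[names(.EXPECTED_COMPOSITION)] != .EXPECTED_COMPOSITION))
    stop("fixture library composition check failed")
  list(records = records, templates = templates, rt = rts)
}

#' Simulation configuration
#'
#' @param mz_jitter_mda Gaussian m/z jitter standard deviation, mDa.
#' @param n_decoys number of uniform-random decoy peaks.
#' @param decoy_intensity decoy relative intensity (percent of base peak).
#' @param intensity_noise multiplicative intensity noise (percent).
#' @param rt_jitter_min retention-time jitter standard deviation, minutes.
#' @param seed mandatory random seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(mz_jitter_mda = 3, n_decoys = 5,
                              decoy_intensity = 5, intensity_noise = 10,
                              rt_jitter_min = 0.01, seed) {
  if (missing(seed) || is.null(seed))
    stop("simulation_config: a seed is mandatory")
  stopifnot(mz_jitter_mda >= 0, n_decoys >= 0, decoy_intensity >= 0,
            intensity_noise >= 0, rt_jitter_min >= 0)
  structure(list(mz_jitter_mda = mz_jitter_mda, n_decoys = n_decoys,
                 decoy_intensity = decoy_intensity,
                 intensity_noise = intensity_noise,
                 rt_jitter_min = rt_jitter_min, seed = as.integer(seed)),
            class = "simulation_config")
}

# Unseeded simulator core; the exported wrappers own the seeding.
.simulate_spectrum_impl <- function(t, cfg, id = t$name, rt = NA_real_) {
  sp <- theoretical_spectrum(t)
  p <- sp$peaks
  p$mz <- p$mz + rnorm(nrow(p), 0, cfg$mz_jitter_mda / 1000)
  p$intensity <- pmax(
    p$intensity * (1 + rnorm(nrow(p), 0, cfg$intensity_noise / 100)), 0.1)
  # the emulated acquisition records the precursor survey scan at four times
  # the fragment-scan resolution, so precursor jitter is a quarter of the
  # fragment jitter
  prec <- sp$precursor_mz + rnorm(1, 0, cfg$mz_jitter_mda / 4000)
  if (cfg$n_decoys > 0L) {
    dmz <- runif(cfg$n_decoys, 50, max(60, prec - 20))
    p <- rbind(p, data.frame(mz = dmz,
                             intensity = rep(cfg$decoy_intensity,
                                             cfg$n_decoys)))
  }
  ms_spectrum(id = id, precursor_mz = prec, peaks = p, adduct = "[M+H]+",
              rt = if (is.na(rt)) NA_real_ else
                rt + rnorm(1, 0, cfg$rt_jitter_min),
              metadata = list(template = t$name))
}

#' Simulate a noisy HCD-like spectrum from a template
#'
#' Applies Gaussian m/z jitter, multiplicative intensity noise and
#' uniform-random decoy peaks below the precursor to the template's
#' theoretical spectrum. Deterministic given the config seed; with zero noise
#' and zero decoys the result equals the theoretical spectrum.
#'
#' @param t a [compound_template()].
#' @param cfg a [simulation_config()] (seed mandatory).
#' @param id spectrum identifier.
#' @param rt optional retention time (jittered by `rt_jitter_min`).
#' @return An [ms_spectrum()].
#' @export
simulate_spectrum <- function(t, cfg, id = t$name, rt = NA_real_) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  .simulate_spectrum_impl(t, cfg, id, rt)
}

#' Simulate a mixed-level query dataset with ground truth
#'
#' Draws `n` queries from the fixture library with designed confidence
#' levels. Templates are partitioned by precursor formula (so a query can
#' never meet a same-formula twin across the evidence boundary): designed
#' level-1 templates enter the standards list (with matching retention time)
#' and the spectral library; level-2a templates the library only; level-2b
#' templates the candidate-structure list only; level-3 templates are
#' withheld everywhere. The candidate list carries all non-withheld
#' templates, as a structure database would.
#'
#' @param n number of queries.
#' @param level_mix named fractions over designed levels, summing to 1,
#'   e.g. `c("1" = 0.1, "2a" = 0.4, "2b" = 0.3, "3" = 0.2)`.
#' @param cfg a [simulation_config()] (seed mandatory).
#' @return List: `queries` (spectra), `ground_truth` (data.frame: query_id,
#'   template, subclass, designed_level), `standards`, `library`,
#'   `candidates`, `seed`.
#' @export
simulate_dataset <- function(n, level_mix = c("1" = 0.1, "2a" = 0.4,
                                              "2b" = 0.3, "3" = 0.2),
                             cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (abs(sum(level_mix) - 1) > 1e-9)
    stop("level_mix fractions must sum to 1")
  levels_req <- names(level_mix)[level_mix > 0]
  if (!all(levels_req %in% c("1", "2a", "2b", "3")))
    stop("designed levels must be among 1, 2a, 2b, 3")
  if (n < length(levels_req))
    stop("n smaller than the number of designed levels requested")
  set.seed(cfg$seed)
  lib <- build_quasi_library()
  tnames <- names(lib$templates)
  formulas <- vapply(lib$templates,
                     function(t) format_formula(compound_formula(t)),
                     character(1))
  groups <- split(tnames, formulas[tnames])      # same-formula co-location
  groups <- groups[sample(length(groups))]
  # allocate formula groups to designed levels proportionally to level_mix
  sizes <- vapply(groups, length, 1L)
  targets <- level_mix[levels_req] * length(tnames)
  assign_level_of <- character(0)
  filled <- setNames(numeric(length(levels_req)), levels_req)
  for (g in seq_along(groups)) {
    deficit <- targets - filled
    lv <- levels_req[which.max(deficit / pmax(targets, 1e-9))]
    for (nm in groups[[g]]) assign_level_of[nm] <- lv
    filled[lv] <- filled[lv] + sizes[g]
  }
  pools <- split(names(assign_level_of), assign_level_of)
  for (lv in levels_req)
    if (is.null(pools[[lv]]) || length(pools[[lv]]) == 0L)
      stop("no fixture templates available for designed level ", lv)
  # query counts per level (largest-remainder rounding to sum n)
  counts <- floor(level_mix[levels_req] * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- level_mix[levels_req] * n - counts
    add <- order(-frac)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  # evidence splits
  std_names <- pools[["1"]]
  lib_names <- c(pools[["1"]], pools[["2a"]])
  cand_names <- c(pools[["1"]], pools[["2a"]], pools[["2b"]])
  rec_names <- vapply(lib$records, function(r) r$name, character(1))
  standards <- lib$records[rec_names %in% std_names]
  library_recs <- lib$records[rec_names %in% lib_names]
  candidates <- unname(lib$templates[cand_names])
  # queries
  queries <- list(); gt <- list(); k <- 0L
  for (lv in levels_req) {
    for (i in seq_len(counts[[lv]])) {
      k <- k + 1L
      tn <- if (length(pools[[lv]]) == 1L) pools[[lv]] else
        sample(pools[[lv]], 1L)
      t <- lib$templates[[tn]]
      qid <- sprintf("Q%04d", k)
      # level-1 queries reproduce the standard's RT; others sit mid-grid so
      # they can never fall inside another standard's RT window
      rt <- if (lv == "1") lib$rt[[tn]] else lib$rt[[tn]] + 0.3
      queries[[qid]] <- .simulate_spectrum_impl(t, cfg, id = qid, rt = rt)
      gt[[qid]] <- data.frame(query_id = qid, template = tn,
                              subclass = t$skeleton, designed_level = lv,
                              stringsAsFactors = FALSE)
    }
  }
  ground_truth <- do.call(rbind, gt)
  rownames(ground_truth) <- NULL
  list(queries = queries, ground_truth = ground_truth,
       standards = standards, library = library_recs,
       candidates = candidates, seed = cfg$seed)
}
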