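# The tiering pipeline: level-1 reference-standard matching, level-2a
# spectral-library search, level-2b in-silico candidate ranking, level-3 de
# novo formula/tree annotation, and Schymanski level assignment with
# quasi-reference promotion.

#' Pipeline configuration
#'
#' Defaults follow the positive-mode flavonoid workflow conventions: 0.05 min
#' retention-time window and 5 mDa precursor tolerance for level-1 standard
#' matching, 10 mDa MS2 (and level-2a precursor) tolerance, an inclusive
#' level-2a score cutoff of 80%, a strict quasi-reference promotion cutoff of
#' 90%, and at least 3 matching fragment ions for a level-1 identification.
#'
#' @param rt_tol_min retention-time tolerance, minutes.
#' @param ms1_tol_mda level-1 precursor mass tolerance, mDa.
#' @param ms2_tol_mda fragment (and level-2a precursor) tolerance, mDa.
#' @param score_cutoff level-2a score cutoff, percent (inclusive).
#' @param quasi_cutoff quasi-reference promotion cutoff, percent (strict).
#' @param min_fragments minimum matched fragment ions for level 1.
#' @param adducts supported adduct set.
#' @param method similarity method, `"dot_product"` or `"entropy"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(rt_tol_min = 0.05, ms1_tol_mda = 5,
                            ms2_tol_mda = 10, score_cutoff = 80,
                            quasi_cutoff = 90, min_fragments = 3L,
                            adducts = c("[M+H]+", "[M+Na]+", "[2M+H]+"),
                            method = c("dot_product", "entropy")) {
  method <- match.arg(method)
  stopifnot(rt_tol_min > 0, ms1_tol_mda > 0, ms2_tol_mda > 0,
            score_cutoff >= 0, score_cutoff <= 100,
            quasi_cutoff >= 0, quasi_cutoff <= 100, min_fragments >= 1)
  structure(list(rt_tol_min = rt_tol_min, ms1_tol_mda = ms1_tol_mda,
                 ms2_tol_mda = ms2_tol_mda, score_cutoff = score_cutoff,
                 quasi_cutoff = quasi_cutoff,
                 min_fragments = as.integer(min_fragments),
                 adducts = adducts, method = method),
            class = "pipeline_config")
}

.similarity_fun <- function(cfg) {
  if (cfg$method == "entropy") entropy_score else cosine_score
}

#' Level 1: match a query against reference standards
#'
#' A standard matches when (1) the retention-time error does not exceed the
#' RT tolerance, (2) the precursor mass error does not exceed the level-1
#' tolerance, and (3) at least `min_fragments` fragment ions match at the MS2
#' tolerance. The best match has the most matched fragments, ties broken by
#' smaller precursor error. Queries without a retention time skip level 1
#' with a warning.
#'
#' @param query an [ms_spectrum()] with retention time.
#' @param standards list of [library_record()]s carrying retention times.
#' @param cfg a [pipeline_config()].
#' @return The best match as a list (`record`, `n_matched`, `rt_error_min`,
#'   `mass_error_mda`), or `NULL`.
#' @export
match_level1 <- function(query, standards, cfg = pipeline_config()) {
  if (is.na(query$rt)) {
    warning("query '", query$id, "' has no retention time; level 1 skipped")
    return(NULL)
  }
  best <- NULL
  for (rec in standards) {
    sp <- rec$spectrum
    if (is.na(sp$rt)) next
    drt <- query$rt - sp$rt
    if (abs(drt) > cfg$rt_tol_min) next
    dm <- 1000 * (query$precursor_mz - sp$precursor_mz)
    if (abs(dm) > cfg$ms1_tol_mda) next
    nm <- nrow(match_peaks(query, sp, cfg$ms2_tol_mda))
    if (nm < cfg$min_fragments) next
    cand <- list(record = rec, n_matched = nm, rt_error_min = drt,
                 mass_error_mda = dm)
    if (is.null(best) || nm > best$n_matched ||
        (nm == best$n_matched && abs(dm) < abs(best$mass_error_mda)))
      best <- cand
  }
  best
}

#' Level 2a: spectral-library search
#'
#' Pre-filters the library by precursor m/z at the MS2 tolerance, scores the
#' survivors with the configured similarity and keeps hits at or above the
#' score cutoff, best first.
#'
#' @param query an [ms_spectrum()].
#' @param library list of [library_record()]s.
#' @param cfg a [pipeline_config()].
#' @return data.frame: `name`, `formula`, `subclass`, `provenance`,
#'   `score_percent`, `library_index`.
#' @export
search_level2a <- function(query, library, cfg = pipeline_config()) {
  score_fun <- .similarity_fun(cfg)
  rows <- list()
  for (i in seq_along(library)) {
    rec <- library[[i]]
    if (abs(query$precursor_mz - rec$spectrum$precursor_mz) >
        cfg$ms2_tol_mda / 1000) next
    s <- score_fun(query, rec$spectrum, cfg$ms2_tol_mda)
    if (!is_hit(s, cfg$score_cutoff)) next
    rows[[length(rows) + 1L]] <- data.frame(
      name = rec$name,
      formula = if (is.null(rec$formula)) NA_character_ else
        format_formula(rec$formula),
      subclass = rec$subclass, provenance = rec$provenance,
      score_percent = s$percent, library_index = i,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(name = character(), formula = character(),
                      subclass = character(), provenance = character(),
                      score_percent = numeric(), library_index = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$score_percent, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Level 2b: rank candidate structures by in-silico fragmentation
#'
#' Candidates incompatible with the precursor m/z (at the MS2 tolerance) are
#' excluded. Each survivor is scored by the fraction of query peak intensity
#' explained by its in-silico bond-breaking fragments plus its diagnostic
#' subclass ions; ties are broken by rule-verdict pass, then by fewer
#' theoretical fragments (parsimony). Candidates whose scores coincide are
#' flagged indistinguishable.
#'
#' @param query an [ms_spectrum()].
#' @param candidates list of [compound_template()]s.
#' @param cfg a [pipeline_config()].
#' @param max_breaks bond-break depth for [insilico_fragments()].
#' @return data.frame: `name`, `skeleton`, `formula`, `explained_intensity`,
#'   `rule_pass`, `n_fragments`, `indistinguishable`.
#' @export
rank_level2b <- function(query, candidates, cfg = pipeline_config(),
                         max_breaks = 2L) {
  rows <- list()
  for (t in candidates) {
    th <- ion_mz(compound_formula(t), "[M+H]+")
    if (abs(th - query$precursor_mz) > cfg$ms2_tol_mda / 1000) next
    frags <- insilico_fragments(t, max_breaks)
    diag <- .diagnostic_ions(t)
    frag_mz <- c(vapply(frags$formula,
                        function(f) ion_mz(f, "cation"), numeric(1)),
                 diag$mz)
    matched <- vapply(query$peaks$mz, function(m)
      any(abs(frag_mz - m) <= cfg$ms2_tol_mda / 1000), logical(1))
    explained <- sum(query$peaks$intensity[matched]) /
      sum(query$peaks$intensity)
    verdict <- verify_annotation(query, t, cfg$ms2_tol_mda)
    rows[[length(rows) + 1L]] <- data.frame(
      name = t$name, skeleton = t$skeleton,
      formula = format_formula(compound_formula(t)),
      explained_intensity = explained, rule_pass = verdict$pass,
      n_fragments = nrow(frags), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(name = character(), skeleton = character(),
                      formula = character(), explained_intensity = numeric(),
                      rule_pass = logical(), n_fragments = integer(),
                      indistinguishable = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$explained_intensity, -out$rule_pass,
                   out$n_fragments, out$name), , drop = FALSE]
  out$indistinguishable <- duplicated(out$explained_intensity) |
    duplicated(out$explained_intensity, fromLast = TRUE)
  rownames(out) <- NULL
  out
}

#' Assemble the evidence bundle for one query
#'
#' @param query_id query identifier.
#' @param level1 result of [match_level1()] (or `NULL`).
#' @param level2a result of [search_level2a()].
#' @param level2b result of [rank_level2b()].
#' @param formulas formula candidates from [decompose_mass()].
#' @param tree a `fragmentation_tree` or `NULL`.
#' @param classification result of [classify_spectrum()] or `NULL`.
#' @return An `evidence_bundle` list.
#' @export
evidence_bundle <- function(query_id, level1 = NULL,
                            level2a = NULL, level2b = NULL,
                            formulas = NULL, tree = NULL,
                            classification = NULL) {
  structure(list(query_id = query_id, level1 = level1, level2a = level2a,
                 level2b = level2b, formulas = formulas, tree = tree,
                 classification = classification),
            class = "evidence_bundle")
}

#' Assign a Schymanski confidence level from evidence
#'
#' Precedence: level 1 (standard match) over 2a (library hit at/above
#' cutoff) over 2b (candidate passing rule verification) over 3 (formula +
#' fragmentation tree + subclass ranking, a candidate set rather than one
#' structure) over 4 (unique formula) over 5 (exact mass only).
#'
#' @param ev an [evidence_bundle()].
#' @param cfg a [pipeline_config()].
#' @return An `annotation_result` list: `query_id`, `level`, `best`,
#'   `score_percent`, `evidence`.
#' @export
assign_level <- function(ev, cfg = pipeline_config()) {
  res <- function(level, best, score = NA_real_)
    structure(list(query_id = ev$query_id, level = level, best = best,
                   score_percent = score, evidence = ev),
              class = "annotation_result")
  if (!is.null(ev$level1))
    return(res("1", ev$level1$record$name))
  if (!is.null(ev$level2a) && nrow(ev$level2a) > 0L)
    return(res("2a", ev$level2a$name[1], ev$level2a$score_percent[1]))
  if (!is.null(ev$level2b) && nrow(ev$level2b) > 0L &&
      any(ev$level2b$rule_pass)) {
    top <- ev$level2b[ev$level2b$rule_pass, , drop = FALSE][1, ]
    best <- top$name
    # report tied flavanone/chalcone pairs jointly
    tied <- ev$level2b$name[ev$level2b$rule_pass &
                            ev$level2b$indistinguishable &
                            abs(ev$level2b$explained_intensity -
                                top$explained_intensity) < 1e-12]
    if (length(tied) > 1L) best <- paste(sort(tied), collapse = " | ")
    return(res("2b", best, 100 * top$explained_intensity))
  }
  has_formula <- !is.null(ev$formulas) && nrow(ev$formulas) > 0L
  has_ranking <- !is.null(ev$classification) &&
    nrow(ev$classification$ranking) > 0L
  if (has_formula && !is.null(ev$tree) && has_ranking)
    return(res("3", paste0(ev$formulas$formula[1], " (",
                           ev$classification$ranking$subclass[1], ")")))
  if (has_formula && nrow(ev$formulas) == 1L)
    return(res("4", ev$formulas$formula[1]))
  return(res("5", NA_character_))
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("<annotation_result> %s: level %s%s%s\n", x$query_id, x$level,
              if (is.na(x$best)) "" else paste0("  ", x$best),
              if (is.na(x$score_percent)) "" else
                sprintf("  (%.1f%%)", x$score_percent)))
  invisible(x)
}

#' Promote high-scoring level-2a results to quasi-reference records
#'
#' Level-2a annotations whose top score strictly exceeds the quasi-reference
#' cutoff are re-emitted as library records with provenance
#' `"quasi-reference-2a"`; level-1 results are already backed by standards
#' and are never promoted.
#'
#' @param results list of `annotation_result`s.
#' @param queries named list of the query spectra (by query id).
#' @param cfg a [pipeline_config()].
#' @return List of [library_record()]s.
#' @export
promote_quasi_reference <- function(results, queries,
                                    cfg = pipeline_config()) {
  out <- list()
  for (r in results) {
    if (!identical(r$level, "2a")) next
    if (!(r$score_percent > cfg$quasi_cutoff)) next
    hit <- r$evidence$level2a[1, ]
    sp <- queries[[r$query_id]]
    out[[length(out) + 1L]] <- library_record(
      sp, name = hit$name, formula = hit$formula,
      subclass = hit$subclass, provenance = "quasi-reference-2a")
  }
  out
}

# Validate an annotation at levels 2a-3 against the subclass rules: does the
# claimed subclass (equivalence class) appear in the rule-based ranking?
.rule_validate <- function(query, formula, claimed_subclass, tol_mda) {
  if (is.na(claimed_subclass) || is.na(formula)) return(NA)
  cls <- try(classify_spectrum(query, formula, tol_mda), silent = TRUE)
  if (inherits(cls, "try-error")) return(NA)
  subclass_equivalence(claimed_subclass) %in%
    subclass_equivalence(cls$ranking$subclass)
}

#' Run the full multi-tier annotation pipeline
#'
#' For every query, evidence is gathered in level order (1, 2a, 2b, 3), the
#' Schymanski level assigned, and the claimed subclass of level-2a/2b/3
#' annotations validated against the fragmentation rules. One failing query
#' is reported as such and never aborts the batch. Output ordering is
#' deterministic (by query id).
#'
#' @param queries list of [ms_spectrum()] queries.
#' @param standards list of [library_record()]s with retention times.
#' @param library list of [library_record()]s (spectral library).
#' @param candidates list of [compound_template()]s (structure database).
#' @param cfg a [pipeline_config()].
#' @param decompose_bounds element bounds for de novo formula annotation.
#' @return List with `results` (annotation results, by query id) and
#'   `report` (one data.frame row per query: id, level, best candidate,
#'   score, subclass, rule validation, tree-loss summary, formula count).
#' @export
run_pipeline <- function(queries, standards, library, candidates,
                         cfg = pipeline_config(),
                         decompose_bounds = c(C = 30, H = 40, O = 10)) {
  ids <- vapply(queries, function(q) q$id, character(1))
  queries <- queries[order(ids)]
  results <- list()
  rows <- list()
  for (q in queries) {
    row <- data.frame(query_id = q$id, level = "error",
                      best_candidate = NA_character_,
                      score_percent = NA_real_, subclass = NA_character_,
                      rule_validated = NA, tree_losses = NA_character_,
                      n_formula_candidates = NA_integer_,
                      stringsAsFactors = FALSE)
    res <- try({
      l1 <- suppressWarnings(match_level1(q, standards, cfg))
      l2a <- NULL; l2b <- NULL; formulas <- NULL; tree <- NULL; cls <- NULL
      subclass <- NA_character_; validated <- NA
      if (is.null(l1)) {
        l2a <- search_level2a(q, library, cfg)
        if (nrow(l2a) == 0L) {
          l2b <- rank_level2b(q, candidates, cfg)
          if (!(nrow(l2b) > 0L && any(l2b$rule_pass))) {
            formulas <- decompose_mass(q$precursor_mz, "[M+H]+",
                                       cfg$ms1_tol_mda, decompose_bounds)
            # de novo engines consider several formula candidates; try up to
            # 10 and keep the first that yields a subclass ranking
            for (fi in seq_len(min(nrow(formulas), 10L))) {
              f <- formulas$formula[fi]
              cls_i <- try(classify_spectrum(q, f, cfg$ms2_tol_mda),
                           silent = TRUE)
              if (inherits(cls_i, "try-error") ||
                  nrow(cls_i$ranking) == 0L) next
              tree_i <- try(fragmentation_tree(q, f, cfg$ms2_tol_mda),
                            silent = TRUE)
              if (inherits(tree_i, "try-error")) next
              cls <- cls_i; tree <- tree_i
              break
            }
            if (is.null(tree) && nrow(formulas) > 0L) {
              tree <- try(fragmentation_tree(q, formulas$formula[1],
                                             cfg$ms2_tol_mda), silent = TRUE)
              if (inherits(tree, "try-error")) tree <- NULL
            }
          }
        }
      }
      ev <- evidence_bundle(q$id, level1 = l1, level2a = l2a, level2b = l2b,
                            formulas = formulas, tree = tree,
                            classification = cls)
      r <- assign_level(ev, cfg)
      # subclass + rule validation for levels 2a-3
      if (r$level == "2a") {
        subclass <- l2a$subclass[1]
        validated <- .rule_validate(q, l2a$formula[1], subclass,
                                    cfg$ms2_tol_mda)
      } else if (r$level == "2b") {
        top <- l2b[l2b$rule_pass, , drop = FALSE][1, ]
        subclass <- top$skeleton
        validated <- TRUE  # 2b assignment already requires a rule pass
      } else if (r$level == "3" && !is.null(cls) &&
                 nrow(cls$ranking) > 0L) {
        subclass <- cls$ranking$subclass[1]
        validated <- TRUE
      }
      row$level <- r$level
      row$best_candidate <- r$best
      row$score_percent <- r$score_percent
      row$subclass <- subclass
      row$rule_validated <- validated
      row$n_formula_candidates <- if (is.null(formulas)) NA_integer_ else
        nrow(formulas)
      if (!is.null(tree))
        row$tree_losses <- paste(tree_losses(tree), collapse = ",")
      r
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      row$level <- "error"
      row$best_candidate <- conditionMessage(attr(res, "condition"))
      results[[q$id]] <- NULL
    } else {
      results[[q$id]] <- res
    }
    rows[[q$id]] <- row
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(), level = character(),
               best_candidate = character(), score_percent = numeric(),
               subclass = character(), rule_validated = logical(),
               tree_losses = character(), n_formula_candidates = integer(),
               stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(results = results, report = report)
}

#' Write a pipeline report as TSV
#'
#' @param report report data.frame from [run_pipeline()].
#' @param path output path.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
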