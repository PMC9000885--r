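# Fragmentation trees: peaks annotated with subformulas of the precursor
# cation, connected by neutral-loss edges. The tree is built with a
# best-parent heuristic (each node attaches to the cheapest heavier node),
# which always yields a tree because edges point down-mass; it serves as a
# readable neutral-loss summary, not an exhaustively optimized tree.

#' Default common neutral losses
#'
#' CO, H2O, CH2O, C2H2O, CH3 (methyl radical), CH4, CO2 and the styryl C8H8
#' loss; edges explicable by at most two of these are preferred when
#' attaching nodes.
#' @return Character vector of loss formulas.
#' @export
common_losses <- function() {
  c("CO", "H2O", "CH2O", "C2H2O", "CH3", "CH4", "CO2", "C8H8")
}

#' Annotate fragment peaks with subformulas of the precursor
#'
#' Every subformula of the precursor cation is a candidate fragment formula;
#' each peak is assigned the candidate minimizing the absolute mass error
#' within tolerance, or left unannotated. The precursor itself is always
#' present as the root node (zero loss), whether or not a peak sits on it.
#'
#' @param spectrum an [ms_spectrum()].
#' @param precursor_formula neutral formula of the precursor; its `[M+H]+`
#'   m/z must agree with the spectrum's precursor m/z within `tol_mda`.
#' @param tol_mda annotation tolerance in mDa.
#' @return List with `nodes` (data.frame: mz, intensity, formula, error_mda,
#'   is_root) and `unannotated` (data.frame of unassigned peaks).
#' @export
annotate_peaks <- function(spectrum, precursor_formula, tol_mda = 10) {
  if (is.character(precursor_formula))
    precursor_formula <- parse_formula(precursor_formula)
  prec_cat <- formula_add(precursor_formula, chem_formula(H = 1L))
  prec_mz <- ion_mz(prec_cat, "cation")
  if (abs(prec_mz - spectrum$precursor_mz) > tol_mda / 1000)
    stop(sprintf("precursor formula %s inconsistent with precursor m/z %.4f",
                 format_formula(precursor_formula), spectrum$precursor_mz))
  v <- .as_formula_vec(prec_cat)
  grid <- expand.grid(C = 0:v[1], H = 0:v[2], O = 0:v[3])
  # organic fragment cations only: at least one carbon, H within the CHO
  # saturation bound (rules out bare HxOy compositions)
  grid <- grid[grid$C >= 1 & grid$H <= 2 * grid$C + 2, , drop = FALSE]
  masses <- grid$C * .ELEMENT_MASS[["C"]] + grid$H * .ELEMENT_MASS[["H"]] +
    grid$O * .ELEMENT_MASS[["O"]] - ELECTRON_MASS
  peaks <- spectrum$peaks
  assigned <- data.frame(mz = numeric(), intensity = numeric(),
                         formula = character(), error_mda = numeric(),
                         is_root = logical(), stringsAsFactors = FALSE)
  un <- peaks[0, , drop = FALSE]
  root_taken <- FALSE
  for (i in seq_len(nrow(peaks))) {
    d <- abs(masses - peaks$mz[i])
    j <- which.min(d)
    if (d[j] <= tol_mda / 1000) {
      f <- chem_formula(C = grid$C[j], H = grid$H[j], O = grid$O[j])
      is_root <- f == prec_cat
      if (is_root) root_taken <- TRUE
      assigned <- rbind(assigned, data.frame(
        mz = peaks$mz[i], intensity = peaks$intensity[i],
        formula = format_formula(f),
        error_mda = 1000 * (peaks$mz[i] - masses[j]),
        is_root = is_root, stringsAsFactors = FALSE))
    } else {
      un <- rbind(un, peaks[i, , drop = FALSE])
    }
  }
  if (!root_taken) {
    assigned <- rbind(data.frame(
      mz = prec_mz, intensity = 0,
      formula = format_formula(prec_cat), error_mda = 0,
      is_root = TRUE, stringsAsFactors = FALSE), assigned)
  }
  rownames(assigned) <- NULL; rownames(un) <- NULL
  list(nodes = assigned, unannotated = un)
}

# Is `loss` a composition of at most two allowed losses?
# Returns the number of radical (CH3) losses used, or -1 when inexplicable.
.loss_composition <- function(loss_str, allowed) {
  if (loss_str %in% allowed) return(as.integer(loss_str == "CH3"))
  lf <- parse_formula(loss_str)
  for (i in seq_along(allowed)) for (j in i:length(allowed)) {
    s <- formula_add(parse_formula(allowed[i]), parse_formula(allowed[j]))
    if (s == lf)
      return(sum(c(allowed[i], allowed[j]) == "CH3"))
  }
  -1L
}

#' Build a fragmentation tree from annotated nodes
#'
#' Each non-root node attaches to the candidate parent (any node with a
#' containing formula and larger m/z) minimizing edge cost: losses that are a
#' composition of at most two common losses cost 0, others cost 1; ties are
#' broken by smaller loss mass, then by the parent's smaller mass error, then
#' by input order. Methyl-radical losses are limited to one per root-to-leaf
#' path (even-electron rule) unless `allow_multiple_radicals`.
#'
#' @param nodes node table from [annotate_peaks()].
#' @param losses common-loss formulas, default [common_losses()].
#' @param allow_multiple_radicals permit more than one CH3 loss per path.
#' @return A `fragmentation_tree`: list with `nodes` and `edges`
#'   (parent/child indexes, loss formula, loss mass) tables.
#' @export
build_tree <- function(nodes, losses = common_losses(),
                       allow_multiple_radicals = FALSE) {
  if (!any(nodes$is_root)) stop("build_tree: no root node present")
  ord <- order(-nodes$mz, abs(nodes$error_mda), seq_len(nrow(nodes)))
  nodes <- nodes[ord, , drop = FALSE]
  rownames(nodes) <- NULL
  root <- which(nodes$is_root)[1]
  if (root != 1L) {  # root must be the heaviest node
    nodes <- nodes[c(root, setdiff(seq_len(nrow(nodes)), root)), ,
                   drop = FALSE]
    root <- 1L
  }
  fvecs <- lapply(nodes$formula, parse_formula)
  n <- nrow(nodes)
  parent <- rep(NA_integer_, n)
  radical_on_path <- rep(0L, n)
  edge_loss <- character(n)
  for (i in seq_len(n)) {
    if (i == root) next
    best <- NULL
    for (j in seq_len(n)) {
      if (j == i) next
      if (!(nodes$mz[j] > nodes$mz[i] ||
            (nodes$mz[j] == nodes$mz[i] && j < i))) next
      if (is.na(parent[j]) && j != root) next  # attach only to placed nodes
      if (!is_subformula(fvecs[[i]], fvecs[[j]])) next
      loss <- formula_diff(fvecs[[j]], fvecs[[i]])
      if (is_zero_formula(loss)) next
      loss_str <- format_formula(loss)
      rad <- .loss_composition(loss_str, losses)
      cost <- if (rad >= 0L) 0L else 1L
      n_rad <- max(rad, 0L)
      if (!allow_multiple_radicals && radical_on_path[j] + n_rad > 1L) {
        # would break the even-electron rule; treat as expensive edge
        cost <- 1L
        n_rad <- 0L
      }
      cand <- list(j = j, cost = cost, loss = loss_str,
                   loss_mass = monoisotopic_mass(loss), n_rad = n_rad)
      if (is.null(best) || cand$cost < best$cost ||
          (cand$cost == best$cost && cand$loss_mass < best$loss_mass))
        best <- cand
    }
    if (is.null(best)) {  # should not happen: root contains every node
      best <- list(j = root, cost = 1L,
                   loss = format_formula(formula_diff(fvecs[[root]], fvecs[[i]])),
                   loss_mass = monoisotopic_mass(
                     formula_diff(fvecs[[root]], fvecs[[i]])), n_rad = 0L)
    }
    parent[i] <- best$j
    edge_loss[i] <- best$loss
    radical_on_path[i] <- radical_on_path[best$j] + best$n_rad
  }
  edges <- data.frame(
    parent = parent[-root], child = setdiff(seq_len(n), root),
    parent_mz = nodes$mz[parent[-root]], child_mz = nodes$mz[-root],
    loss = edge_loss[-root],
    loss_mass = vapply(edge_loss[-root],
                       function(s) monoisotopic_mass(parse_formula(s)),
                       numeric(1)),
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, root = root),
            class = "fragmentation_tree")
}

#' Convenience: annotate a spectrum and build its fragmentation tree
#'
#' @inheritParams annotate_peaks
#' @param losses common-loss formulas for [build_tree()].
#' @return A `fragmentation_tree` with the unannotated peaks attached as
#'   attribute `"unannotated"`.
#' @export
fragmentation_tree <- function(spectrum, precursor_formula, tol_mda = 10,
                               losses = common_losses()) {
  ann <- annotate_peaks(spectrum, precursor_formula, tol_mda)
  tree <- build_tree(ann$nodes, losses)
  attr(tree, "unannotated") <- ann$unannotated
  tree
}

#' Neutral losses of a fragmentation tree
#'
#' @param tree a `fragmentation_tree`.
#' @return Character vector (multiset) of edge loss formulas.
#' @export
tree_losses <- function(tree) tree$edges$loss

#' @export
print.fragmentation_tree <- function(x, ...) {
  cat("<fragmentation_tree> ", nrow(x$nodes), " nodes\n", sep = "")
  recurse <- function(i, depth) {
    ind <- strrep("  ", depth)
    loss <- if (i == x$root) "" else {
      e <- x$edges[x$edges$child == i, ]
      sprintf("  -%s (%.4f)", e$loss, e$loss_mass)
    }
    cat(sprintf("%s%.4f %s%s\n", ind, x$nodes$mz[i], x$nodes$formula[i], loss))
    for (ch in x$edges$child[x$edges$parent == i]) recurse(ch, depth + 1L)
  }
  recurse(x$root, 0L)
  invisible(x)
}

#' Tabular edge list of a fragmentation tree
#'
#' @param tree a `fragmentation_tree`.
#' @return data.frame: parent m/z, child m/z, loss formula, loss mass.
#' @export
tree_edge_table <- function(tree) {
  tree$edges[, c("parent_mz", "child_mz", "loss", "loss_mass")]
}
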