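# Bonded-atom graphs and MetFrag-style iterative bond breaking. Graphs carry
# explicit per-atom hydrogen counts, so fragment formulas are exact element
# inventories without valence bookkeeping.

.graph_env <- new.env(parent = emptyenv())

.load_graphs <- function() {
  if (!is.null(.graph_env$graphs)) return(.graph_env$graphs)
  path <- system.file("extdata", "skeleton_graphs.yaml",
                      package = "flavotier", mustWork = TRUE)
  g <- yaml::read_yaml(path)$graphs
  reg <- skeleton_registry()
  for (id in names(g)) {
    gf <- .graph_formula(g[[id]])
    if (!(gf == reg[[id]]$scaffold_formula))
      stop("skeleton graph '", id, "' implies ", format_formula(gf),
           " but the registry scaffold is ",
           format_formula(reg[[id]]$scaffold_formula))
  }
  .graph_env$graphs <- g
  g
}

.graph_formula <- function(g, which_atoms = NULL) {
  atoms <- g$atoms
  if (!is.null(which_atoms)) atoms <- atoms[which_atoms]
  el <- vapply(atoms, function(a) a$el, character(1))
  h <- sum(vapply(atoms, function(a) a$h, numeric(1)))
  chem_formula(C = sum(el == "C"), H = as.integer(h),
               O = sum(el == "O"), Na = sum(el == "Na"))
}

#' Bonded-atom graph of a compound template
#'
#' Builds the molecular graph of a template: the skeleton's scaffold graph
#' with substituents attached as explicit atoms at the skeleton's
#' substitutable ring positions (an attachment consumes one ring hydrogen).
#'
#' @param t a [compound_template()].
#' @return A `mol_graph` list with `atoms` (element, hydrogen count) and
#'   `bonds` (2-column index matrix); its formula equals
#'   [compound_formula()].
#' @export
template_graph <- function(t) {
  g <- .load_graphs()[[t$skeleton]]
  if (is.null(g)) stop("no graph registered for skeleton '", t$skeleton, "'")
  atoms <- g$atoms
  bonds <- do.call(rbind, g$bonds)
  free <- g$attach
  for (region in c("ringA", "ringB", "ringC")) {
    slots <- unlist(free[[region]])
    counts <- t$subs[[region]]
    n_needed <- sum(counts)
    if (n_needed == 0L) next
    if (n_needed > length(slots))
      stop("template '", t$name, "': ", n_needed, " substituents on ",
           region, " but only ", length(slots), " positions on skeleton '",
           t$skeleton, "'")
    k <- 0L
    for (s in c("oh", "ome", "me")) {
      for (i in seq_len(counts[[s]])) {
        k <- k + 1L
        at <- slots[k]
        if (atoms[[at]]$h < 1L)
          stop("template '", t$name, "': position ", at, " has no free H")
        atoms[[at]]$h <- atoms[[at]]$h - 1L
        if (s == "oh") {
          atoms[[length(atoms) + 1L]] <- list(el = "O", h = 1L)
          bonds <- rbind(bonds, c(at, length(atoms)))
        } else if (s == "ome") {
          atoms[[length(atoms) + 1L]] <- list(el = "O", h = 0L)
          o <- length(atoms)
          atoms[[length(atoms) + 1L]] <- list(el = "C", h = 3L)
          bonds <- rbind(bonds, c(at, o), c(o, length(atoms)))
        } else {
          atoms[[length(atoms) + 1L]] <- list(el = "C", h = 3L)
          bonds <- rbind(bonds, c(at, length(atoms)))
        }
      }
    }
  }
  structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d atoms, %d bonds\n",
              format_formula(.graph_formula(x)), length(x$atoms),
              nrow(x$bonds)))
  invisible(x)
}

#' In-silico fragment formulas by iterative bond breaking
#'
#' Deletes up to `max_breaks` bonds (one bridge, or a pair of bonds whose
#' joint removal disconnects the graph, i.e. a ring opening) and collects the
#' connected components. Each fragment is emitted together with
#' hydrogen-transfer variants at -1, 0 and +1 H, the standard allowance for
#' rearrangement during collision-induced fragmentation.
#'
#' @param graph a `mol_graph` (from [template_graph()]) or a
#'   [compound_template()].
#' @param max_breaks 0, 1 or 2.
#' @return data.frame with columns `formula` (element inventory including the
#'   H variant), `h_shift`, `n_breaks`; unique rows, whole molecule included
#'   at `n_breaks = 0`.
#' @export
insilico_fragments <- function(graph, max_breaks = 2L) {
  if (inherits(graph, "compound_template")) graph <- template_graph(graph)
  stopifnot(inherits(graph, "mol_graph"), max_breaks %in% 0:2)
  n <- length(graph$atoms)
  ig <- igraph::graph_from_edgelist(graph$bonds, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, n - igraph::vcount(ig)))
  if (igraph::components(ig)$no != 1L)
    stop("insilico_fragments: input graph is disconnected")
  frag_sets <- list(list(atoms = seq_len(n), breaks = 0L))
  collect <- function(g2, k) {
    comp <- igraph::components(g2)
    if (comp$no < 2L) return(list())
    lapply(split(seq_len(n), comp$membership),
           function(a) list(atoms = a, breaks = k))
  }
  if (max_breaks >= 1L) {
    nb <- nrow(graph$bonds)
    bridges <- which(vapply(seq_len(nb), function(i) {
      igraph::components(igraph::delete_edges(ig, i))$no > 1L
    }, logical(1)))
    for (i in bridges)
      frag_sets <- c(frag_sets, collect(igraph::delete_edges(ig, i), 1L))
    if (max_breaks == 2L && nb >= 2L) {
      # all bond pairs: two acyclic bonds, or a pair opening one ring
      prs <- utils::combn(seq_len(nb), 2L)
      for (k in seq_len(ncol(prs))) {
        g2 <- igraph::delete_edges(ig, prs[, k])
        frag_sets <- c(frag_sets, collect(g2, 2L))
      }
    }
  }
  rows <- list()
  seen <- character(0)
  for (fs in frag_sets) {
    f0 <- .graph_formula(graph, fs$atoms)
    for (h in -1:1) {
      f <- .apply_h_offset(f0, h)
      if (is.null(f) || is_zero_formula(f)) next
      key <- format_formula(f)
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- data.frame(
        formula = key, h_shift = h, n_breaks = fs$breaks,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
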