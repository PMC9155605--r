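#' Molecular heavy-atom graphs
#'
#' Molecules are represented as unweighted, undirected graphs whose nodes
#' are heavy atoms and whose edges are covalent bonds.  Hydrogens are not
#' graph nodes; each heavy atom carries its attached-hydrogen count.
#' Atom indices follow the 0-based convention: `atoms$index` runs
#' `0..n-1` and `bonds$from`/`bonds$to` refer to those indices.
#'
#' @param x object to test or print.
#' @name molecular_graph
NULL

.new_molecular_graph <- function(atoms, bonds, smiles = NA_character_,
                                 pattern = FALSE) {
  n <- nrow(atoms)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(bonds) > 0L) {
    g <- igraph::add_edges(g, rbind(bonds$i, bonds$j))
  }
  comp <- igraph::components(g)$membership - 1L
  structure(
    list(
      atoms = data.frame(
        index = seq_len(n) - 1L,
        element = atoms$element,
        charge = atoms$charge,
        hcount = atoms$hcount,
        aromatic = atoms$aromatic,
        stringsAsFactors = FALSE
      ),
      bonds = data.frame(
        from = bonds$i - 1L,
        to = bonds$j - 1L,
        order = bonds$order,
        aromatic = bonds$aromatic
      ),
      component_ids = as.integer(comp),
      smiles = smiles,
      pattern = pattern
    ),
    class = "molecular_graph"
  )
}

#' @rdname molecular_graph
#' @export
is_molecular_graph <- function(x) inherits(x, "molecular_graph")

#' @rdname molecular_graph
#' @param ... ignored.
#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf(
    "<molecular_graph> %d atoms, %d bonds, %d component(s)%s\n",
    n_atoms(x), nrow(x$bonds), n_components(x),
    if (!is.na(x$smiles)) sprintf(" [%s]", x$smiles) else ""
  ))
  invisible(x)
}

#' @rdname molecular_graph
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' @rdname molecular_graph
#' @export
n_components <- function(x) {
  if (n_atoms(x) == 0L) 0L else max(x$component_ids) + 1L
}

## igraph view with vertex/edge attributes (1-based vertex ids).
as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n_atoms(graph), directed = FALSE)
  if (nrow(graph$bonds) > 0L) {
    g <- igraph::add_edges(g, rbind(graph$bonds$from + 1L, graph$bonds$to + 1L))
    igraph::E(g)$order <- graph$bonds$order
    igraph::E(g)$aromatic <- graph$bonds$aromatic
  }
  igraph::V(g)$element <- graph$atoms$element
  igraph::V(g)$aromatic <- graph$atoms$aromatic
  igraph::V(g)$charge <- graph$atoms$charge
  g
}

## Integer colour encodings shared by the fragment miner and VF2 matching.
## Charge-insensitive by default: matching respects element and aromatic
## flag on atoms, order and aromatic flag on bonds.
.atom_colors <- function(graph) {
  elt <- match(graph$atoms$element, .known_elements)
  as.integer(elt * 2L + as.integer(graph$atoms$aromatic))
}

.bond_colors <- function(graph) {
  as.integer(ifelse(graph$bonds$aromatic, 4L, graph$bonds$order))
}

#' Retain only the largest connected component of a molecule
#'
#' Salts and mixtures parse to multi-component graphs; featurization keeps
#' the largest component (by heavy-atom count, ties broken by lowest
#' component id) so that all-pairs distances are finite.
#'
#' @param graph a `molecular_graph`.
#' @return a `molecular_graph` with a single component.
#' @export
keep_largest_component <- function(graph) {
  if (n_components(graph) <= 1L) return(graph)
  sizes <- tabulate(graph$component_ids + 1L)
  keep <- which.max(sizes) - 1L
  hs_log("multi-component molecule: keeping largest component (%d of %d atoms)",
         sizes[[keep + 1L]], n_atoms(graph), level = "info")
  sel <- graph$component_ids == keep
  old_idx <- graph$atoms$index[sel]
  remap <- setNames(seq_along(old_idx), old_idx)   # old 0-based -> new 1-based
  atoms <- graph$atoms[sel, , drop = FALSE]
  bk <- graph$bonds$from %in% old_idx & graph$bonds$to %in% old_idx
  bonds <- graph$bonds[bk, , drop = FALSE]
  .new_molecular_graph(
    atoms = data.frame(element = atoms$element, aromatic = atoms$aromatic,
                       charge = atoms$charge, hcount = atoms$hcount,
                       bracket = TRUE, stringsAsFactors = FALSE),
    bonds = data.frame(i = unname(remap[as.character(bonds$from)]),
                       j = unname(remap[as.character(bonds$to)]),
                       order = bonds$order, aromatic = bonds$aromatic),
    smiles = NA_character_,
    pattern = graph$pattern
  )
}
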