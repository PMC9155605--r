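#' Render a molecular graph as a SMILES string
#'
#' Writes a SMILES rendering by depth-first traversal.  For molecule
#' graphs, atoms are written as plain organic-subset tokens whenever a
#' re-parse would infer the same hydrogen count, and as bracket atoms
#' otherwise, so that parse -> write -> parse round-trips the graph.  For
#' pattern graphs (substructure fragments), hydrogen counts are omitted:
#' fragment strings are SMILES-like patterns in which aromatic atoms may
#' appear outside complete rings, as in SMARTS.
#'
#' @param graph a `molecular_graph`.
#' @param priority optional numeric vector (one per atom) controlling the
#'   traversal: lower priority atoms are visited first.  Defaults to input
#'   atom order, which makes the output deterministic.
#' @return a single SMILES string.
#' @seealso [random_smiles()] for randomised renderings.
#' @export
write_smiles <- function(graph, priority = NULL) {
  n <- n_atoms(graph)
  if (n == 0L) contract_error("cannot write SMILES for an empty graph")
  if (is.null(priority)) priority <- seq_len(n)
  if (length(priority) != n) contract_error("priority length must equal atom count")

  from <- graph$bonds$from + 1L
  to <- graph$bonds$to + 1L
  adj <- vector("list", n)
  for (k in seq_along(from)) {
    adj[[from[k]]] <- rbind(adj[[from[k]]], c(to[k], k))
    adj[[to[k]]] <- rbind(adj[[to[k]]], c(from[k], k))
  }

  visited <- logical(n)
  visit_time <- integer(n)
  clock <- 0L
  parent_edge <- integer(n)
  children <- vector("list", n)
  seen_edge <- logical(length(from))
  roots <- integer(0)

  rec <- function(v) {
    visited[[v]] <<- TRUE
    clock <<- clock + 1L
    visit_time[[v]] <<- clock
    nb <- adj[[v]]
    if (is.null(nb)) return(invisible(NULL))
    ord <- order(priority[nb[, 1L]])
    for (r in ord) {
      w <- nb[r, 1L]; bidx <- nb[r, 2L]
      if (seen_edge[[bidx]]) next
      seen_edge[[bidx]] <<- TRUE
      if (!visited[[w]]) {
        parent_edge[[w]] <<- bidx
        children[[v]] <<- c(children[[v]], w)
        rec(w)
      } else {
        back_edges <<- c(back_edges, bidx)
      }
    }
    invisible(NULL)
  }

  back_edges <- integer(0)
  for (v in order(priority)) {
    if (!visited[[v]]) { roots <- c(roots, v); rec(v) }
  }

  ## Ring-closure digit assignment: opener = earlier-visited end.
  closures <- vector("list", n)         # per vertex: list of (digit, bond, open)
  if (length(back_edges) > 0L) {
    op <- ifelse(visit_time[from[back_edges]] <= visit_time[to[back_edges]],
                 from[back_edges], to[back_edges])
    cl <- ifelse(op == from[back_edges], to[back_edges], from[back_edges])
    ord <- order(visit_time[op], visit_time[cl])
    for (d in seq_along(ord)) {
      k <- ord[[d]]
      closures[[op[[k]]]] <- c(closures[[op[[k]]]],
                               list(list(digit = d, bond = back_edges[[k]], open = TRUE)))
      closures[[cl[[k]]]] <- c(closures[[cl[[k]]]],
                               list(list(digit = d, bond = back_edges[[k]], open = FALSE)))
    }
  }

  bond_sym <- function(bidx) {
    if (graph$bonds$aromatic[[bidx]]) return("")
    ord <- graph$bonds$order[[bidx]]
    u <- from[[bidx]]; v <- to[[bidx]]
    if (ord == 1L) {
      if (graph$atoms$aromatic[[u]] && graph$atoms$aromatic[[v]]) "-" else ""
    } else if (ord == 2L) "=" else "#"
  }

  digit_tok <- function(d) if (d > 9L) sprintf("%%%02d", d) else as.character(d)

  emit <- function(v) {
    out <- atom_token(graph, v)
    for (clo in closures[[v]]) {
      out <- paste0(out,
                    if (!clo$open) bond_sym(clo$bond) else "",
                    digit_tok(clo$digit))
    }
    kids <- children[[v]]
    if (length(kids) > 0L) {
      for (idx in seq_along(kids)) {
        w <- kids[[idx]]
        part <- paste0(bond_sym(parent_edge[[w]]), emit(w))
        out <- if (idx < length(kids)) paste0(out, "(", part, ")")
               else paste0(out, part)
      }
    }
    out
  }

  paste(vapply(roots, emit, character(1)), collapse = ".")
}

atom_token <- function(graph, v) {
  el <- graph$atoms$element[[v]]
  arom <- graph$atoms$aromatic[[v]]
  chg <- graph$atoms$charge[[v]]
  h <- graph$atoms$hcount[[v]]
  sym <- if (arom) tolower(el) else el
  plain_ok <- if (arom) tolower(el) %in% .organic_aromatic else el %in% .organic_aliphatic
  plain_ok <- plain_ok && chg == 0L
  if (plain_ok && !graph$pattern) {
    ## plain token legal only if a re-parse infers the same H count
    inferred <- .reinferred_h(graph, v)
    plain_ok <- !is.na(h) && inferred == h
  }
  if (plain_ok) return(sym)
  hpart <- if (graph$pattern || is.na(h) || h == 0L) ""
           else if (h == 1L) "H" else paste0("H", h)
  cpart <- if (chg == 0L) ""
           else if (chg == 1L) "+"
           else if (chg == -1L) "-"
           else sprintf("%+d", chg)
  paste0("[", sym, hpart, cpart, "]")
}

.reinferred_h <- function(graph, v) {
  idx <- v - 1L
  inc <- graph$bonds$from == idx | graph$bonds$to == idx
  used <- sum(ifelse(graph$bonds$aromatic[inc], 1, graph$bonds$order[inc])) +
    if (graph$atoms$aromatic[[v]]) 1 else 0
  vals <- .default_valences[[graph$atoms$element[[v]]]]
  if (is.null(vals)) return(0L)
  fit <- vals[vals >= used]
  if (length(fit) == 0L) 0L else as.integer(fit[[1L]] - used)
}

#' Random SMILES renderings of a molecule
#'
#' Generates alternative, non-canonical SMILES strings for the same
#' molecule by randomising the atom traversal order.  Used to exercise the
#' permutation invariance of graph signatures.
#'
#' @param graph a `molecular_graph`.
#' @param n number of renderings.
#' @param seed RNG seed (optional).
#' @return character vector of `n` SMILES strings.
#' @export
random_smiles <- function(graph, n = 1L, seed = NULL) {
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      write_smiles(graph, priority = sample(n_atoms(graph)))
    }, character(1))
  })
}
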