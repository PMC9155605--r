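#' Pharmacophore label vocabulary
#'
#' Fixed, ordered 7-label vocabulary used to categorise atom pairs in
#' graph signatures.  The order defines the feature-vector layout.
#'
#' @export
pharmacophore_labels <- c("Hydrophobic", "Aromatic", "Donor", "Acceptor",
                          "PosIonizable", "NegIonizable", "Neutral")

## Builtin attribute predicates.  Each takes (graph, neighbors list) and
## returns a logical vector over atoms.  `nbrs` is a list of 0-based
## neighbour index vectors.
.builtin_predicates <- list(
  aromatic = function(graph, nbrs) graph$atoms$aromatic,

  ## N/O bearing at least one hydrogen
  hbond_donor = function(graph, nbrs) {
    graph$atoms$element %in% c("N", "O") & graph$atoms$hcount >= 1L
  },

  ## N/O with a lone pair: formal charge <= 0
  hbond_acceptor = function(graph, nbrs) {
    graph$atoms$element %in% c("N", "O") & graph$atoms$charge <= 0L
  },

  ## C, S or halogen not bonded to a formally charged atom
  hydrophobic = function(graph, nbrs) {
    cand <- graph$atoms$element %in% c("C", "S", "F", "Cl", "Br", "I")
    charged_nbr <- vapply(seq_len(n_atoms(graph)), function(v) {
      nb <- nbrs[[v]]
      length(nb) > 0L && any(graph$atoms$charge[nb + 1L] != 0L)
    }, logical(1))
    cand & !charged_nbr
  },

  pos_charge = function(graph, nbrs) graph$atoms$charge > 0L,
  neg_charge = function(graph, nbrs) graph$atoms$charge < 0L,

  ## Aliphatic primary/secondary/tertiary amine nitrogen: neutral,
  ## non-aromatic N, all single bonds, only carbon neighbours, none of
  ## which is a carbonyl/thiocarbonyl carbon (excludes amides).
  aliphatic_amine = function(graph, nbrs) {
    vapply(seq_len(n_atoms(graph)), function(v) {
      at <- graph$atoms[v, ]
      if (at$element != "N" || at$aromatic || at$charge != 0L) return(FALSE)
      idx <- at$index
      inc <- graph$bonds$from == idx | graph$bonds$to == idx
      if (any(graph$bonds$order[inc] > 1L) || any(graph$bonds$aromatic[inc])) {
        return(FALSE)
      }
      nb <- nbrs[[v]]
      if (length(nb) == 0L || length(nb) > 3L) return(FALSE)
      if (!all(graph$atoms$element[nb + 1L] == "C")) return(FALSE)
      !any(vapply(nb, function(c0) .is_acyl_carbon(graph, c0), logical(1)))
    }, logical(1))
  },

  ## Acidic oxygen/sulfur of a carboxylic, sulfonic or phosphonic acid:
  ## O with H (or negative charge) attached to a C/S/P carrying a double
  ## bond to another O.
  acid_group = function(graph, nbrs) {
    vapply(seq_len(n_atoms(graph)), function(v) {
      at <- graph$atoms[v, ]
      if (at$element != "O") return(FALSE)
      if (at$hcount < 1L && at$charge >= 0L) return(FALSE)
      nb <- nbrs[[v]]
      any(vapply(nb, function(c0) {
        graph$atoms$element[[c0 + 1L]] %in% c("C", "S", "P") &&
          .has_double_bonded_o(graph, c0, exclude = at$index)
      }, logical(1)))
    }, logical(1))
  }
)

.neighbors_list <- function(graph) {
  n <- n_atoms(graph)
  nbrs <- vector("list", n)
  for (k in seq_len(nrow(graph$bonds))) {
    f <- graph$bonds$from[[k]]; t <- graph$bonds$to[[k]]
    nbrs[[f + 1L]] <- c(nbrs[[f + 1L]], t)
    nbrs[[t + 1L]] <- c(nbrs[[t + 1L]], f)
  }
  lapply(nbrs, function(x) x %||% integer(0))
}

.is_acyl_carbon <- function(graph, idx) {
  inc <- which((graph$bonds$from == idx | graph$bonds$to == idx) &
                 graph$bonds$order == 2L & !graph$bonds$aromatic)
  length(inc) > 0L && any(vapply(inc, function(k) {
    other <- if (graph$bonds$from[[k]] == idx) graph$bonds$to[[k]]
             else graph$bonds$from[[k]]
    graph$atoms$element[[other + 1L]] %in% c("O", "S")
  }, logical(1)))
}

.has_double_bonded_o <- function(graph, idx, exclude = -1L) {
  inc <- which((graph$bonds$from == idx | graph$bonds$to == idx) &
                 graph$bonds$order == 2L & !graph$bonds$aromatic)
  any(vapply(inc, function(k) {
    other <- if (graph$bonds$from[[k]] == idx) graph$bonds$to[[k]]
             else graph$bonds$from[[k]]
    other != exclude && graph$atoms$element[[other + 1L]] == "O"
  }, logical(1)))
}

#' Default pharmacophore typing rules
#'
#' An ordered table of `(pattern, label)` rules.  Patterns are either
#' builtin attribute predicates (prefixed `@`) or SMILES-like substructure
#' patterns; labels come from [pharmacophore_labels].  Atoms are labelled
#' with the union over all matching rules, so rule order never matters;
#' atoms matching no rule are labelled `Neutral`.
#'
#' @return data frame with columns `pattern`, `label`, `atoms`.
#' @export
default_rule_table <- function() {
  read_rule_table(system.file("extdata", "pharmacophore_rules.txt",
                              package = "herbsig"))
}

#' Read a pharmacophore rule table
#'
#' Plain-text format, one rule per line:
#' `pattern  label  [comma-separated 0-based pattern-atom indices]`.
#' A `pattern` starting with `@` names a builtin attribute predicate;
#' otherwise it is a substructure pattern whose matched atoms (all of
#' them, or only those at the listed positions) receive the label.
#' Invalid patterns or labels raise a configuration error at load time.
#'
#' @param path file path.
#' @return validated rule table data frame.
#' @export
read_rule_table <- function(path) {
  if (!nzchar(path) || !file.exists(path)) {
    config_error(sprintf("rule table '%s' not found", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  rules <- lapply(lines, function(ln) {
    fields <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(fields) < 2L) {
      config_error(sprintf("malformed rule line: '%s'", ln))
    }
    list(pattern = fields[[1]], label = fields[[2]],
         atoms = if (length(fields) >= 3L) fields[[3]] else NA_character_)
  })
  out <- data.frame(
    pattern = vapply(rules, `[[`, character(1), "pattern"),
    label = vapply(rules, `[[`, character(1), "label"),
    atoms = vapply(rules, `[[`, character(1), "atoms"),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(out$label, pharmacophore_labels)
  if (length(bad) > 0L) {
    config_error(sprintf("unknown pharmacophore label(s): %s",
                         paste(bad, collapse = ", ")))
  }
  for (p in out$pattern) {
    if (startsWith(p, "@")) {
      if (!substring(p, 2) %in% names(.builtin_predicates)) {
        config_error(sprintf("unknown builtin predicate '%s'", p))
      }
    } else {
      tryCatch(parse_pattern(p), herbsig_parse_error = function(e) {
        config_error(sprintf("invalid rule pattern '%s': %s", p,
                             conditionMessage(e)))
      })
    }
  }
  out
}

#' Assign pharmacophore labels to every atom of a molecule
#'
#' Applies an ordered rule table; each atom receives the union of the
#' labels of all rules it matches, and atoms matching none are labelled
#' `Neutral`.  The labelling depends only on the graph, not on atom
#' order, so isomorphic graphs receive the permuted labelling.
#'
#' @param graph a [molecular_graph].
#' @param rule_table rule table data frame (default [default_rule_table()]).
#' @return a `pharmacophore_labeling`: an `n x 7` logical matrix with one
#'   column per label in [pharmacophore_labels].
#' @export
assign_labels <- function(graph, rule_table = default_rule_table()) {
  n <- n_atoms(graph)
  lab <- matrix(FALSE, n, length(pharmacophore_labels),
                dimnames = list(NULL, pharmacophore_labels))
  nbrs <- .neighbors_list(graph)
  for (r in seq_len(nrow(rule_table))) {
    pat <- rule_table$pattern[[r]]
    label <- rule_table$label[[r]]
    if (startsWith(pat, "@")) {
      hit <- .builtin_predicates[[substring(pat, 2)]](graph, nbrs)
      lab[hit, label] <- TRUE
    } else {
      frag <- parse_pattern(pat)
      sel <- rule_table$atoms[[r]]
      sel <- if (is.na(sel)) seq_len(n_atoms(frag))
             else as.integer(strsplit(sel, ",")[[1]]) + 1L
      maps <- .all_embeddings(frag, graph)
      for (mp in maps) lab[mp[sel], label] <- TRUE
    }
  }
  unlabeled <- rowSums(lab) == 0L
  lab[unlabeled, "Neutral"] <- TRUE
  structure(lab, class = c("pharmacophore_labeling", class(lab)))
}

## All subgraph monomorphisms of pattern into target (element-, aromatic-
## and bond-order-aware); returns list of 1-based target index vectors.
.all_embeddings <- function(pattern, target) {
  if (n_atoms(pattern) > n_atoms(target)) return(list())
  gp <- as_igraph(pattern)
  gt <- as_igraph(target)
  maps <- igraph::subgraph_isomorphisms(
    pattern = gp, target = gt, method = "vf2",
    vertex.color1 = .atom_colors(target), vertex.color2 = .atom_colors(pattern),
    edge.color1 = .bond_colors(target), edge.color2 = .bond_colors(pattern)
  )
  lapply(maps, as.integer)
}
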