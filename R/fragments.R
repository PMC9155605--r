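## Fragment (substructure) mining: exhaustive connected edge-subgraph
## enumeration with canonical-form dedup, molecule-level supports, and
## enrichment ranking between an active and an inactive class.

## Canonical fragment keys for one molecule (see src/fragments.cpp).
.molecule_fragment_keys <- function(graph, max_atoms = 8L,
                                    max_fragments = 5e5) {
  ed <- cbind(graph$bonds$from, graph$bonds$to)
  storage.mode(ed) <- "integer"
  .fragment_keys_cpp(n_atoms(graph), ed, .atom_colors(graph),
                     .bond_colors(graph), as.integer(max_atoms),
                     max_fragments)
}

## Decode a canonical key into a pattern molecular_graph.
.decode_fragment_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  n <- as.integer(parts[[1]])
  vcol <- as.integer(strsplit(parts[[2]], ",", fixed = TRUE)[[1]])
  element <- .known_elements[vcol %/% 2L]
  aromatic <- vcol %% 2L == 1L
  if (length(parts) >= 3L && nzchar(parts[[3]])) {
    es <- do.call(rbind, lapply(
      strsplit(strsplit(parts[[3]], ";", fixed = TRUE)[[1]], "-", fixed = TRUE),
      as.integer))
  } else {
    es <- matrix(integer(0), 0, 3)
  }
  bonds <- data.frame(
    i = es[, 1] + 1L, j = es[, 2] + 1L,
    order = ifelse(es[, 3] == 4L, 1L, es[, 3]),
    aromatic = es[, 3] == 4L
  )
  .new_molecular_graph(
    data.frame(element = element, aromatic = aromatic, charge = 0L,
               hcount = NA_integer_, bracket = FALSE,
               stringsAsFactors = FALSE),
    bonds, pattern = TRUE
  )
}

.records_to_graphs <- function(x) {
  if (is.data.frame(x)) {
    can <- ob_canonical(x$smiles)
    lapply(seq_len(nrow(x)), function(i) {
      if (is.na(can[[i]])) parse_error(sprintf("bad SMILES '%s'", x$smiles[[i]]), 1L)
      keep_largest_component(parse_smiles(can[[i]], canonical_input = TRUE))
    })
  } else if (is_molecular_graph(x)) {
    list(x)
  } else {
    lapply(x, function(g) {
      if (is_molecular_graph(g)) g else keep_largest_component(parse_smiles(g))
    })
  }
}

#' Enumerate all connected fragments of a molecule
#'
#' All connected edge-induced subgraphs with up to `max_atoms` atoms
#' (plus single-atom fragments), deduplicated by exact canonical form.
#' Fragment strings are SMILES-like patterns: aromatic atoms may appear
#' outside complete rings, as in SMARTS.
#'
#' @param graph a [molecular_graph] or SMILES string.
#' @param max_atoms maximum fragment atom count (default 8).
#' @return data frame with columns `fragment` (pattern string), `size`
#'   (atom count) and `key` (canonical form identifier).
#' @export
enumerate_fragments <- function(graph, max_atoms = 8L) {
  if (max_atoms < 1L) contract_error("max_atoms must be >= 1")
  if (is.character(graph)) graph <- parse_smiles(graph)
  keys <- .molecule_fragment_keys(graph, max_atoms)
  frags <- lapply(keys, .decode_fragment_key)
  data.frame(
    fragment = vapply(frags, write_smiles, character(1)),
    size = vapply(frags, n_atoms, integer(1)),
    key = keys,
    stringsAsFactors = FALSE
  )
}

#' Support of a fragment in a molecule set
#'
#' Fraction of molecules containing at least one subgraph-isomorphic
#' embedding of the fragment.  Matching respects element, aromatic flag
#' and bond order; it is charge-insensitive and hydrogen counts are not
#' compared.  Each molecule counts once however many embeddings it holds.
#'
#' @param fragment fragment pattern string (or pattern
#'   [molecular_graph]).
#' @param dataset molecule record data frame, list of graphs, or
#'   character vector of SMILES.
#' @return support fraction in `[0, 1]`.
#' @export
fragment_support <- function(fragment, dataset) {
  if (is.character(fragment)) fragment <- parse_pattern(fragment)
  graphs <- .records_to_graphs(dataset)
  if (length(graphs) == 0L) contract_error("empty dataset")
  hits <- vapply(graphs, function(g) .has_embedding(fragment, g), logical(1))
  mean(hits)
}

.has_embedding <- function(pattern, target) {
  if (n_atoms(pattern) > n_atoms(target)) return(FALSE)
  if (nrow(pattern$bonds) > nrow(target$bonds)) return(FALSE)
  igraph::subgraph_isomorphic(
    pattern = as_igraph(pattern), target = as_igraph(target), method = "vf2",
    vertex.color1 = .atom_colors(target), vertex.color2 = .atom_colors(pattern),
    edge.color1 = .bond_colors(target), edge.color2 = .bond_colors(pattern)
  )
}

#' Mine fragments enriched in the active class
#'
#' Enumerates fragments of every molecule in both classes, computes
#' molecule-level supports, and reports fragments with
#' `support_pos >= min_support_pos`, `support_neg <= max_support_neg` and
#' `fold_change >= min_fold`, where
#' `fold_change = support_pos / max(support_neg, epsilon)` and `epsilon`
#' defaults to `1 / (2 * n_neg)` (regularises zero negative support).
#' Results are ranked by fold change, then positive support, then size
#' (largest first, so maximal discriminating motifs lead).
#'
#' @param pos,neg active- and inactive-class molecules (record data
#'   frames, graph lists or SMILES vectors).
#' @param min_support_pos minimum support among actives (default 0.05).
#' @param max_support_neg maximum support among inactives (default 0.10).
#' @param min_fold minimum fold change (default 10).
#' @param max_atoms maximum fragment size (default 8).
#' @param epsilon zero-support regulariser; default `1 / (2 * n_neg)`.
#' @param maximal_only drop fragments contained in an equally-supported
#'   larger fragment (default `FALSE`).
#' @return data frame of `EnrichedFragment` rows: `fragment`, `size`,
#'   `support_pos`, `support_neg`, `fold_change`.
#' @export
mine_enriched <- function(pos, neg, min_support_pos = 0.05,
                          max_support_neg = 0.10, min_fold = 10,
                          max_atoms = 8L, epsilon = NULL,
                          maximal_only = FALSE) {
  if (min_support_pos <= 0 || min_support_pos > 1) {
    contract_error("min_support_pos must be in (0, 1]")
  }
  if (min_fold < 1) contract_error("min_fold must be >= 1")
  gp <- .records_to_graphs(pos)
  gn <- .records_to_graphs(neg)
  if (length(gp) == 0L || length(gn) == 0L) {
    contract_error("both classes must be non-empty")
  }
  eps <- epsilon %||% (1 / (2 * length(gn)))

  keys_pos <- lapply(gp, .molecule_fragment_keys, max_atoms = max_atoms)
  keys_neg <- lapply(gn, .molecule_fragment_keys, max_atoms = max_atoms)
  cnt_pos <- table(unlist(keys_pos))
  cnt_neg <- table(unlist(keys_neg))

  all_keys <- names(cnt_pos)
  sp <- as.numeric(cnt_pos) / length(gp)
  sn <- as.numeric(cnt_neg[all_keys]) / length(gn)
  sn[is.na(sn)] <- 0
  fold <- sp / pmax(sn, eps)
  keep <- sp >= min_support_pos & sn <= max_support_neg & fold >= min_fold
  keys <- all_keys[keep]
  if (length(keys) == 0L) {
    return(data.frame(fragment = character(0), size = integer(0),
                      support_pos = numeric(0), support_neg = numeric(0),
                      fold_change = numeric(0), stringsAsFactors = FALSE))
  }
  frags <- lapply(keys, .decode_fragment_key)
  out <- data.frame(
    fragment = vapply(frags, write_smiles, character(1)),
    size = vapply(frags, n_atoms, integer(1)),
    support_pos = sp[keep],
    support_neg = sn[keep],
    fold_change = fold[keep],
    stringsAsFactors = FALSE
  )
  ord <- order(-out$fold_change, -out$support_pos, -out$size, out$fragment)
  out <- out[ord, , drop = FALSE]
  frags <- frags[ord]
  if (maximal_only && nrow(out) > 1L) {
    drop <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      for (j in seq_len(nrow(out))) {
        if (i == j || drop[[j]]) next
        if (out$size[[j]] > out$size[[i]] &&
            out$support_pos[[j]] == out$support_pos[[i]] &&
            out$support_neg[[j]] == out$support_neg[[i]] &&
            .has_embedding(frags[[i]], frags[[j]])) {
          drop[[i]] <- TRUE
          break
        }
      }
    }
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Threshold presets for enrichment mining
#'
#' Named support regimes crossed with a 5- or 10-fold enrichment
#' requirement: `s1`/`s5` set the minimum active-class support to 1%/5%
#' with no cap on inactive support beyond the fold rule; `s1-10`/`s2-10`
#' additionally cap inactive-class support at 10% while requiring 1%/2%
#' active support.
#'
#' @param preset one of `"s1"`, `"s5"`, `"s1-10"`, `"s2-10"`.
#' @param fold 5 or 10.
#' @return list of arguments for [mine_enriched()].
#' @export
mining_preset <- function(preset = c("s5", "s1", "s1-10", "s2-10"),
                          fold = c(10, 5)) {
  preset <- match.arg(preset)
  fold <- as.numeric(fold[[1]])
  if (!fold %in% c(5, 10)) contract_error("fold must be 5 or 10")
  th <- switch(preset,
    "s1" = list(min_support_pos = 0.01, max_support_neg = 1.0),
    "s5" = list(min_support_pos = 0.05, max_support_neg = 1.0),
    "s1-10" = list(min_support_pos = 0.01, max_support_neg = 0.10),
    "s2-10" = list(min_support_pos = 0.02, max_support_neg = 0.10)
  )
  c(th, list(min_fold = fold))
}
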