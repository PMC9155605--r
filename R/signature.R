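#' All-pairs shortest-path distances on the heavy-atom graph
#'
#' Breadth-first distances in bond steps on the unweighted molecular
#' graph.  Pairs in different components hold `Inf` (the unreachable
#' sentinel).
#'
#' @param graph a [molecular_graph].
#' @return symmetric `n x n` numeric matrix with zero diagonal.
#' @export
all_pairs_distances <- function(graph) {
  n <- n_atoms(graph)
  if (n == 0L) return(matrix(numeric(0), 0, 0))
  g <- as_igraph(graph)
  d <- igraph::distances(g, algorithm = "unweighted")
  dimnames(d) <- NULL
  d
}

#' Compute the pair block of a graph-based signature
#'
#' The cutoff scanning matrix: for every unordered pharmacophore label
#' pair `(a, b)` and cutoff `c`, counts the unordered atom pairs `(i, j)`
#' whose shortest-path distance is `<= c` and that realise the label pair
#' (`a` on one end, `b` on the other).  Each atom pair contributes once
#' per distinct unordered label pair it realises; rows are cumulative,
#' hence non-decreasing in the cutoff.  Unreachable pairs contribute
#' nothing.
#'
#' @param graph a [molecular_graph].
#' @param labeling a labelling from [assign_labels()].
#' @param cutoffs strictly increasing positive integer cutoffs (bond
#'   steps); default `1:10`.
#' @return named numeric vector of length `28 * length(cutoffs)`, ordered
#'   pair-major (all cutoffs of the first label pair, then the second...).
#' @export
compute_signature <- function(graph, labeling, cutoffs = 1:10) {
  n <- n_atoms(graph)
  if (nrow(labeling) != n) {
    contract_error("labeling and graph disagree on atom count")
  }
  if (length(cutoffs) == 0L || any(cutoffs <= 0) ||
      any(diff(cutoffs) <= 0)) {
    contract_error("cutoffs must be strictly increasing positive integers")
  }
  d <- all_pairs_distances(graph)
  labs <- pharmacophore_labels
  pairs <- .label_pairs()
  out <- numeric(nrow(pairs) * length(cutoffs))
  names(out) <- .pair_block_names(cutoffs)
  L <- matrix(as.numeric(labeling), n, length(labs))
  for (ci in seq_along(cutoffs)) {
    A <- (d >= 1 & d <= cutoffs[[ci]]) * 1
    P <- t(L) %*% A %*% L              # ordered pair counts
    for (pi in seq_len(nrow(pairs))) {
      a <- pairs$a[[pi]]; b <- pairs$b[[pi]]
      cnt <- if (a == b) {
        P[a, a] / 2
      } else {
        both <- L[, a] * L[, b]        # atoms carrying both labels
        P[a, b] - as.numeric(both %*% A %*% both) / 2
      }
      out[[(pi - 1L) * length(cutoffs) + ci]] <- cnt
    }
  }
  out
}

.label_pairs <- function() {
  labs <- seq_along(pharmacophore_labels)
  idx <- which(upper.tri(diag(length(labs)), diag = TRUE), arr.ind = TRUE)
  data.frame(a = idx[, "row"], b = idx[, "col"])[order(idx[, "row"], idx[, "col"]), ]
}

.pair_block_names <- function(cutoffs = 1:10) {
  pairs <- .label_pairs()
  labs <- pharmacophore_labels
  unlist(lapply(seq_len(nrow(pairs)), function(pi) {
    sprintf("%s:%s_d%d", labs[[pairs$a[[pi]]]], labs[[pairs$b[[pi]]]], cutoffs)
  }))
}

#' Featurize a set of molecule records
#'
#' Builds the full feature matrix: the signature pair block (28 label
#' pairs x cutoffs, cumulative counts) followed by the 10-descriptor
#' physicochemical block.  Multi-component molecules are reduced to their
#' largest component before featurization; molecules that fail to parse
#' are dropped with a logged identifier.
#'
#' @param records molecule record data frame ([molecule_records()] or
#'   [read_smiles_file()]).
#' @param rule_table pharmacophore rule table.
#' @param cutoffs distance cutoffs, default `1:10`.
#' @param normalise divide the pair block of each molecule by its heavy
#'   atom count (default `FALSE`: raw cumulative counts preserve size
#'   information).
#' @return numeric matrix with one row per surviving record (rownames =
#'   record ids) and attribute `dropped` (ids of failed molecules).
#' @export
featurize_dataset <- function(records, rule_table = default_rule_table(),
                              cutoffs = 1:10, normalise = FALSE) {
  if (nrow(records) == 0L) data_error("empty record set")
  can <- ob_canonical(records$smiles)
  rows <- vector("list", nrow(records))
  dropped <- character(0)
  descs <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    row <- tryCatch({
      if (is.na(can[[i]])) parse_error("canonicalizer rejected input", 1L)
      g <- parse_smiles(can[[i]], canonical_input = TRUE)
      g <- keep_largest_component(g)
      labs <- assign_labels(g, rule_table)
      sig <- compute_signature(g, labs, cutoffs)
      if (normalise) sig <- sig / n_atoms(g)
      descs[[i]] <- g
      sig
    }, herbsig_parse_error = function(e) NULL)
    if (is.null(row)) {
      dropped <- c(dropped, records$id[[i]])
      hs_log("dropping unfeaturizable molecule '%s'", records$id[[i]],
             level = "warning")
    }
    rows[i] <- list(row)                # keep NULL slots (no list shrink)
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) data_error("no featurizable molecules in record set")
  smi <- vapply(descs[keep], function(g) {
    if (is.na(g$smiles)) write_smiles(g) else g$smiles
  }, character(1))
  ob <- .ob_props(smi)                  # one OpenBabel round trip per dataset
  desc_block <- do.call(rbind, lapply(seq_along(which(keep)), function(r) {
    i <- which(keep)[[r]]
    unlist(compute_descriptors(
      descs[[i]], ob = list(logP = ob$logP[[r]], TPSA = ob$TPSA[[r]])))
  }))
  mat <- cbind(do.call(rbind, rows[keep]), desc_block)
  rownames(mat) <- records$id[keep]
  attr(mat, "dropped") <- dropped
  attr(mat, "cutoffs") <- cutoffs
  mat
}

#' Column names of the default feature layout
#'
#' @param cutoffs distance cutoffs, default `1:10`.
#' @return character vector: pair block names then descriptor names.
#' @export
signature_colnames <- function(cutoffs = 1:10) {
  c(.pair_block_names(cutoffs), .descriptor_names)
}
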