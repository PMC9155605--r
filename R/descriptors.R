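.descriptor_names <- c("MW", "logP", "HBA", "HBD", "RotB", "RingCount",
                       "AromaticRings", "HeavyAtoms", "TPSA", "FractionCsp3")

#' Molecular weight from the atomic-mass table
#'
#' Sum of standard atomic weights over heavy atoms plus 1.008 Da per
#' attached hydrogen.
#'
#' @param graph a [molecular_graph].
#' @return molecular weight in Da.
#' @export
molecular_weight <- function(graph) {
  m <- .atomic_masses[graph$atoms$element]
  sum(m, na.rm = TRUE) + 1.008 * sum(graph$atoms$hcount, na.rm = TRUE)
}

## Batched OpenBabel properties (logP, TPSA) for a vector of SMILES.
.ob_props <- function(smiles) {
  sdf <- suppressWarnings(
    ChemmineR::smiles2sdf(setNames(smiles, seq_along(smiles)))
  )
  p <- ChemmineR::propOB(sdf)
  out <- data.frame(logP = rep(NA_real_, length(smiles)),
                    TPSA = rep(NA_real_, length(smiles)))
  idx <- as.integer(p$title)
  out$logP[idx] <- p$logP
  out$TPSA[idx] <- p$TPSA
  out
}

#' Physicochemical descriptor block
#'
#' The 10 complementary descriptors appended to the signature pair block:
#' molecular weight (Da), logP, H-bond acceptor and donor counts,
#' rotatable bond count, ring count, aromatic ring count, heavy atom
#' count, topological polar surface area (A^2) and the fraction of sp3
#' carbons.  Counts are computed on the heavy-atom graph with implicit
#' hydrogens; logP and TPSA come from OpenBabel.
#'
#' @param graph a [molecular_graph].
#' @param ob optional precomputed `list(logP=, TPSA=)` (used internally to
#'   batch OpenBabel calls over datasets).
#' @return named list of the 10 descriptor values.
#' @export
compute_descriptors <- function(graph, ob = NULL) {
  atoms <- graph$atoms
  bonds <- graph$bonds
  n <- n_atoms(graph)
  deg <- tabulate(c(bonds$from, bonds$to) + 1L, nbins = n)

  hba <- sum(atoms$element %in% c("N", "O") & atoms$charge <= 0L)
  hbd <- sum(atoms$element %in% c("N", "O") & atoms$hcount >= 1L)

  g <- as_igraph(graph)
  ncomp <- n_components(graph)
  ring_count <- nrow(bonds) - n + ncomp

  arom_v <- which(atoms$aromatic)
  arom_e <- which(bonds$aromatic)
  aromatic_rings <- if (length(arom_v) == 0L) 0L else {
    sub <- igraph::subgraph_from_edges(
      g, arom_e, delete.vertices = FALSE)
    sub <- igraph::induced_subgraph(sub, arom_v)
    length(arom_e) - length(arom_v) + igraph::components(sub)$no
  }

  in_ring <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0L) {
    bridge_ids <- as.integer(igraph::bridges(g))
    in_ring <- !(seq_len(nrow(bonds)) %in% bridge_ids)
  }
  rotb <- sum(bonds$order == 1L & !bonds$aromatic & !in_ring &
                deg[bonds$from + 1L] >= 2L & deg[bonds$to + 1L] >= 2L)

  carbons <- atoms$element == "C"
  sp3 <- vapply(seq_len(n), function(v) {
    if (!carbons[[v]] || atoms$aromatic[[v]]) return(FALSE)
    inc <- bonds$from == atoms$index[[v]] | bonds$to == atoms$index[[v]]
    all(bonds$order[inc] == 1L & !bonds$aromatic[inc])
  }, logical(1))
  fcsp3 <- if (sum(carbons) == 0L) 0 else sum(sp3) / sum(carbons)

  if (is.null(ob)) {
    smi <- graph$smiles
    if (is.na(smi)) smi <- write_smiles(graph)
    p <- .ob_props(smi)
    ob <- list(logP = p$logP[[1]], TPSA = p$TPSA[[1]])
  }

  list(MW = molecular_weight(graph), logP = ob$logP, HBA = hba, HBD = hbd,
       RotB = rotb, RingCount = ring_count, AromaticRings = aromatic_rings,
       HeavyAtoms = n, TPSA = ob$TPSA, FractionCsp3 = fcsp3)
}

#' Herbicide-likeness property windows
#'
#' Property bounds enclosing 90% and 95% of known herbicidally active
#' compounds: the 90% tier requires MW < 517 Da, at most 9 H-bond
#' acceptors, at most 4 donors, fewer than 9 rotatable bonds and logP in
#' [-1.7, 6.1]; the 95% tier relaxes these to MW < 700 Da, at most 11
#' acceptors, 6 donors, fewer than 11 rotatable bonds and logP in
#' [-3.0, 6.1].
#'
#' @param desc a descriptor block from [compute_descriptors()] (any list
#'   with `MW`, `HBA`, `HBD`, `RotB`, `logP`).
#' @return list with elements `tier90` and `tier95`, each holding
#'   `pass` (logical) and `violations` (character vector of violated
#'   bounds).
#' @export
herbicide_likeness <- function(desc) {
  check_tier <- function(mw_max, hba_max, hbd_max, rotb_max, logp_lo, logp_hi) {
    v <- character(0)
    if (!(desc$MW < mw_max)) v <- c(v, sprintf("MW >= %g Da", mw_max))
    if (!(desc$HBA <= hba_max)) v <- c(v, sprintf("HBA > %d", hba_max))
    if (!(desc$HBD <= hbd_max)) v <- c(v, sprintf("HBD > %d", hbd_max))
    if (!(desc$RotB < rotb_max)) v <- c(v, sprintf("RotB >= %d", rotb_max))
    if (!(desc$logP >= logp_lo && desc$logP <= logp_hi)) {
      v <- c(v, sprintf("logP outside [%g, %g]", logp_lo, logp_hi))
    }
    list(pass = length(v) == 0L, violations = v)
  }
  list(
    tier90 = check_tier(517, 9L, 4L, 9L, -1.7, 6.1),
    tier95 = check_tier(700, 11L, 6L, 11L, -3.0, 6.1)
  )
}
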