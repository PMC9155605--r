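# Independent oracles used to cross-check the implementation.  These are
# deliberately naive (brute force) and share no code with the package
# internals they verify.

## Floyd-Warshall all-pairs shortest paths from the bond list.
fw_distances <- function(graph) {
  n <- n_atoms(graph)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (k in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$from[[k]] + 1L
    j <- graph$bonds$to[[k]] + 1L
    D[i, j] <- D[j, i] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  D
}

## Connected components by explicit breadth-first traversal (0-based ids).
bfs_components <- function(graph) {
  n <- n_atoms(graph)
  nbr <- vector("list", n)
  for (k in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$from[[k]] + 1L
    j <- graph$bonds$to[[k]] + 1L
    nbr[[i]] <- c(nbr[[i]], j)
    nbr[[j]] <- c(nbr[[j]], i)
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[[s]])) next
    queue <- s
    comp[[s]] <- cid
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (w in nbr[[v]]) {
        if (is.na(comp[[w]])) {
          comp[[w]] <- cid
          queue <- c(queue, w)
        }
      }
    }
    cid <- cid + 1L
  }
  comp
}

## Classification metrics by direct confusion-matrix arithmetic.
confusion_metrics <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  list(
    accuracy = (tp + tn) / n,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den
  )
}

## ROC-AUC as the exhaustive concordant-pair fraction (ties count 1/2).
pairwise_auc <- function(y, s) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + if (s[[i]] > s[[j]]) 1 else if (s[[i]] == s[[j]]) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

## Random grammar molecules for property tests (inputs, not oracles).
random_test_smiles <- function(n, seed, max_heavy = Inf) {
  set.seed(seed)
  grammar <- herbsig:::.syn_grammar()
  out <- character(0)
  while (length(out) < n) {
    smi <- herbsig:::.random_molecule(grammar)
    g <- herbsig:::.quick_graph(smi)
    if (n_atoms(g) <= max_heavy) out <- c(out, smi)
  }
  out
}

## Exhaustive support oracle: fraction of molecules with >= 1 embedding,
## found by brute-force search over injective vertex assignments.
brute_force_contains <- function(pattern, target) {
  pa <- pattern$atoms
  ta <- target$atoms
  np <- nrow(pa)
  nt <- nrow(ta)
  if (np > nt) return(FALSE)
  pb <- pattern$bonds
  tb <- target$bonds
  tkey <- paste(pmin(tb$from, tb$to), pmax(tb$from, tb$to))
  tcol <- paste(tb$order, tb$aromatic)
  compatible <- function(i, j) {           # pattern atom i vs target atom j
    pa$element[[i]] == ta$element[[j]] && pa$aromatic[[i]] == ta$aromatic[[j]]
  }
  assign_next <- function(map) {
    i <- length(map) + 1L
    if (i > np) return(TRUE)
    for (j in seq_len(nt)) {
      if (j %in% map) next
      if (!compatible(i, j)) next
      ok <- TRUE
      for (k in seq_len(nrow(pb))) {
        a <- pb$from[[k]] + 1L
        b <- pb$to[[k]] + 1L
        if (a > i || b > i) next
        ja <- if (a == i) j else map[[a]]
        jb <- if (b == i) j else map[[b]]
        hit <- which(tkey == paste(min(ja, jb) - 1L, max(ja, jb) - 1L))
        if (length(hit) == 0L ||
            tcol[[hit]] != paste(pb$order[[k]], pb$aromatic[[k]])) {
          ok <- FALSE
          break
        }
      }
      if (ok && assign_next(c(map, j))) return(TRUE)
    }
    FALSE
  }
  assign_next(integer(0))
}
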