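# Low-level SMILES reader.
#
# This is a deliberately small reader for the organic chemistry subset of
# SMILES (organic-subset atoms, bracket atoms, branches, ring closures,
# bond symbols, disconnected components).  It exists to (a) report syntax
# errors with the offending token position, which external converters do
# not, and (b) build the atom-level heavy-atom graph (element, formal
# charge, implicit hydrogens, aromatic flags) that the signature machinery
# consumes.  Aromatic perception of Kekule inputs is delegated to the
# canonicalizer (see parse_smiles): molecules are re-read from their
# canonical aromatic rendering, so this reader only needs to honour
# lowercase aromatic atoms as written.

.organic_aliphatic <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.organic_aromatic <- c("b", "c", "n", "o", "p", "s")

# Standard atomic weights; implicit hydrogens contribute 1.008 each.
.atomic_masses <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.086, P = 30.974,
  S = 32.065, Cl = 35.453, K = 39.098, Ca = 40.078, Mn = 54.938,
  Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38,
  As = 74.922, Se = 78.971, Br = 79.904, Sn = 118.710, Te = 127.60,
  I = 126.904, Hg = 200.59, Pb = 207.2
)

# Normal valences of the organic subset, used for implicit-H inference;
# multiple entries allow hypervalent states written without charges.
.default_valences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

.known_elements <- names(.atomic_masses)

## Tokenising parser.  Returns list(atoms=..., bonds=...) with 1-based
## indices; smiles_to_graph() converts to the public 0-based convention.
.parse_smiles_tokens <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || nchar(s) == 0L) {
    parse_error("empty SMILES string", 1L)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  np <- length(chars)

  el <- character(0); arom <- logical(0); chg <- integer(0)
  hc <- integer(0); brk <- logical(0)
  bi <- integer(0); bj <- integer(0); border <- integer(0); barom <- logical(0)
  bexpl <- logical(0)

  prev <- NA_integer_
  pending <- NULL                       # list(order, aromatic, pos) or NULL
  stack <- integer(0)
  rings <- list()                       # digit -> list(atom, bond, pos)

  add_atom <- function(element, aromatic, charge, hcount, bracket, pos) {
    el[[length(el) + 1L]] <<- element
    arom[[length(arom) + 1L]] <<- aromatic
    chg[[length(chg) + 1L]] <<- as.integer(charge)
    hc[[length(hc) + 1L]] <<- as.integer(hcount)
    brk[[length(brk) + 1L]] <<- bracket
    idx <- length(el)
    if (!is.na(prev)) {
      add_bond(prev, idx, pending, pos)
      pending <<- NULL
    } else if (!is.null(pending)) {
      parse_error("bond symbol with no preceding atom", pending$pos)
    }
    prev <<- idx
    idx
  }

  add_bond <- function(i, j, spec, pos) {
    if (i == j) parse_error("ring bond closing on its own atom", pos)
    if (any(bi == i & bj == j) || any(bi == j & bj == i)) {
      parse_error("duplicate bond between the same atoms", pos)
    }
    if (is.null(spec)) {
      aromatic <- arom[[i]] && arom[[j]]
      ord <- 1L
    } else if (isTRUE(spec$aromatic)) {
      aromatic <- TRUE
      ord <- 1L
    } else {
      aromatic <- FALSE
      ord <- spec$order
    }
    bi[[length(bi) + 1L]] <<- i
    bj[[length(bj) + 1L]] <<- j
    border[[length(border) + 1L]] <<- ord
    barom[[length(barom) + 1L]] <<- aromatic
    bexpl[[length(bexpl) + 1L]] <<- !is.null(spec)
  }

  i <- 1L
  while (i <= np) {
    ch <- chars[[i]]
    if (ch == "(") {
      if (is.na(prev)) parse_error("branch opened before any atom", i)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) parse_error("unmatched closing parenthesis", i)
      if (!is.null(pending)) parse_error("branch closed after a dangling bond", i)
      prev <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      if (!is.null(pending)) parse_error("bond symbol before component separator", i)
      prev <- NA_integer_
      i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {      # stereo slashes read as single
      if (!is.null(pending)) parse_error("two consecutive bond symbols", i)
      pending <- list(order = 1L, aromatic = FALSE, pos = i)
      i <- i + 1L
    } else if (ch == "=") {
      if (!is.null(pending)) parse_error("two consecutive bond symbols", i)
      pending <- list(order = 2L, aromatic = FALSE, pos = i)
      i <- i + 1L
    } else if (ch == "#") {
      if (!is.null(pending)) parse_error("two consecutive bond symbols", i)
      pending <- list(order = 3L, aromatic = FALSE, pos = i)
      i <- i + 1L
    } else if (ch == ":") {
      if (!is.null(pending)) parse_error("two consecutive bond symbols", i)
      pending <- list(order = 1L, aromatic = TRUE, pos = i)
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > np || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L]))) {
          parse_error("'%' ring closure needs two digits", i)
        }
        key <- paste0(chars[i + 1L], chars[i + 2L])
        i <- i + 3L
      } else {
        key <- ch
        i <- i + 1L
      }
      if (is.na(prev)) parse_error("ring closure digit before any atom", i - 1L)
      if (!is.null(rings[[key]])) {
        opener <- rings[[key]]
        spec <- pending %||% opener$bond
        if (!is.null(pending) && !is.null(opener$bond) &&
            !identical(pending[c("order", "aromatic")],
                       opener$bond[c("order", "aromatic")])) {
          parse_error(sprintf("conflicting bond orders on ring closure %s", key), i - 1L)
        }
        add_bond(opener$atom, prev, spec, i - 1L)
        rings[[key]] <- NULL
        pending <- NULL
      } else {
        rings[[key]] <- list(atom = prev, bond = pending, pos = i - 1L)
        pending <- NULL
      }
    } else if (ch == "[") {
      close <- NA_integer_
      j <- i + 1L
      while (j <= np) {
        if (chars[[j]] == "]") { close <- j; break }
        j <- j + 1L
      }
      if (is.na(close)) parse_error("unclosed bracket atom", i)
      body <- paste0(chars[(i + 1L):(close - 1L)], collapse = "")
      at <- .parse_bracket_atom(body, i)
      add_atom(at$element, at$aromatic, at$charge, at$hcount, TRUE, i)
      i <- close + 1L
    } else if (grepl("[A-Z]", ch)) {
      two <- if (i < np) paste0(ch, chars[[i + 1L]]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, 0L, NA_integer_, FALSE, i)
        i <- i + 2L
      } else if (ch %in% .organic_aliphatic) {
        add_atom(ch, FALSE, 0L, NA_integer_, FALSE, i)
        i <- i + 1L
      } else {
        parse_error(sprintf("invalid element '%s' outside brackets", ch), i)
      }
    } else if (ch %in% .organic_aromatic) {
      add_atom(toupper(ch), TRUE, 0L, NA_integer_, FALSE, i)
      i <- i + 1L
    } else {
      parse_error(sprintf("unexpected character '%s'", ch), i)
    }
  }

  if (length(stack) > 0L) parse_error("unclosed branch", np)
  if (length(rings) > 0L) {
    first <- rings[[1L]]
    parse_error(sprintf("unclosed ring bond '%s'", names(rings)[[1L]]), first$pos)
  }
  if (!is.null(pending)) parse_error("dangling bond symbol at end of input", pending$pos)
  if (length(el) == 0L) parse_error("no atoms in SMILES", 1L)

  list(
    atoms = data.frame(element = el, aromatic = arom, charge = chg,
                       hcount = hc, bracket = brk, stringsAsFactors = FALSE),
    bonds = data.frame(i = bi, j = bj, order = border, aromatic = barom,
                       explicit = bexpl)
  )
}

.parse_bracket_atom <- function(body, pos) {
  m <- regexec(
    "^([0-9]*)([A-Z][a-z]?|as|se|[bcnops])(@{0,2})(H[0-9]*)?(\\+{1,3}|-{1,3}|\\+[0-9]+|-[0-9]+)?$",
    body
  )
  parts <- regmatches(body, m)[[1]]
  if (length(parts) == 0L) {
    parse_error(sprintf("malformed bracket atom '[%s]'", body), pos)
  }
  sym <- parts[[3]]
  aromatic <- sym %in% c(.organic_aromatic, "as", "se")
  element <- if (aromatic) {
    paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  } else {
    sym
  }
  if (!element %in% .known_elements) {
    parse_error(sprintf("unknown element '%s'", sym), pos)
  }
  hspec <- parts[[5]]
  hcount <- if (hspec == "") 0L
            else if (hspec == "H") 1L
            else as.integer(substring(hspec, 2))
  cspec <- parts[[6]]
  charge <- if (cspec == "") 0L
            else if (grepl("^[+-][0-9]+$", cspec)) {
              as.integer(cspec)
            } else {
              nchar(cspec) * if (substr(cspec, 1, 1) == "+") 1L else -1L
            }
  list(element = element, aromatic = aromatic, charge = charge, hcount = hcount)
}

## An implicit bond between two aromatic atoms is only aromatic when it
## lies in a ring: the biaryl single bond of e.g. biphenyl connects two
## aromatic systems without being part of either.  Demote aromatic bonds
## that are bridges (molecule graphs only; ring fragments in pattern mode
## legitimately carry acyclic aromatic bonds).
.demote_nonring_aromatic <- function(toks) {
  ab <- which(toks$bonds$aromatic)
  if (length(ab) == 0L) return(toks)
  g <- igraph::make_graph(rbind(toks$bonds$i, toks$bonds$j),
                          n = nrow(toks$atoms), directed = FALSE)
  demote <- intersect(ab, as.integer(igraph::bridges(g)))
  if (length(demote) > 0L) {
    toks$bonds$aromatic[demote] <- FALSE
    toks$bonds$order[demote] <- 1L
  }
  toks
}

## Implicit hydrogen inference for organic-subset (non-bracket) atoms.
## Aromatic atoms consume one extra valence unit for the delocalised system:
## used = n_aromatic_bonds + 1 + sum(orders of plain bonds).
.infer_hydrogens <- function(atoms, bonds) {
  n <- nrow(atoms)
  used <- numeric(n)
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      o <- if (bonds$aromatic[[k]]) 1 else bonds$order[[k]]
      used[[bonds$i[[k]]]] <- used[[bonds$i[[k]]]] + o
      used[[bonds$j[[k]]]] <- used[[bonds$j[[k]]]] + o
    }
  }
  used <- used + ifelse(atoms$aromatic, 1, 0)
  h <- atoms$hcount
  for (a in seq_len(n)) {
    if (!is.na(h[[a]])) next
    vals <- .default_valences[[atoms$element[[a]]]]
    if (is.null(vals)) { h[[a]] <- 0L; next }
    fit <- vals[vals >= used[[a]]]
    h[[a]] <- if (length(fit) == 0L) 0L else as.integer(fit[[1L]] - used[[a]])
  }
  h
}
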