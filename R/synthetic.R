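## Synthetic structure-activity data with planted, recoverable ground
## truth.  Molecules are assembled from a scaffold/decorator grammar
## (aromatic and saturated rings, chains, halogens and polar groups) so
## that planted fragments are chemically well-formed; activity labels
## follow a planted fragment rule, a descriptor window, or both, with
## optional label-flip noise.

.syn_grammar <- function() {
  list(
    scaffolds = list(
      list(tokens = c("c1", "c", "c", "c", "c", "c1"), sites = 1:6, w = 4),
      list(tokens = c("c1", "c", "c", "n", "c", "c1"), sites = c(1:3, 5:6), w = 2),
      list(tokens = c("C1", "C", "C", "C", "C", "C1"), sites = 1:6, w = 2),
      list(tokens = c("c1", "c", "c", "c", "s1"), sites = 1:4, w = 1),
      list(tokens = c("c1", "c", "c", "c", "o1"), sites = 1:4, w = 1),
      list(tokens = c("C", "C", "C", "C"), sites = 1:4, w = 2)
    ),
    decorators = c("C", "CC", "CCC", "C(C)C", "F", "Cl", "Br", "O", "OC",
                   "N", "C(=O)O", "CC(=O)O", "C#N", "C(F)(F)F", "S", "CO"),
    decorator_w = c(4, 2, 1, 1, 2, 3, 1, 3, 2, 2, 2, 1, 1, 1, 1, 1)
  )
}

## Default planted motif: a chloroacetic-acid arm.  The decorator attaches
## through its first carbon, so every planted molecule contains the
## Cl-C-C(=O)-O pattern; the plain grammar offers chlorine and carboxyl
## decorations separately but never that combination.
.default_planted <- list(fragment = "ClCC(=O)O", decorator = "C(Cl)C(=O)O")

#' Planted structure-activity rule
#'
#' Describes the ground truth of a synthetic dataset: activity is driven
#' by a planted substructure (`fragment` mode), a physicochemical window
#' (`descriptor` mode) or their conjunction (`mixed`), at a target
#' positive prevalence, with optional label-flip noise.
#'
#' @param mode `"fragment"`, `"descriptor"` or `"mixed"`.
#' @param active_fragment substructure pattern planted into actives
#'   (default a chloroacetic-acid arm, `ClCC(=O)O`).  A custom fragment
#'   must be plantable as a branch through its first atom; this is
#'   validated at construction.
#' @param descriptor_window named list of `c(lo, hi)` bounds on `MW`
#'   and/or `logP` (default MW in `[0, 120]`, which splits the grammar's
#'   mass distribution near its median).
#' @param prevalence target positive fraction (default 0.22, the typical
#'   prevalence of curated herbicidal-activity sets).
#' @param label_noise label flip probability in `[0, 0.5)`.
#' @param seed RNG seed.
#' @return a `planted_rule` list.
#' @export
planted_rule <- function(mode = c("fragment", "descriptor", "mixed"),
                         active_fragment = .default_planted$fragment,
                         descriptor_window = list(MW = c(0, 120)),
                         prevalence = 0.22, label_noise = 0, seed = 1L) {
  mode <- match.arg(mode)
  if (prevalence <= 0 || prevalence >= 1) {
    config_error("prevalence must be in (0, 1)")
  }
  if (label_noise < 0 || label_noise >= 0.5) {
    config_error("label_noise must be in [0, 0.5)")
  }
  decorator <- if (identical(active_fragment, .default_planted$fragment)) {
    .default_planted$decorator
  } else {
    active_fragment
  }
  if (mode != "descriptor") {
    pat <- tryCatch(parse_pattern(active_fragment),
                    herbsig_parse_error = function(e) {
                      config_error(sprintf("active_fragment does not parse: %s",
                                           conditionMessage(e)))
                    })
    probe <- sprintf("c1cc(%s)ccc1", decorator)
    ok <- tryCatch({
      g <- parse_smiles(probe)
      .has_embedding(pat, g)
    }, herbsig_error = function(e) FALSE)
    if (!ok) {
      config_error(
        "active_fragment cannot be planted by the scaffold grammar")
    }
  }
  bad <- setdiff(names(descriptor_window), c("MW", "logP"))
  if (length(bad) > 0L) {
    config_error(sprintf("unsupported descriptor window(s): %s",
                         paste(bad, collapse = ", ")))
  }
  structure(list(mode = mode, active_fragment = active_fragment,
                 decorator = decorator, descriptor_window = descriptor_window,
                 prevalence = prevalence, label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "planted_rule")
}

## One random molecule from the grammar; returns its SMILES.
.random_molecule <- function(grammar, extra_decorator = NULL) {
  sc <- grammar$scaffolds[[sample(length(grammar$scaffolds), 1,
                                  prob = vapply(grammar$scaffolds, `[[`,
                                                numeric(1), "w"))]]
  ndec <- sample(0:3, 1, prob = c(0.15, 0.4, 0.3, 0.15))
  sites <- if (ndec > 0) sample(sc$sites, min(ndec, length(sc$sites))) else integer(0)
  decs <- if (length(sites) > 0) {
    sample(grammar$decorators, length(sites), replace = TRUE,
           prob = grammar$decorator_w)
  } else {
    character(0)
  }
  if (!is.null(extra_decorator)) {
    free <- setdiff(sc$sites, sites)
    if (length(free) == 0L) {          # displace a random decoration
      k <- sample(length(sites), 1)
      decs[[k]] <- extra_decorator
    } else {
      sites <- c(sites, if (length(free) == 1L) free else sample(free, 1))
      decs <- c(decs, extra_decorator)
    }
  }
  toks <- sc$tokens
  if (length(sites) > 0) {
    toks[sites] <- paste0(toks[sites], "(", decs, ")")
  }
  paste(toks, collapse = "")
}

## Grammar output is already in valid aromatic form, so candidates can be
## graphed with the package's own reader alone (no canonicalizer round
## trip inside the sampling loop).
.quick_graph <- function(smiles) {
  toks <- .demote_nonring_aromatic(.parse_smiles_tokens(smiles))
  toks$atoms$hcount <- .infer_hydrogens(toks$atoms, toks$bonds)
  .new_molecular_graph(toks$atoms, toks$bonds, smiles = smiles)
}

.quick_mw <- function(smiles) molecular_weight(.quick_graph(smiles))

.in_window <- function(smiles, window, logp = NULL) {
  ok <- TRUE
  if (!is.null(window$MW)) {
    mw <- .quick_mw(smiles)
    ok <- ok && mw >= window$MW[[1]] && mw <= window$MW[[2]]
  }
  if (!is.null(window$logP) && !is.null(logp)) {
    ok <- ok && logp >= window$logP[[1]] && logp <= window$logP[[2]]
  }
  ok
}

#' Generate a labelled synthetic structure-activity dataset
#'
#' Draws each molecule's true activity from the rule's prevalence, builds
#' a molecule consistent with that truth (planting the active fragment
#' and/or sampling into or out of the descriptor window), then flips the
#' label with probability `label_noise`.  Deterministic under the rule's
#' seed.
#'
#' @param n number of molecules (>= 20).
#' @param rule a [planted_rule()].
#' @return molecule records with `label`, plus attributes `truth` (the
#'   pre-noise activity) and `rule`.
#' @export
generate_dataset <- function(n, rule = planted_rule()) {
  if (n < 20) contract_error("n must be >= 20")
  grammar <- .syn_grammar()
  pat <- if (rule$mode != "descriptor") parse_pattern(rule$active_fragment)
  use_window <- rule$mode %in% c("descriptor", "mixed")
  with_seed(rule$seed, {
    truth <- runif(n) < rule$prevalence
    smiles <- character(n)
    for (i in seq_len(n)) {
      for (try in 1:200) {
        cand <- if (truth[[i]] && rule$mode != "descriptor") {
          .random_molecule(grammar, extra_decorator = rule$decorator)
        } else {
          .random_molecule(grammar)
        }
        ok <- TRUE
        if (!truth[[i]] && rule$mode != "descriptor") {
          g <- tryCatch(.quick_graph(cand),
                        herbsig_parse_error = function(e) NULL)
          ok <- !is.null(g) && !.has_embedding(pat, g)
        }
        if (ok && use_window) {
          inw <- .in_window(cand, rule$descriptor_window)
          ok <- if (truth[[i]]) inw else !inw || rule$mode == "mixed"
          ## mixed mode: inactives may sit inside the window as long as
          ## they lack the fragment (handled above)
        }
        if (ok) break
        cand <- NA_character_
      }
      if (is.na(cand)) {
        config_error("could not satisfy the planted rule; check the window")
      }
      smiles[[i]] <- cand
    }
    label <- as.integer(xor(truth, runif(n) < rule$label_noise))
    recs <- molecule_records(smiles, id = sprintf("syn%d", seq_len(n)),
                             label = label)
    attr(recs, "truth") <- as.integer(truth)
    attr(recs, "rule") <- rule
    recs
  })
}

#' Generate a synthetic regression dataset
#'
#' Molecules are drawn from the scaffold grammar; the continuous endpoint
#' is a stated linear function of the molecule's true descriptors plus
#' Gaussian noise, emulating LC50/LD50-style endpoints.
#'
#' @param n number of molecules (>= 20).
#' @param coefficients named numeric vector over descriptor names (see
#'   [compute_descriptors()]) plus optional `"(Intercept)"`; default
#'   `c("(Intercept)" = 2, MW = -0.01, logP = 0.5)`.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return molecule records with `value`, plus attributes
#'   `true_descriptors` (matrix) and `true_value` (noise-free values).
#' @export
generate_regression_dataset <- function(n,
                                        coefficients = c("(Intercept)" = 2,
                                                         MW = -0.01,
                                                         logP = 0.5),
                                        noise_sd = 0.1, seed = 1L) {
  if (n < 20) contract_error("n must be >= 20")
  if (noise_sd < 0) contract_error("noise_sd must be >= 0")
  bad <- setdiff(names(coefficients), c("(Intercept)", .descriptor_names))
  if (length(bad) > 0L) {
    config_error(sprintf("unknown descriptor(s) in coefficients: %s",
                         paste(bad, collapse = ", ")))
  }
  grammar <- .syn_grammar()
  with_seed(seed, {
    smiles <- vapply(seq_len(n), function(i) .random_molecule(grammar),
                     character(1))
    recs <- molecule_records(smiles, id = sprintf("syn%d", seq_len(n)))
    can <- ob_canonical(smiles)
    graphs <- lapply(can, parse_smiles, canonical_input = TRUE)
    ob <- .ob_props(can)
    desc <- do.call(rbind, lapply(seq_len(n), function(i) {
      unlist(compute_descriptors(graphs[[i]],
                                 ob = list(logP = ob$logP[[i]],
                                           TPSA = ob$TPSA[[i]])))
    }))
    eta <- rep(unname(coefficients["(Intercept)"] %||% 0), n)
    eta[is.na(eta)] <- 0
    for (nm in intersect(names(coefficients), .descriptor_names)) {
      eta <- eta + coefficients[[nm]] * desc[, nm]
    }
    recs$value <- eta + rnorm(n, 0, noise_sd)
    attr(recs, "true_descriptors") <- desc
    attr(recs, "true_value") <- eta
    recs
  })
}
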