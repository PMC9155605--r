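test_that("fragment enumeration matches hand enumeration on small inputs", {
  pr <- enumerate_fragments("CCC", max_atoms = 2)
  expect_setequal(pr$fragment, c("C", "CC"))

  benz <- enumerate_fragments("c1ccccc1", max_atoms = 6)
  expect_true("c1ccccc1" %in% benz$fragment)
  expect_equal(max(benz$size), 6L)

  atoms_only <- enumerate_fragments("CCO", max_atoms = 1)
  expect_setequal(atoms_only$fragment, c("C", "O"))

  expect_error(enumerate_fragments("CC", max_atoms = 0),
               class = "herbsig_contract_error")
})

test_that("support counts molecule-level presence", {
  dataset <- c("Cc1ccccc1", "Oc1ccccc1", "C1CCCCC1")
  expect_equal(fragment_support("c1ccccc1", dataset), 2 / 3)
  ## single-atom fragments match element + aromatic flag
  expect_equal(fragment_support("c", dataset), 2 / 3)
  expect_equal(fragment_support("C", c("CCO", "CC", "C1CCCCC1")), 1)
  expect_equal(fragment_support("c1ccc2ccccc2c1",
                                c("CCO", "c1ccccc1")), 0)
  expect_error(fragment_support("C", list()), class = "herbsig_contract_error")
})

test_that("enumerated presence equals brute-force embedding search", {
  smiles <- random_test_smiles(12, seed = 121, max_heavy = 10)
  graphs <- lapply(smiles, function(s) keep_largest_component(parse_smiles(s)))
  frag_tbl <- do.call(rbind, lapply(graphs, enumerate_fragments,
                                    max_atoms = 4))
  frags <- unique(frag_tbl$fragment)
  keysets <- lapply(graphs, function(g) {
    enumerate_fragments(g, max_atoms = 4)$key
  })
  for (f in frags) {
    pat <- herbsig:::parse_pattern(f)
    key <- frag_tbl$key[match(f, frag_tbl$fragment)]
    for (i in seq_along(graphs)) {
      expect_equal(key %in% keysets[[i]],
                   brute_force_contains(pat, graphs[[i]]),
                   info = sprintf("fragment %s in %s", f, smiles[[i]]))
    }
  }
})

test_that("support is anti-monotone over the fragment lattice", {
  dataset <- lapply(random_test_smiles(15, seed = 141), function(s) {
    keep_largest_component(parse_smiles(s))
  })
  g <- keep_largest_component(parse_smiles(random_test_smiles(1, seed = 131)))
  tbl <- enumerate_fragments(g, max_atoms = 4)
  pats <- lapply(tbl$fragment, herbsig:::parse_pattern)
  sup <- vapply(tbl$fragment, function(f) fragment_support(f, dataset),
                numeric(1))
  checked <- 0L
  for (i in seq_along(pats)) {
    for (j in seq_along(pats)) {
      if (tbl$size[[i]] >= tbl$size[[j]]) next
      if (herbsig:::.has_embedding(pats[[i]], pats[[j]])) {
        expect_gte(sup[[i]], sup[[j]])    # subfragment at least as frequent
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 0L)
})

test_that("mining recovers a planted fragment and honours thresholds", {
  recs <- generate_dataset(120, planted_rule(prevalence = 0.3, seed = 151))
  pos <- recs[recs$label == 1, ]
  neg <- recs[recs$label == 0, ]
  res <- mine_enriched(pos, neg, min_support_pos = 0.05,
                       max_support_neg = 0.10, min_fold = 5, max_atoms = 5)
  expect_gt(nrow(res), 0)
  top <- herbsig:::parse_pattern(res$fragment[[1]])
  planted <- herbsig:::parse_pattern("ClCC(=O)O")
  expect_equal(n_atoms(top), n_atoms(planted))
  expect_true(brute_force_contains(planted, top))
  expect_true(all(res$support_pos >= 0.05))
  expect_true(all(res$support_neg <= 0.10))
  expect_true(all(res$fold_change >= 5))

  ## identical classes cannot be enriched
  same <- mine_enriched(pos, pos, min_support_pos = 0.05,
                        max_support_neg = 1.0, min_fold = 5, max_atoms = 4)
  expect_equal(nrow(same), 0L)
})

test_that("mining output is invariant to row order and SMILES rendering", {
  recs <- generate_dataset(60, planted_rule(prevalence = 0.35, seed = 161))
  pos <- recs[recs$label == 1, ]
  neg <- recs[recs$label == 0, ]
  res1 <- mine_enriched(pos, neg, min_support_pos = 0.10,
                        max_support_neg = 0.10, min_fold = 5, max_atoms = 4)
  res2 <- mine_enriched(pos[rev(seq_len(nrow(pos))), ],
                        neg[rev(seq_len(nrow(neg))), ],
                        min_support_pos = 0.10, max_support_neg = 0.10,
                        min_fold = 5, max_atoms = 4)
  expect_identical(res1, res2)

  rerender <- function(df) {
    df$smiles <- vapply(df$smiles, function(s) {
      random_smiles(parse_smiles(s), 1, seed = nchar(s))
    }, character(1))
    df
  }
  res3 <- mine_enriched(rerender(pos), rerender(neg),
                        min_support_pos = 0.10, max_support_neg = 0.10,
                        min_fold = 5, max_atoms = 4)
  expect_identical(res1, res3)
})

test_that("maximal-only filtering collapses dominated subfragments", {
  recs <- generate_dataset(80, planted_rule(prevalence = 0.3, seed = 171))
  pos <- recs[recs$label == 1, ]
  neg <- recs[recs$label == 0, ]
  full <- mine_enriched(pos, neg, min_support_pos = 0.05,
                        max_support_neg = 0.10, min_fold = 5, max_atoms = 5)
  maxi <- mine_enriched(pos, neg, min_support_pos = 0.05,
                        max_support_neg = 0.10, min_fold = 5, max_atoms = 5,
                        maximal_only = TRUE)
  expect_lte(nrow(maxi), nrow(full))
  expect_true(all(maxi$fragment %in% full$fragment))
})

test_that("mining presets encode the published threshold regimes", {
  p <- mining_preset("s5", fold = 10)
  expect_equal(p$min_support_pos, 0.05)
  expect_equal(p$min_fold, 10)
  p2 <- mining_preset("s2-10", fold = 5)
  expect_equal(p2$min_support_pos, 0.02)
  expect_equal(p2$max_support_neg, 0.10)
  expect_equal(p2$min_fold, 5)
  expect_error(mining_preset("s5", fold = 7), class = "herbsig_contract_error")
})
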