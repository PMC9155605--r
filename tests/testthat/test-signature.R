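test_that("all-pairs distances reproduce hand censuses", {
  benz <- parse_smiles("c1ccccc1")
  D <- all_pairs_distances(benz)
  expect_equal(unname(table(D[upper.tri(D)])), array(c(6L, 6L, 3L)))

  prop <- parse_smiles("CCC")
  Dp <- all_pairs_distances(prop)
  expect_equal(Dp[1, 3], 2)

  single <- all_pairs_distances(parse_smiles("C"))
  expect_equal(dim(single), c(1L, 1L))

  disc <- all_pairs_distances(parse_smiles("C.O"))
  expect_true(is.infinite(disc[1, 2]))
})

test_that("distances match a Floyd-Warshall brute force on random molecules", {
  for (smi in random_test_smiles(200, seed = 51, max_heavy = 12)) {
    g <- parse_smiles(smi)
    expect_equal(all_pairs_distances(g), fw_distances(g))
  }
})

test_that("signatures reproduce hand counts on ethane and ethanol", {
  eth <- parse_smiles("CC")
  sig <- compute_signature(eth, assign_labels(eth), cutoffs = c(1, 2, 3))
  hh <- sig[paste0("Hydrophobic:Hydrophobic_d", 1:3)]
  expect_equal(unname(hh), c(1, 1, 1))
  expect_true(all(sig[setdiff(names(sig), names(hh))] == 0))

  etoh <- parse_smiles("CCO")
  s <- compute_signature(etoh, assign_labels(etoh), cutoffs = 1:2)
  expect_equal(unname(s["Hydrophobic:Acceptor_d2"]), 2)
  expect_equal(unname(s["Hydrophobic:Acceptor_d1"]), 1)
  expect_equal(unname(s["Hydrophobic:Donor_d2"]), 2)
})

test_that("signature rows are cumulative and non-negative", {
  cutoffs <- 1:10
  for (smi in random_test_smiles(30, seed = 61)) {
    g <- keep_largest_component(parse_smiles(smi))
    sig <- compute_signature(g, assign_labels(g), cutoffs)
    m <- matrix(sig, nrow = length(cutoffs))
    expect_true(all(m >= 0))
    expect_true(all(apply(m, 2, function(col) all(diff(col) >= 0))))
  }
})

test_that("single-label atoms satisfy the pair-count sum rule", {
  ## a labelling with exactly one label per atom: every unordered atom
  ## pair lands in exactly one pair bin, so the largest cutoff totals
  ## n(n-1)/2 for connected molecules
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines("@aromatic Aromatic", path)   # others fall back to Neutral
  tbl <- read_rule_table(path)
  for (smi in random_test_smiles(20, seed = 71, max_heavy = 12)) {
    g <- keep_largest_component(parse_smiles(smi))
    L <- assign_labels(g, tbl)
    expect_true(all(rowSums(L) == 1L))
    sig <- compute_signature(g, L, cutoffs = c(1, 50))
    tot <- sum(sig[grepl("_d50$", names(sig))])
    n <- n_atoms(g)
    expect_equal(tot, n * (n - 1) / 2)
  }
})

test_that("signatures are invariant to SMILES re-rendering", {
  for (smi in random_test_smiles(100, seed = 81)) {
    g <- parse_smiles(smi)
    sig0 <- compute_signature(g, assign_labels(g))
    for (r in random_smiles(g, 5, seed = 9)) {
      g2 <- parse_smiles(r)
      expect_identical(compute_signature(g2, assign_labels(g2)), sig0)
    }
  }
})

test_that("featurize_dataset has fixed layout and preserves order", {
  recs <- molecule_records(c("CCO", "c1ccccc1", "CC(=O)O"))
  X <- featurize_dataset(recs)
  expect_equal(dim(X), c(3L, 28L * 10L + 10L))
  expect_equal(colnames(X), signature_colnames())
  expect_equal(rownames(X), recs$id)

  dup <- molecule_records(c("CCO", "OCC"), id = c("a", "b"))
  Xd <- featurize_dataset(dup)
  expect_equal(unname(Xd[1, ]), unname(Xd[2, ]))

  rev_recs <- recs[3:1, ]
  Xr <- featurize_dataset(rev_recs)
  expect_equal(unname(Xr[3:1, ]), unname(X), ignore_attr = TRUE)

  with_bad <- molecule_records(c("CCO", "C1CC"), id = c("ok", "bad"))
  Xb <- suppressMessages(featurize_dataset(with_bad))
  expect_equal(rownames(Xb), "ok")
  expect_equal(attr(Xb, "dropped"), "bad")

  expect_error(featurize_dataset(molecule_records("C1CC")),
               class = "herbsig_data_error")
})

test_that("contract violations are rejected", {
  g <- parse_smiles("CCO")
  L <- assign_labels(parse_smiles("CC"))
  expect_error(compute_signature(g, L), class = "herbsig_contract_error")
  expect_error(compute_signature(g, assign_labels(g), cutoffs = c(3, 2)),
               class = "herbsig_contract_error")
})
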