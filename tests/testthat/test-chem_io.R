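test_that("parse_smiles builds the expected heavy-atom graphs", {
  g <- parse_smiles("c1ccccc1")
  expect_equal(n_atoms(g), 6L)
  expect_equal(nrow(g$bonds), 6L)
  expect_equal(n_components(g), 1L)
  expect_true(all(g$atoms$element == "C"))
  expect_true(all(g$atoms$aromatic))

  g1 <- parse_smiles("C")
  expect_equal(n_atoms(g1), 1L)
  expect_equal(nrow(g1$bonds), 0L)
  expect_equal(g1$atoms$hcount, 4L)

  gm <- parse_smiles("C1CC1.O")
  expect_equal(n_atoms(gm), 4L)
  expect_equal(nrow(gm$bonds), 3L)
  expect_equal(n_components(gm), 2L)
  expect_equal(sort(tabulate(gm$component_ids + 1L)), c(1L, 3L))

  ac <- parse_smiles("CC(=O)[O-]")
  expect_equal(sum(ac$atoms$charge), -1L)
})

test_that("malformed SMILES raise positional parse errors", {
  err <- tryCatch(parse_smiles("C1CC"), herbsig_parse_error = identity)
  expect_s3_class(err, "herbsig_parse_error")
  expect_match(conditionMessage(err), "unclosed ring")
  expect_false(is.na(err$position))

  expect_error(parse_smiles("C(C"), class = "herbsig_parse_error")
  expect_error(parse_smiles("CX"), class = "herbsig_parse_error")
  expect_error(parse_smiles("[Qq]C"), class = "herbsig_parse_error")
  expect_error(parse_smiles(""), class = "herbsig_parse_error")
})

test_that("canonicalize is rendering-invariant, idempotent and injective", {
  expect_identical(canonicalize("OCC"), canonicalize("CCO"))
  expect_identical(canonicalize(canonicalize("c1ccc(Cl)cc1O")),
                   canonicalize("c1ccc(Cl)cc1O"))
  expect_false(canonicalize("CCO") == canonicalize("CCN"))
})

test_that("parse -> canonical write -> parse preserves graph invariants", {
  for (smi in random_test_smiles(25, seed = 11)) {
    g1 <- parse_smiles(smi)
    g2 <- parse_smiles(write_smiles(g1))
    expect_equal(sort(g1$atoms$element), sort(g2$atoms$element))
    expect_equal(nrow(g1$bonds), nrow(g2$bonds))
    deg <- function(g) sort(tabulate(c(g$bonds$from, g$bonds$to) + 1L,
                                     nbins = n_atoms(g)))
    expect_equal(deg(g1), deg(g2))
    expect_equal(sort(g1$atoms$hcount), sort(g2$atoms$hcount))
  }
})

test_that("component labelling matches an independent BFS on random graphs", {
  smiles <- random_test_smiles(200, seed = 21)
  ## add some multi-component salts/mixtures
  smiles[seq(1, 200, by = 10)] <- paste0(smiles[seq(1, 200, by = 10)], ".O")
  for (smi in smiles) {
    g <- parse_smiles(smi)
    oracle <- bfs_components(g)
    ## same partition (ids may be permuted)
    expect_equal(length(unique(g$component_ids)), length(unique(oracle)))
    expect_true(all(tapply(oracle, g$component_ids,
                           function(x) length(unique(x))) == 1L))
  }
})

test_that("read_smiles_file handles order, skips and label mapping", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO mol1 1", "c1ccccc1 mol2 0", "", "# comment",
               "C1CC mol3 1", "CCN mol4 active"), path)
  recs <- read_smiles_file(path, label_col = 3L)
  expect_equal(recs$id, c("mol1", "mol2", "mol4"))
  expect_equal(recs$label, c(1L, 0L, 1L))
  expect_equal(attr(recs, "skipped"), 1L)

  expect_error(read_smiles_file(file.path(tempdir(), "nope.smi")),
               class = "herbsig_data_error")
  allbad <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("C1CC", "X"), allbad)
  expect_error(read_smiles_file(allbad), class = "herbsig_data_error")
})

test_that("prediction tables round-trip through CSV", {
  recs <- molecule_records(c("CCO", "c1ccccc1"))
  preds <- data.frame(herbicide_prob = c(0.91, 0.12),
                      ames_class = c("active", NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_prediction_table(recs, preds, path)
  back <- read.csv(path)
  expect_equal(back$id, recs$id)
  expect_equal(back$herbicide_prob, preds$herbicide_prob)
  expect_true(is.na(back$ames_class[[2]]) || back$ames_class[[2]] == "")

  expect_error(write_prediction_table(recs, preds[1, , drop = FALSE], path),
               class = "herbsig_contract_error")
  header_only <- molecule_records(character(0))
  write_prediction_table(header_only, NULL, path)
  expect_equal(nrow(read.csv(path)), 0L)
})

test_that("multi-component molecules reduce to their largest component", {
  g <- keep_largest_component(parse_smiles("CCO.[Na+]"))
  expect_equal(n_components(g), 1L)
  expect_equal(n_atoms(g), 3L)
  expect_equal(sort(g$atoms$element), c("C", "C", "O"))
})

test_that("molecules above 2 kDa warn but still parse", {
  big <- paste0("C", strrep("(Br)C", 25))
  expect_warning(parse_smiles(big), "2 kDa")
})
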