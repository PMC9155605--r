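test_that("stratified folds balance size and prevalence", {
  y <- rep(c(1, 0), each = 50)
  f <- stratified_kfold(y, k = 10, seed = 1)
  expect_true(all(table(f) == 10))
  expect_true(all(table(f[y == 1]) == 5))

  expect_identical(stratified_kfold(y, 10, seed = 7),
                   stratified_kfold(y, 10, seed = 7))

  ## herbicide-set shape: 997 positives across 10 folds -> 99 or 100 each
  yh <- rep(c(1, 0), c(997, 3516))
  fh <- stratified_kfold(yh, k = 10, seed = 3)
  pos_per_fold <- table(fh[yh == 1])
  expect_true(all(pos_per_fold %in% c(99L, 100L)))
  expect_true(max(table(fh)) - min(table(fh)) <= 1L)

  expect_error(stratified_kfold(c(1, rep(0, 20)), k = 10),
               class = "herbsig_contract_error")
})

test_that("blind split is exact, disjoint and deterministic", {
  bs <- blind_split(4513, fraction = 0.10, seed = 2)
  expect_equal(length(bs$test), 451L)
  expect_length(intersect(bs$train, bs$test), 0)
  expect_equal(sort(c(bs$train, bs$test)), 1:4513)

  expect_equal(length(blind_split(10, 0.10, seed = 1)$test), 1L)
  expect_identical(blind_split(100, 0.2, seed = 5),
                   blind_split(100, 0.2, seed = 5))
  expect_error(blind_split(5, 0.01), class = "herbsig_contract_error")

  ys <- rep(c(1, 0), c(20, 80))
  st <- blind_split(100, 0.10, seed = 4, labels = ys)
  expect_equal(length(st$test), 10L)
  expect_equal(sum(ys[st$test]), 2L)     # stratified option keeps prevalence
})

test_that("classification metrics agree with confusion arithmetic", {
  ev <- evaluate_classification(
    rep(c(1, 0), c(10, 10)),
    c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 3), rep(0.1, 7)))
  oracle <- confusion_metrics(tp = 8, fn = 2, fp = 3, tn = 7)
  expect_equal(ev$accuracy, oracle$accuracy)
  expect_equal(ev$mcc, oracle$mcc)
  expect_equal(ev$sensitivity, oracle$sensitivity)
  expect_equal(ev$specificity, oracle$specificity)
  expect_equal(unname(ev$confusion), c(8L, 2L, 3L, 7L))

  set.seed(101)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 2)
    th <- 0.5
    ev <- evaluate_classification(y, s, th)
    p <- as.integer(s >= th)
    oracle <- confusion_metrics(sum(p & y), sum(!p & y), sum(p & !y),
                                sum(!p & !y))
    expect_equal(ev$accuracy, oracle$accuracy)
    expect_equal(ev$mcc, oracle$mcc)
    expect_equal(ev$roc_auc, pairwise_auc(y, s))
  }
})

test_that("degenerate score vectors hit the expected fixed points", {
  y <- rep(c(1, 0), each = 5)
  perfect <- evaluate_classification(y, as.numeric(y))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$roc_auc, 1)

  all_pos <- evaluate_classification(y, rep(1, 10))
  expect_equal(all_pos$accuracy, 0.5)
  expect_equal(all_pos$mcc, 0)

  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_error(evaluate_classification(rep(1, 5), runif(5)),
               class = "herbsig_contract_error")
})

test_that("PR-AUC integrates the precision-recall curve", {
  y <- c(1, 1, 0, 0)
  s <- c(0.9, 0.8, 0.7, 0.1)
  expect_equal(pr_auc(y, s), 1)          # both positives rank first
  y2 <- c(1, 0, 1, 0)
  ## thresholds: P=1 R=.5; P=2/3 R=1 -> AP = .5*1 + .5*(2/3)
  expect_equal(pr_auc(y2, s), 0.5 + 0.5 * 2 / 3)
})

test_that("regression evaluation implements the 10% trimming rule", {
  x <- seq_len(20) / 10
  perfect <- evaluate_regression(x, x)
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$rmse, 0)

  scaled <- evaluate_regression(x, 2 * x)
  expect_equal(scaled$pearson_r, 1)
  expect_true(scaled$rmse > 0)

  set.seed(5)
  y <- x + rnorm(20, 0, 0.01)
  y[c(4, 18)] <- y[c(4, 18)] + 3        # planted outliers
  er <- evaluate_regression(x, y, trim_fraction = 0.10)
  expect_equal(er$n_removed, 2L)
  expect_setequal(er$removed, c(4L, 18L))
  expect_true(er$trimmed_r >= er$pearson_r)

  expect_error(evaluate_regression(rep(1, 5), rnorm(5)),
               class = "herbsig_contract_error")
})

test_that("Fisher r-to-z comparison matches its closed form", {
  eq <- fisher_r_to_z_compare(0.5, 100, 0.5, 200)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  ## minnow-model comparison: r = 0.86 vs 0.74 at n = 554
  cmp <- fisher_r_to_z_compare(0.86, 554, 0.74, 554)
  z_oracle <- (atanh(0.86) - atanh(0.74)) / sqrt(1 / 551 + 1 / 551)
  expect_equal(cmp$z, z_oracle)
  expect_lte(cmp$p, 0.05)

  swap <- fisher_r_to_z_compare(0.74, 554, 0.86, 554)
  expect_equal(swap$z, -cmp$z)
  expect_error(fisher_r_to_z_compare(0.5, 3, 0.4, 100),
               class = "herbsig_contract_error")
  expect_error(fisher_r_to_z_compare(1, 10, 0.4, 100),
               class = "herbsig_contract_error")
})

test_that("training is deterministic and sane on toy sets", {
  set.seed(7)
  X <- cbind(a = c(rnorm(20, 0), rnorm(20, 4)), b = rnorm(40))
  y <- rep(c(0, 1), each = 20)
  m1 <- train_model(X, y, model_spec(seed = 3))
  m2 <- train_model(X, y, model_spec(seed = 3))
  expect_identical(predict(m1, X), predict(m2, X))
  expect_equal(roc_auc(y, predict(m1, X)), 1)

  ## randomForest notes the degenerate constant response; that is the point
  const <- suppressWarnings(
    train_model(X, rep(2.5, 40), model_spec("regression", seed = 1)))
  expect_true(all(abs(predict(const, X) - 2.5) < 1e-9))

  expect_error(train_model(X, rep(1, 40), model_spec()),
               class = "herbsig_contract_error")
  expect_error(train_model(X[1:10, ], y, model_spec()),
               class = "herbsig_contract_error")
})

test_that("cross-validation predicts every sample exactly once", {
  set.seed(11)
  X <- cbind(x1 = rnorm(30), x2 = rnorm(30))
  y <- rep(c(0L, 1L), 15)               # both classes well-populated
  for (k in c(2L, 10L)) {
    cv <- cross_validate(X, y, model_spec(ntree = 50L, seed = 2), k = k,
                         seed = 2)
    expect_false(anyNA(cv$predictions))
    expect_length(cv$predictions, 30L)
  }
  ## leave-one-out on a regression target
  yr <- X[, 1] * 2 + rnorm(30, 0, 0.1)
  cv <- cross_validate(X, yr, model_spec("regression", algorithm = "linear"),
                       k = 30L, seed = 4)
  expect_false(anyNA(cv$predictions))
})

test_that("greedy forward selection finds planted signal and breaks ties", {
  set.seed(13)
  n <- 120
  informative <- rep(c(0, 3), each = n / 2) + rnorm(n, 0, 0.3)
  X <- cbind(matrix(rnorm(n * 10), n), informative,
             matrix(rnorm(n * 10), n))
  colnames(X) <- c(sprintf("noise%d", 1:10), "signal", sprintf("noise%d", 11:20))
  y <- rep(c(0L, 1L), each = n / 2)
  spec <- model_spec(algorithm = "logistic", seed = 5)
  ## glm warns about perfect separation on this cleanly planted signal
  sel <- suppressWarnings(greedy_forward_selection(X, y, spec, k = 3L))
  expect_equal(sel[[1]], "signal")

  single <- suppressWarnings(
    greedy_forward_selection(X, y, spec, tolerance = Inf, k = 3L))
  expect_length(single, 1L)

  Xd <- cbind(dupA = informative, dupB = informative)
  sel2 <- suppressWarnings(
    greedy_forward_selection(Xd, y, spec, tolerance = Inf, k = 3L))
  expect_equal(sel2, "dupA")
})

test_that("label noise degrades cross-validated recovery monotonically", {
  ## planted linear rule, three noise levels, three seeds averaged
  set.seed(17)
  n <- 150
  X <- cbind(s = rnorm(n), matrix(rnorm(n * 5), n))
  colnames(X) <- c("s", sprintf("n%d", 1:5))
  y0 <- as.integer(X[, "s"] > 0)
  mean_auc <- function(noise) {
    mean(vapply(1:3, function(sd) {
      set.seed(sd * 100)
      flip <- runif(n) < noise
      y <- ifelse(flip, 1L - y0, y0)
      if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
      cross_validate(X, y, model_spec(ntree = 100L, seed = sd), k = 5L,
                     seed = sd)$pooled$roc_auc
    }, numeric(1)))
  }
  aucs <- vapply(c(0, 0.05, 0.10), mean_auc, numeric(1))
  expect_true(all(diff(aucs) < 0))
})

test_that("models persist with a plain-text spec and round-trip", {
  set.seed(19)
  X <- cbind(a = rnorm(40), b = rnorm(40))
  y <- as.integer(X[, 1] > 0)
  m <- train_model(X, y, model_spec(ntree = 50L, seed = 8))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path, checksum = "abc123")
  back <- load_model(path)
  expect_identical(predict(back, X), predict(m, X))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$algorithm, "rf")
  expect_equal(meta$ntree, 50L)
  expect_equal(meta$seed, 8L)
  expect_equal(meta$training_checksum, "abc123")
})

test_that("predict_profile produces one column group per endpoint", {
  recs <- generate_dataset(30, planted_rule(prevalence = 0.4, seed = 23))
  X <- featurize_dataset(recs)
  clf <- train_model(X, recs$label, model_spec(ntree = 50L, seed = 1))
  reg <- train_model(X, seq_len(nrow(X)) / 10,
                     model_spec("regression", ntree = 50L, seed = 1))
  out <- predict_profile(recs, list(herbicide = list(model = clf),
                                    lc50 = list(model = reg)))
  expect_equal(nrow(out), 30L)
  expect_true(all(c("id", "smiles", "herbicide_class", "herbicide_prob",
                    "lc50_value") %in% colnames(out)))
  expect_true(all(out$herbicide_prob >= 0 & out$herbicide_prob <= 1))

  empty <- predict_profile(recs, list())
  expect_equal(colnames(empty), c("id", "smiles"))

  out2 <- predict_profile(recs, list(herbicide = list(model = clf)))
  expect_identical(out2, predict_profile(recs, list(herbicide = list(model = clf))))
})

test_that("rank-based AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(y, s), ref)
  }
})
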