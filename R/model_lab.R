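#' Model specification
#'
#' Describes a supervised model: task, learning algorithm, hyperparameters
#' and random seed.  The default mirrors the herbicidal-activity model: a
#' random forest with 300 trees.
#'
#' @param task `"classification"` or `"regression"`.
#' @param algorithm `"rf"` (random forest, default), `"logistic"`
#'   (binomial GLM; classification only) or `"linear"` (least squares;
#'   regression only).
#' @param ntree number of trees for `"rf"` (default 300).
#' @param seed integer RNG seed recorded with the spec.
#' @param features optional character vector restricting training to a
#'   feature subset.
#' @param threshold classification decision threshold (default 0.5).
#' @return a `model_spec` list.
#' @export
model_spec <- function(task = c("classification", "regression"),
                       algorithm = "rf", ntree = 300L, seed = 1L,
                       features = NULL, threshold = 0.5) {
  task <- match.arg(task)
  ok <- switch(task,
               classification = c("rf", "logistic"),
               regression = c("rf", "linear"))
  if (!algorithm %in% ok) {
    contract_error(sprintf("algorithm '%s' unsupported for %s", algorithm, task))
  }
  structure(list(task = task, algorithm = algorithm, ntree = as.integer(ntree),
                 seed = as.integer(seed), features = features,
                 threshold = threshold),
            class = "model_spec")
}

#' Stratified k-fold assignment
#'
#' Shuffles each class independently and deals its members across folds so
#' that fold sizes differ by at most one sample overall and per-fold class
#' prevalence is within one sample of the global prevalence.
#' Deterministic under `seed`.
#'
#' @param labels binary (or categorical) label vector.
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @return integer fold assignment in `1..k`, one per sample.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  if (k < 2L) contract_error("k must be >= 2")
  if (n < k) contract_error("need at least k samples")
  tab <- table(labels)
  if (any(tab < k)) {
    contract_error(sprintf(
      "class '%s' has fewer members (%d) than folds (%d)",
      names(tab)[which.min(tab)], min(tab), k))
  }
  fold <- integer(n)
  totals <- integer(k)
  with_seed(seed, {
    for (cls in names(tab)) {
      idx <- sample(which(labels == cls))
      m <- length(idx)
      base <- m %/% k
      extra <- m %% k
      sizes <- rep(base, k)
      if (extra > 0L) {
        ## extras go to the currently smallest folds (ties: lowest index)
        recv <- order(totals, seq_len(k))[seq_len(extra)]
        sizes[recv] <- sizes[recv] + 1L
      }
      pos <- 1L
      for (f in seq_len(k)) {
        if (sizes[[f]] > 0L) {
          fold[idx[pos:(pos + sizes[[f]] - 1L)]] <- f
          pos <- pos + sizes[[f]]
        }
      }
      totals <- totals + sizes
    }
  })
  fold
}

#' Random blind-test split
#'
#' Holds out `round(fraction * n)` records selected at random (simple
#' random sampling by default, stratified by label optionally) for use as
#' an external validation set.
#'
#' @param n number of records, or a vector/data frame whose length/rows
#'   give it.
#' @param fraction held-out fraction (default 0.10).
#' @param seed RNG seed.
#' @param labels optional label vector; when supplied, sampling is
#'   stratified per class.
#' @return list with integer index vectors `train` and `test`.
#' @export
blind_split <- function(n, fraction = 0.10, seed = 1L, labels = NULL) {
  if (is.data.frame(n)) n <- nrow(n) else if (length(n) > 1L) n <- length(n)
  n <- as.integer(n)
  if (fraction <= 0 || fraction >= 1) {
    contract_error("fraction must be in (0, 1)")
  }
  m <- as.integer(round_half_up(fraction * n))
  if (m == 0L || m == n) contract_error("fraction yields an empty split")
  test <- with_seed(seed, {
    if (is.null(labels)) {
      sort(sample(n, m))
    } else {
      per <- split(seq_len(n), labels)
      take <- vapply(per, function(ix) round_half_up(fraction * length(ix)),
                     numeric(1))
      ## adjust rounding so the total held-out count is exact
      while (sum(take) > m) take[[which.max(take)]] <- take[[which.max(take)]] - 1
      while (sum(take) < m) take[[which.min(take)]] <- take[[which.min(take)]] + 1
      sort(unlist(Map(function(ix, t) sample(ix, t), per, take),
                  use.names = FALSE))
    }
  })
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Train a supervised model
#'
#' @param X numeric feature matrix.
#' @param y labels (0/1) or continuous endpoint values.
#' @param spec a [model_spec()].
#' @return a `herbsig_model` wrapping the fitted learner and its spec.
#' @export
train_model <- function(X, y, spec = model_spec()) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) contract_error("X rows must equal length(y)")
  if (anyNA(X)) contract_error("X contains missing features")
  if (!is.null(spec$features)) X <- X[, spec$features, drop = FALSE]
  if (spec$task == "classification" && length(unique(y)) < 2L) {
    contract_error("classification requires both classes in y")
  }
  colnames(X) <- .safe_names(colnames(X))
  fit <- with_seed(spec$seed, {
    switch(paste(spec$task, spec$algorithm),
      "classification rf" = randomForest::randomForest(
        X, factor(y, levels = c(0, 1)), ntree = spec$ntree),
      "regression rf" = randomForest::randomForest(X, as.numeric(y),
                                                   ntree = spec$ntree),
      "classification logistic" = stats::glm.fit(
        cbind(1, X), y, family = stats::binomial()),
      "regression linear" = stats::lm.fit(cbind(1, X), as.numeric(y))
    )
  })
  structure(list(fit = fit, spec = spec, features = colnames(X)),
            class = "herbsig_model")
}

.safe_names <- function(x) {
  if (is.null(x)) return(NULL)
  make.names(x, unique = TRUE)
}

#' Predict scores or values from a trained model
#'
#' @param object a `herbsig_model`.
#' @param X feature matrix (same layout as training).
#' @param ... ignored.
#' @return classification: probabilities of the positive class in
#'   `[0, 1]`; regression: predicted values.
#' @export
predict.herbsig_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (!is.null(object$spec$features)) {
    X <- X[, object$spec$features, drop = FALSE]
  }
  colnames(X) <- .safe_names(colnames(X))
  spec <- object$spec
  if (spec$algorithm == "rf") {
    if (spec$task == "classification") {
      unname(predict(object$fit, X, type = "prob")[, "1"])
    } else {
      unname(predict(object$fit, X))
    }
  } else {
    co <- object$fit$coefficients
    co[is.na(co)] <- 0                  # collinear columns dropped by the fit
    eta <- drop(cbind(1, X) %*% co)
    if (spec$task == "classification") 1 / (1 + exp(-eta)) else eta
  }
}

#' Classification evaluation report
#'
#' Accuracy, sensitivity and specificity at the decision threshold, MCC
#' from the confusion matrix, ROC-AUC by rank concordance (ties counted
#' one half) and PR-AUC by precision-recall step integration.
#'
#' @param y_true 0/1 labels.
#' @param scores classifier scores in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return list of metrics plus the confusion counts.
#' @export
evaluate_classification <- function(y_true, scores, threshold = 0.5) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores)) {
    contract_error("y_true and scores differ in length")
  }
  if (length(unique(y_true)) < 2L) {
    contract_error("AUC undefined: y_true holds a single class")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y_true == 1L)
  tn <- sum(pred == 0L & y_true == 0L)
  fp <- sum(pred == 1L & y_true == 0L)
  fn <- sum(pred == 0L & y_true == 1L)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    accuracy = (tp + tn) / length(y_true),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
    roc_auc = roc_auc(y_true, scores),
    pr_auc = pr_auc(y_true, scores),
    confusion = c(TP = tp, FN = fn, FP = fp, TN = tn),
    threshold = threshold
  )
}

#' Rank-concordance ROC-AUC
#'
#' Equals the probability that a random positive outranks a random
#' negative, with ties counted one half (Mann-Whitney statistic).
#'
#' @param y_true 0/1 labels.
#' @param scores classifier scores.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores) {
  pos <- y_true == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) contract_error("AUC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall AUC (average precision)
#'
#' Step-function integration of the precision-recall curve: the sum over
#' descending-score thresholds of the recall increment times the
#' precision at that threshold.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in `[0, 1]`.
#' @export
pr_auc <- function(y_true, scores) {
  n1 <- sum(y_true == 1L)
  if (n1 == 0L) contract_error("PR-AUC needs positive samples")
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / n1
  ## evaluate only at distinct-score boundaries (ties share a threshold)
  last <- rev(!duplicated(rev(s)))
  precision <- precision[last]; recall <- recall[last]
  sum(diff(c(0, recall)) * precision)
}

#' Regression evaluation report
#'
#' Pearson correlation and RMSE over all points, plus a trimmed Pearson
#' correlation computed after removing the `round(trim_fraction * n)`
#' points with the largest absolute residuals.  The trimming is purely a
#' reporting device; predictions are untouched.
#'
#' @param y_true observed values.
#' @param y_pred predicted values.
#' @param trim_fraction fraction of points removed for the trimmed
#'   correlation (default 0.10).
#' @return list with `pearson_r`, `rmse`, `trimmed_r`, `n_removed` and the
#'   indices of removed points.
#' @export
evaluate_regression <- function(y_true, y_pred, trim_fraction = 0.10) {
  if (length(y_true) != length(y_pred)) {
    contract_error("y_true and y_pred differ in length")
  }
  n <- length(y_true)
  if (n < 3L) contract_error("need at least 3 points")
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) {
    contract_error("correlation undefined for zero-variance input")
  }
  resid <- abs(y_true - y_pred)
  n_rm <- as.integer(round_half_up(trim_fraction * n))
  removed <- if (n_rm > 0L) {
    order(resid, decreasing = TRUE)[seq_len(n_rm)]
  } else {
    integer(0)
  }
  keep <- setdiff(seq_len(n), removed)
  trimmed_r <- if (length(keep) >= 3L &&
                   stats::sd(y_true[keep]) > 0 && stats::sd(y_pred[keep]) > 0) {
    cor(y_true[keep], y_pred[keep])
  } else {
    NA_real_
  }
  list(
    pearson_r = cor(y_true, y_pred),
    rmse = sqrt(mean((y_true - y_pred)^2)),
    trimmed_r = trimmed_r,
    n_removed = n_rm,
    removed = removed
  )
}

#' Compare two Pearson correlations by Fisher r-to-z
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided p-value from the standard normal.
#'
#' @param r1,r2 correlation coefficients (`|r| < 1`).
#' @param n1,n2 sample sizes (`> 3`).
#' @return list with `z` and `p`.
#' @export
fisher_r_to_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) contract_error("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) contract_error("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Cross-validated evaluation
#'
#' Stratified (classification) or plain (regression) k-fold
#' cross-validation.  Out-of-fold predictions are pooled over all folds
#' and the headline metrics computed once on the pooled vector; per-fold
#' metrics are also reported.  When the spec carries a feature subset
#' obtained by selection, selection should be re-run inside each fold via
#' `nested_selection`.
#'
#' @param X feature matrix.
#' @param y labels or values.
#' @param spec a [model_spec()].
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param nested_selection optional list of arguments (`metric`,
#'   `tolerance`, `k`) enabling greedy forward selection nested within
#'   each training fold.
#' @return list with `pooled` (metric list), `per_fold`, `predictions`
#'   (pooled out-of-fold scores, one per sample), `folds` and
#'   `protocol = "cross-validation"`.
#' @export
cross_validate <- function(X, y, spec = model_spec(), k = 10L, seed = 1L,
                           nested_selection = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n != length(y)) contract_error("X rows must equal length(y)")
  folds <- if (spec$task == "classification") {
    stratified_kfold(y, k = k, seed = seed)
  } else {
    with_seed(seed, {
      f <- rep(seq_len(k), length.out = n)
      sample(f)
    })
  }
  preds <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    tr <- folds != f
    fold_spec <- spec
    if (!is.null(nested_selection)) {
      sel <- do.call(greedy_forward_selection, c(
        list(X = X[tr, , drop = FALSE], y = y[tr], spec = spec),
        nested_selection))
      fold_spec$features <- sel
    }
    fit <- train_model(X[tr, , drop = FALSE], y[tr], fold_spec)
    preds[!tr] <- predict(fit, X[!tr, , drop = FALSE])
  }
  eval_fun <- if (spec$task == "classification") {
    function(idx) evaluate_classification(y[idx], preds[idx], spec$threshold)
  } else {
    function(idx) evaluate_regression(y[idx], preds[idx])
  }
  per_fold <- lapply(seq_len(k), function(f) {
    tryCatch(eval_fun(which(folds == f)), herbsig_contract_error = function(e) NULL)
  })
  list(pooled = eval_fun(seq_len(n)), per_fold = per_fold,
       predictions = preds, folds = folds, protocol = "cross-validation")
}

#' Stepwise forward greedy feature selection
#'
#' Starts from the empty set; at each step adds the feature whose
#' addition maximises the cross-validated metric, stopping when the best
#' improvement is `<= tolerance`.  Ties break towards the lower column
#' index.  Deterministic under the spec's seed.
#'
#' @param X feature matrix with column names.
#' @param y labels or values.
#' @param spec a [model_spec()] (its `features` field is ignored).
#' @param metric `"roc_auc"`, `"accuracy"`, `"mcc"` (classification) or
#'   `"pearson_r"`, `"neg_rmse"` (regression).
#' @param tolerance minimum improvement to continue (default 1e-4).
#' @param k folds for the internal cross-validation (default 5 for
#'   speed).
#' @param max_features optional cap on the subset size.
#' @return character vector of selected feature names, in selection
#'   order.
#' @export
greedy_forward_selection <- function(X, y, spec = model_spec(),
                                     metric = NULL, tolerance = 1e-4,
                                     k = 5L, max_features = Inf) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  if (ncol(X) < 2L) contract_error("need at least 2 features")
  metric <- metric %||% if (spec$task == "classification") "roc_auc"
                        else "pearson_r"
  score_subset <- function(feats) {
    s <- spec; s$features <- feats
    cv <- cross_validate(X, y, s, k = k, seed = spec$seed)
    m <- cv$pooled
    switch(metric,
           roc_auc = m$roc_auc, accuracy = m$accuracy, mcc = m$mcc,
           pearson_r = m$pearson_r, neg_rmse = -m$rmse,
           contract_error(sprintf("unknown metric '%s'", metric)))
  }
  selected <- character(0)
  best_score <- -Inf
  repeat {
    remaining <- setdiff(colnames(X), selected)
    if (length(remaining) == 0L || length(selected) >= max_features) break
    scores <- vapply(remaining, function(f) score_subset(c(selected, f)),
                     numeric(1))
    cand <- which.max(scores)           # ties: first = lowest column index
    if (scores[[cand]] - best_score <= tolerance && length(selected) > 0L) break
    if (length(selected) == 0L || scores[[cand]] > best_score) {
      selected <- c(selected, remaining[[cand]])
      best_score <- scores[[cand]]
    } else {
      break
    }
  }
  selected
}

#' Persist a trained model
#'
#' Writes the model as a versioned binary file with an adjacent
#' plain-text JSON spec (algorithm, hyperparameters, seed, feature
#' configuration and a training-data checksum).
#'
#' @param model a `herbsig_model`.
#' @param path output path (`.rds`); the spec is written to
#'   `<path>.json`.
#' @param checksum optional training-data checksum to record.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, checksum = NULL) {
  saveRDS(model, path)
  meta <- list(
    format_version = 1L,
    package_version = as.character(utils::packageVersion("herbsig")),
    task = model$spec$task,
    algorithm = model$spec$algorithm,
    ntree = model$spec$ntree,
    seed = model$spec$seed,
    threshold = model$spec$threshold,
    features = model$features,
    training_checksum = checksum
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "herbsig_model")) data_error("not a herbsig model file")
  m
}

#' Predict herbicidal and toxicity profiles for molecules
#'
#' Featurizes the records once and applies every model in the registry.
#' Classification endpoints yield a class call and a probability column;
#' regression endpoints yield a value column.  Molecules that cannot be
#' featurized keep their row with empty endpoint fields.
#'
#' @param records molecule record data frame.
#' @param registry named list of entries `list(model=, rule_table=,
#'   cutoffs=, normalise=)` keyed by endpoint name (missing featurization
#'   fields default to the package defaults).
#' @return data frame with `id`, `smiles` and one column group per
#'   endpoint.
#' @export
predict_profile <- function(records, registry = list()) {
  out <- data.frame(id = records$id, smiles = records$smiles,
                    stringsAsFactors = FALSE)
  if (length(registry) == 0L) return(out)
  for (ep in names(registry)) {
    entry <- registry[[ep]]
    feats <- tryCatch(
      featurize_dataset(records,
                        rule_table = entry$rule_table %||% default_rule_table(),
                        cutoffs = entry$cutoffs %||% 1:10,
                        normalise = entry$normalise %||% FALSE),
      herbsig_error = function(e) NULL)
    model <- entry$model
    if (model$spec$task == "classification") {
      cls <- rep(NA_character_, nrow(records))
      prob <- rep(NA_real_, nrow(records))
      if (!is.null(feats)) {
        p <- predict(model, feats)
        hit <- match(rownames(feats), records$id)
        prob[hit] <- p
        cls[hit] <- ifelse(p >= model$spec$threshold, "active", "inactive")
      }
      out[[paste0(ep, "_class")]] <- cls
      out[[paste0(ep, "_prob")]] <- prob
    } else {
      val <- rep(NA_real_, nrow(records))
      if (!is.null(feats)) {
        val[match(rownames(feats), records$id)] <- predict(model, feats)
      }
      out[[paste0(ep, "_value")]] <- val
    }
    failed <- records$id[!records$id %in% rownames(feats %||% matrix(0, 0, 0))]
    if (length(failed) > 0L) {
      hs_log("endpoint %s: %d molecule(s) left empty", ep, length(failed),
             level = "warning")
    }
  }
  out
}
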