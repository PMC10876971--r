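# The boosted cargo-gene classifier: grouped stratified cross-validation,
# random hyperparameter search, per-fold early stopping on held-out average
# precision, refit on the full table at the selected configuration. The
# positive class (ecDNA cargo genes) is ~0.35% of rows in the regime this
# model targets, hence auPRC as the selection metric and a positive-class
# weight in the search space.

#' Stratified grouped k-fold assignment
#'
#' Partitions groups (tumor samples) into k folds so that all rows of a group
#' share a fold and the number of positive groups per fold is as balanced as
#' integer counts allow: positive and negative groups are shuffled separately
#' and dealt round-robin. Deterministic given `seed`.
#'
#' @param groups character vector of unique group ids.
#' @param group_labels 0/1 vector, one per group (1 = group contains a
#'   positive row).
#' @param k number of folds, `2 <= k <= length(groups)`.
#' @param seed integer seed.
#' @return named integer vector: fold (1..k) per group.
#' @export
stratified_group_kfold <- function(groups, group_labels, k, seed = 1L) {
  if (anyDuplicated(groups)) stopf("groups must be unique ids")
  if (length(group_labels) != length(groups))
    stopf("group_labels must match groups")
  if (k < 2) stopf("k must be >= 2")
  if (k > length(groups))
    stopf("k (%d) exceeds the number of groups (%d)", k, length(groups))
  groups <- as.character(groups)
  fold <- integer(length(groups))
  names(fold) <- groups
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (lab in c(1, 0)) {
    idx <- which(group_labels == lab)
    if (!length(idx)) next
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Model configuration
#'
#' Defaults reproduce the training protocol scale: 10-fold grouped CV, 1000
#' random hyperparameter draws, early stopping after 10 rounds without
#' held-out auPRC improvement, at most 500 boosting rounds. Scale `n_search`
#' and `k_folds` down for small cohorts.
#'
#' @param k_folds folds for grouped CV (>= 2).
#' @param n_search random hyperparameter draws.
#' @param patience early-stopping rounds without auPRC improvement.
#' @param max_rounds boosting-round ceiling.
#' @param search_space function(n) returning a data.table of n hyperparameter
#'   draws; `NULL` uses [default_search_space()].
#' @param seed integer seed for folds, search and boosting.
#' @param p_cut gene probability cutoff used downstream.
#' @return list of class `cargo_model_config`.
#' @export
cargo_model_config <- function(k_folds = 10L, n_search = 1000L, patience = 10L,
                               max_rounds = 500L, search_space = NULL,
                               seed = 1L, p_cut = 0.5) {
  if (k_folds < 2) stopf("k_folds must be >= 2")
  structure(list(k_folds = as.integer(k_folds), n_search = as.integer(n_search),
                 patience = as.integer(patience), max_rounds = as.integer(max_rounds),
                 search_space = search_space %||% default_search_space,
                 seed = as.integer(seed), p_cut = p_cut),
            class = "cargo_model_config")
}

#' Default random-search space
#'
#' Learning rate log-uniform on \[0.01, 0.3\]; tree depth 3..8; row and
#' column subsampling on \[0.5, 1\]; minimum child weight in \{1, 5, 10\};
#' positive-class weight in \{1, n_neg/n_pos\} (the imbalance ratio is
#' substituted at training time for the sentinel `-1`).
#'
#' @param n number of draws.
#' @return data.table with one row per draw.
#' @export
default_search_space <- function(n) {
  data.table(
    learning_rate = exp(runif(n, log(0.01), log(0.3))),
    max_depth = sample(3:8, n, replace = TRUE),
    subsample = runif(n, 0.5, 1),
    colsample_bytree = runif(n, 0.5, 1),
    min_child_weight = sample(c(1, 5, 10), n, replace = TRUE),
    scale_pos_weight = sample(c(1, -1), n, replace = TRUE)
  )
}

ap_metric <- function(preds, dtrain) {
  lab <- xgboost::getinfo(dtrain, "label")
  v <- tryCatch(average_precision(lab, preds), error = function(e) 0)
  list(metric = "auprc", value = v)
}

feature_matrix_input <- function(table, feature_names = FEATURE_COLS) {
  miss <- setdiff(feature_names, names(table))
  if (length(miss))
    stopf("feature table lacks column(s): %s", paste(miss, collapse = ", "))
  m <- as.matrix(as.data.table(table)[, feature_names, with = FALSE])
  storage.mode(m) <- "double"
  m
}

xgb_params <- function(row, spw, seed) {
  xgboost::xgb.params(
    objective = "binary:logistic", tree_method = "hist", nthread = 1,
    learning_rate = row$learning_rate, max_depth = row$max_depth,
    subsample = row$subsample, colsample_bytree = row$colsample_bytree,
    min_child_weight = row$min_child_weight,
    scale_pos_weight = if (row$scale_pos_weight == -1) spw else row$scale_pos_weight,
    seed = seed)
}

best_iter_of <- function(fit) {
  es <- attributes(fit)$early_stop
  bi <- es$best_iteration %||% xgboost::xgb.attr(fit, "best_iteration")
  sc <- es$best_score
  if (is.null(bi) || is.na(bi)) bi <- xgboost::xgb.get.num.boosted.rounds(fit)
  list(iter = as.integer(bi), score = as.numeric(sc))
}

#' Train the boosted cargo-gene classifier
#'
#' For each of `n_search` sampled hyperparameter sets, runs grouped
#' stratified k-fold CV with per-fold early stopping (training stops after
#' `patience` rounds without held-out auPRC improvement), selects the
#' configuration with the best mean CV auPRC, and refits on the full table at
#' that configuration for the mean stopped round count. Missing feature
#' values are routed natively by the trees, never imputed.
#'
#' @param table data.table with `sample_id`, `label` (0/1) and the 11 feature
#'   columns ([FEATURE_COLS]).
#' @param config a [cargo_model_config()].
#' @return object of class `cargo_classifier`: the fitted booster, chosen
#'   hyperparameters, full CV history (`config_id`, `fold`, `auprc`,
#'   `best_iter`), out-of-fold probabilities at the chosen configuration
#'   (`oof_prob`, with `row_fold` giving each row's fold), probability
#'   cutoff and feature schema.
#' @export
train_cargo_classifier <- function(table, config = cargo_model_config()) {
  table <- as.data.table(table)
  if (!"label" %in% names(table)) stopf("table lacks a 'label' column")
  if (!"sample_id" %in% names(table)) stopf("table lacks a 'sample_id' column")
  y <- as.numeric(table$label)
  if (all(y == 0) || all(y == 1)) stopf("both classes must be present to train")
  x <- feature_matrix_input(table)

  grp <- table[, .(pos = as.numeric(any(label == 1))), by = sample_id]
  if (nrow(grp) < config$k_folds)
    stopf("fewer groups (%d) than folds (%d)", nrow(grp), config$k_folds)
  fold_of <- stratified_group_kfold(grp$sample_id, grp$pos, config$k_folds,
                                    seed = config$seed)
  row_fold <- fold_of[table$sample_id]

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  draws <- config$search_space(config$n_search)
  spw <- sum(y == 0) / sum(y == 1)

  dmats <- lapply(seq_len(config$k_folds), function(f) {
    tr <- row_fold != f
    list(train = xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr]),
         val = xgboost::xgb.DMatrix(x[!tr, , drop = FALSE], label = y[!tr]))
  })

  history <- vector("list", nrow(draws))
  for (i in seq_len(nrow(draws))) {
    params <- xgb_params(draws[i], spw, config$seed)
    res <- lapply(dmats, function(d) {
      fit <- xgboost::xgb.train(params = params, data = d$train,
                                nrounds = config$max_rounds,
                                evals = list(val = d$val),
                                custom_metric = ap_metric, maximize = TRUE,
                                early_stopping_rounds = config$patience,
                                verbose = 0)
      best_iter_of(fit)
    })
    history[[i]] <- data.table(config_id = i,
                               fold = seq_along(res),
                               auprc = vapply(res, `[[`, 0, "score"),
                               best_iter = vapply(res, `[[`, 0L, "iter"))
  }
  history <- rbindlist(history)
  summary <- history[, .(mean_auprc = mean(auprc),
                         mean_iter = max(1, round(mean(best_iter)))),
                     by = config_id]
  best_id <- summary[order(-mean_auprc, config_id)]$config_id[1]
  best_row <- draws[best_id]
  best_iter <- summary[config_id == best_id]$mean_iter
  # out-of-fold probabilities at the selected configuration, for unbiased
  # downstream evaluation
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(config$k_folds)) {
    fit <- xgboost::xgb.train(params = xgb_params(best_row, spw, config$seed),
                              data = dmats[[f]]$train, nrounds = best_iter,
                              verbose = 0)
    oof[row_fold == f] <- as.numeric(predict(fit, dmats[[f]]$val))
  }
  final <- xgboost::xgb.train(params = xgb_params(best_row, spw, config$seed),
                              data = xgboost::xgb.DMatrix(x, label = y),
                              nrounds = best_iter,
                              verbose = 0)
  structure(list(booster = final,
                 hyperparameters = c(as.list(best_row),
                                     list(scale_pos_weight_value =
                                            if (best_row$scale_pos_weight == -1) spw
                                            else best_row$scale_pos_weight,
                                          nrounds = summary[config_id == best_id]$mean_iter)),
                 cv_history = history, cv_summary = summary,
                 best_config_id = best_id,
                 oof_prob = oof, row_fold = unname(row_fold),
                 feature_names = FEATURE_COLS,
                 p_cut = config$p_cut, seed = config$seed),
            class = "cargo_classifier")
}

#' @export
print.cargo_classifier <- function(x, ...) {
  cat(sprintf("<cargo_classifier> %d-round booster, mean CV auPRC %.3f (config %d of %d), p_cut %.2f\n",
              x$hyperparameters$nrounds,
              x$cv_summary[config_id == x$best_config_id]$mean_auprc,
              x$best_config_id, nrow(x$cv_summary), x$p_cut))
  invisible(x)
}

#' Predict per-gene cargo probabilities
#'
#' @param model a [train_cargo_classifier()] fit or [train_cn_only_baseline()] fit.
#' @param features data.table carrying the model's feature columns; missing
#'   values are allowed (native tree routing for the boosted model, median
#'   imputation for the baseline).
#' @return numeric vector of probabilities in \[0, 1\], one per row.
#' @export
predict_gene_prob <- function(model, features) UseMethod("predict_gene_prob")

#' @export
predict_gene_prob.cargo_classifier <- function(model, features) {
  m <- feature_matrix_input(features, model$feature_names)
  as.numeric(predict(model$booster, xgboost::xgb.DMatrix(m)))
}

#' Copy-number-only logistic baseline
#'
#' Single-feature logistic regression of the label on total copy number
#' (missing values median-imputed), exposing the same prediction interface
#' as the boosted model. Serves as the reference the full model must beat.
#'
#' @param table data.table with `label` and `total_cn`.
#' @return object of class `cn_baseline`.
#' @export
train_cn_only_baseline <- function(table) {
  table <- as.data.table(table)
  if (!all(c("label", "total_cn") %in% names(table)))
    stopf("table needs 'label' and 'total_cn'")
  med <- median(table$total_cn, na.rm = TRUE)
  cn <- fifelse(is.na(table$total_cn), as.numeric(med), as.numeric(table$total_cn))
  if (length(unique(cn)) < 2) stopf("total_cn is constant; baseline is degenerate")
  fit <- glm(label ~ cn, data = data.frame(label = table$label, cn = cn),
             family = binomial())
  structure(list(fit = fit, impute = med), class = "cn_baseline")
}

#' @export
predict_gene_prob.cn_baseline <- function(model, features) {
  cn <- as.numeric(features$total_cn)
  cn[is.na(cn)] <- model$impute
  as.numeric(predict(model$fit, newdata = data.frame(cn = cn), type = "response"))
}

#' Normalized feature importance
#'
#' Gain-based importance of the boosted model, normalized to sum to 1 over
#' all 11 features (features never used by a split get 0).
#'
#' @param model a `cargo_classifier`.
#' @return named numeric vector over [FEATURE_COLS], non-negative, summing
#'   to 1.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "cargo_classifier")) stopf("not a trained cargo_classifier")
  imp <- xgboost::xgb.importance(model = model$booster)
  out <- setNames(numeric(length(model$feature_names)), model$feature_names)
  out[imp$Feature] <- imp$Gain
  if (sum(out) > 0) out <- out / sum(out)
  out
}

#' Sample-level evaluation
#'
#' A sample's score is the maximum cargo probability over its genes; a sample
#' is truly positive iff it has at least one true cargo gene. Reports auPRC,
#' auROC and cutoff metrics at `p_cut`.
#'
#' @param model fitted model accepted by [predict_gene_prob()].
#' @param features feature table with `sample_id` rows.
#' @param truth_labels 0/1 vector aligned with `features` rows (gene-level
#'   truth).
#' @param p_cut decision threshold for the cutoff metrics.
#' @return one-row data.table `auPRC`, `auROC`, `precision`, `sensitivity`,
#'   `specificity`.
#' @export
evaluate_sample_level <- function(model, features, truth_labels, p_cut = 0.5) {
  features <- as.data.table(features)
  dt <- data.table(sample_id = features$sample_id,
                   prob = predict_gene_prob(model, features),
                   label = as.numeric(truth_labels))
  s <- dt[, .(score = max(prob), pos = as.numeric(any(label == 1))),
          by = sample_id]
  tm <- threshold_metrics(s$pos, s$score, p_cut)
  data.table(auPRC = average_precision(s$pos, s$score),
             auROC = auroc(s$pos, s$score),
             precision = tm$precision, sensitivity = tm$sensitivity,
             specificity = tm$specificity)
}

#' Serialize / restore a trained classifier
#'
#' The model is written as a single RDS file bundling the raw booster bytes,
#' hyperparameters, CV history, cutoff and feature schema.
#'
#' @param model a `cargo_classifier`.
#' @param path output path.
#' @return `path` invisibly ([save_classifier()]); the restored
#'   `cargo_classifier` ([load_classifier()]).
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "cargo_classifier"))
  obj <- model
  obj$booster <- xgboost::xgb.save.raw(model$booster)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  obj$booster <- xgboost::xgb.load.raw(obj$booster)
  obj
}
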