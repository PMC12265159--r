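#' Specify a gradient-boosted classification model
#'
#' Fixed hyperparameter set for the boosted-tree classifiers: 5-fold
#' stratified cross-validation, 200 rounds, logistic objective with AUC as
#' the evaluation metric, learning rate 0.05, gamma 1, lambda 3, max depth
#' 10, min child weight 1, subsample 0.8, colsample_bytree 0.8. Age and
#' sex are never features.
#'
#' @param task Label of the classification task:
#'   `"ControlVsIBD"`, `"CDvsUC"` or `"RemissiveVsActive"`.
#' @param representation `"presence_absence"` (species coded 0/1) or
#'   `"relative_abundance"`.
#' @param feature_blocks Subset of `c("species", "species_count",
#'   "human_reads_pct")`.
#' @param n_folds Stratified CV folds (default 5).
#' @param nrounds,eta,gamma,lambda,max_depth,min_child_weight,subsample,colsample_bytree
#'   Boosting hyperparameters (defaults as above).
#' @param seed Integer seed (fold hashing and boosting randomness).
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(task = c("ControlVsIBD", "CDvsUC",
                                     "RemissiveVsActive"),
                            representation = c("presence_absence",
                                               "relative_abundance"),
                            feature_blocks = c("species", "species_count",
                                               "human_reads_pct"),
                            n_folds = 5L, nrounds = 200L, eta = 0.05,
                            gamma = 1, lambda = 3, max_depth = 10L,
                            min_child_weight = 1, subsample = 0.8,
                            colsample_bytree = 0.8, seed = 1L) {
  task <- match.arg(task)
  representation <- match.arg(representation)
  feature_blocks <- match.arg(feature_blocks, several.ok = TRUE)
  banned <- c("age", "Age", "sex", "Sex")
  stopifnot(!any(banned %in% feature_blocks))
  structure(list(task = task, representation = representation,
                 feature_blocks = feature_blocks, n_folds = as.integer(n_folds),
                 nrounds = as.integer(nrounds), eta = eta, gamma = gamma,
                 lambda = lambda, max_depth = as.integer(max_depth),
                 min_child_weight = min_child_weight, subsample = subsample,
                 colsample_bytree = colsample_bytree, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Build the classifier feature matrix
#'
#' Assembles the requested feature blocks from a species table: the species
#' block (presence/absence 0/1 or percent relative abundance), the
#' per-sample species count, and the metagenomic human-read percentage.
#' Age and sex are deliberately not accepted as blocks.
#'
#' @param species Species x samples matrix of percent relative abundances
#'   (or `tax_profile`).
#' @param spec A [classifier_spec()].
#' @param human_reads_pct Optional named per-sample percentage (required
#'   when the block is requested).
#' @return Samples x features numeric matrix.
#' @export
build_feature_matrix <- function(species, spec, human_reads_pct = NULL) {
  if (inherits(species, "tax_profile")) species <- species$matrix
  blocks <- list()
  if ("species" %in% spec$feature_blocks) {
    m <- t(species)
    if (spec$representation == "presence_absence") m <- (m > 0) * 1
    blocks$species <- m
  }
  if ("species_count" %in% spec$feature_blocks)
    blocks$species_count <- matrix(species_count(species),
                                   dimnames = list(colnames(species),
                                                   "species_count"))
  if ("human_reads_pct" %in% spec$feature_blocks) {
    if (is.null(human_reads_pct))
      stop("human_reads_pct block requested but not supplied")
    blocks$human <- matrix(human_reads_pct[colnames(species)],
                           dimnames = list(colnames(species),
                                           "human_reads_pct"))
  }
  do.call(cbind, blocks)
}

# Deterministic string hash (polynomial rolling hash mod a prime kept
# within double precision); used for reproducible, order-invariant fold
# assignment.
.hash_id <- function(ids, seed = 0L) {
  vapply(ids, function(s) {
    h <- (seed %% 1000003) + 7
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 1000000007
    h
  }, numeric(1))
}

# Stratified fold assignment by hash of sample id: within each class,
# samples are ordered by hash and dealt round-robin. Invariant to the
# order of the input rows.
.hash_folds <- function(ids, labels, n_folds, seed) {
  fold <- integer(length(ids))
  h <- .hash_id(ids, seed)
  for (cl in unique(labels)) {
    i <- which(labels == cl)
    fold[i[order(h[i], ids[i])]] <- rep_len(seq_len(n_folds), length(i))
  }
  fold
}

.xgb_params <- function(spec) {
  list(objective = "binary:logistic", eval_metric = "auc",
       eta = spec$eta, gamma = spec$gamma, lambda = spec$lambda,
       max_depth = spec$max_depth, min_child_weight = spec$min_child_weight,
       subsample = spec$subsample, colsample_bytree = spec$colsample_bytree,
       nthread = 1L, seed = spec$seed)
}

#' Train a cross-validated boosted-tree classifier
#'
#' Stratified k-fold cross-validation with fold assignment by a
#' deterministic hash of the sample identifiers, so the fold structure is
#' reproducible and invariant to row order. Each fold's model is trained
#' for the full round budget with the held-out fold as evaluation set.
#' Out-of-fold predictions (each sample predicted exactly once, by the
#' model that did not see it, after the full round budget) are pooled into
#' the reported CV AUC. The best round — the round maximizing the mean
#' held-out AUC across folds — is used only to refit a final model on all
#' samples for external validation and feature importance; scoring the
#' pooled predictions at that selected round would bias the AUC upward.
#'
#' @param features Samples x features numeric matrix with rownames.
#' @param labels Factor or character with exactly 2 levels; the second
#'   level (alphabetically last if character) is the positive class.
#' @param spec A [classifier_spec()].
#' @return A `cv_classifier`: list with `oof` (data frame sample_id,
#'   label, fold, pred), `auc`, `roc` (data frame of ROC points),
#'   `best_round`, `model` (final booster), `feature_names`, `spec`.
#' @export
train_cv_classifier <- function(features, labels, spec = classifier_spec()) {
  stopifnot(is.matrix(features), !is.null(rownames(features)))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    stop("need exactly 2 classes, got ", nlevels(labels))
  y <- as.integer(labels) - 1L
  ids <- rownames(features)
  fold <- .hash_folds(ids, y, spec$n_folds, spec$seed)
  if (any(tabulate(fold, spec$n_folds) == 0) ||
      any(vapply(seq_len(spec$n_folds), function(f)
        length(unique(y[fold == f])) < 2L, logical(1))))
    stop("stratification error: a fold is empty or missing a class")

  params <- .xgb_params(spec)
  fold_models <- vector("list", spec$n_folds)
  eval_auc <- matrix(NA_real_, spec$nrounds, spec$n_folds)
  for (f in seq_len(spec$n_folds)) {
    tr <- fold != f
    dtrain <- xgboost::xgb.DMatrix(features[tr, , drop = FALSE],
                                   label = y[tr], nthread = 1L)
    dtest <- xgboost::xgb.DMatrix(features[!tr, , drop = FALSE],
                                  label = y[!tr], nthread = 1L)
    bst <- xgboost::xgb.train(params, dtrain, nrounds = spec$nrounds,
                              evals = list(test = dtest), verbose = 0)
    log <- attributes(bst)$evaluation_log
    eval_auc[, f] <- log$test_auc
    fold_models[[f]] <- bst
  }
  best_round <- which.max(rowMeans(eval_auc))

  # out-of-fold predictions come from the full-round CV run; the best
  # round is used only for the final refit below. Selecting the round by
  # held-out AUC and then reporting AUC at that same round would leak the
  # selection into the estimate (visible as >0.5 AUC on label-permuted
  # data).
  pred <- numeric(length(y))
  for (f in seq_len(spec$n_folds)) {
    te <- fold == f
    d <- xgboost::xgb.DMatrix(features[te, , drop = FALSE], nthread = 1L)
    pred[te] <- predict(fold_models[[f]], d)
  }
  roc_obj <- pROC::roc(response = y, predictor = pred, quiet = TRUE,
                       levels = c(0, 1), direction = "<")
  auc <- as.numeric(pROC::auc(roc_obj))

  dall <- xgboost::xgb.DMatrix(features, label = y, nthread = 1L)
  final <- xgboost::xgb.train(params, dall, nrounds = best_round, verbose = 0)

  structure(list(
    oof = data.frame(sample_id = ids, label = as.character(labels),
                     fold = fold, pred = pred, stringsAsFactors = FALSE),
    auc = auc,
    roc = data.frame(threshold = roc_obj$thresholds,
                     sensitivity = roc_obj$sensitivities,
                     specificity = roc_obj$specificities),
    mean_cv_auc_by_round = rowMeans(eval_auc),
    best_round = best_round,
    model = final, feature_names = colnames(features),
    positive_class = levels(labels)[2L], spec = spec
  ), class = "cv_classifier")
}

#' @export
print.cv_classifier <- function(x, ...) {
  cat(sprintf("CV classifier [%s, %s]: AUC = %.3f at best round %d\n",
              x$spec$task, x$spec$representation, x$auc, x$best_round))
  invisible(x)
}

#' Validate a trained classifier on an external cohort
#'
#' Feature spaces are reconciled by name: features absent from the
#' validation table are imputed as 0 (absent species), extra features are
#' dropped. A feature overlap below 50 percent raises a hard warning but
#' the validation still runs.
#'
#' @param fit A `cv_classifier`.
#' @param features Samples x features matrix of the external cohort.
#' @param labels Two-level labels; the positive class must match training.
#' @return List with `auc`, `roc`, `pred` (data frame), and
#'   `reconciliation` (`n_shared`, `n_imputed`, `n_dropped`).
#' @export
external_validate <- function(fit, features, labels) {
  stopifnot(inherits(fit, "cv_classifier"), is.matrix(features))
  labels <- as.factor(labels)
  train_feats <- fit$feature_names
  shared <- intersect(train_feats, colnames(features))
  imputed <- setdiff(train_feats, colnames(features))
  dropped <- setdiff(colnames(features), train_feats)
  if (length(shared) < 0.5 * length(train_feats))
    warning("feature overlap below 50% (", length(shared), "/",
            length(train_feats), "); validation may be unreliable")
  x <- matrix(0, nrow(features), length(train_feats),
              dimnames = list(rownames(features), train_feats))
  x[, shared] <- features[, shared]
  y <- as.integer(labels) - 1L
  d <- xgboost::xgb.DMatrix(x, nthread = 1L)
  pred <- predict(fit$model, d)
  roc_obj <- pROC::roc(response = y, predictor = pred, quiet = TRUE,
                       levels = c(0, 1), direction = "<")
  list(auc = as.numeric(pROC::auc(roc_obj)),
       roc = data.frame(threshold = roc_obj$thresholds,
                        sensitivity = roc_obj$sensitivities,
                        specificity = roc_obj$specificities),
       pred = data.frame(sample_id = rownames(features),
                         label = as.character(labels), pred = pred,
                         stringsAsFactors = FALSE),
       reconciliation = list(n_shared = length(shared),
                             n_imputed = length(imputed),
                             n_dropped = length(dropped)))
}

#' Feature importance and per-sample Shapley values
#'
#' Gain / Cover / Frequency importance from the final refit model, sorted
#' by Gain, plus per-sample Shapley values on the log-odds scale. The
#' Shapley values of a sample, plus the base value, sum to that sample's
#' margin (log-odds) prediction.
#'
#' @param fit A `cv_classifier`.
#' @param features Samples x features matrix to explain (typically the
#'   training matrix).
#' @return List with `importance` (data frame Feature, Gain, Cover,
#'   Frequency), `shap` (samples x features matrix), `base_value`.
#' @export
feature_importance <- function(fit, features) {
  stopifnot(inherits(fit, "cv_classifier"), is.matrix(features))
  imp <- xgboost::xgb.importance(model = fit$model)
  imp <- as.data.frame(imp)
  d <- xgboost::xgb.DMatrix(features[, fit$feature_names, drop = FALSE],
                            nthread = 1L)
  contrib <- predict(fit$model, d, predcontrib = TRUE)
  base_col <- ncol(contrib)
  list(importance = imp,
       shap = contrib[, -base_col, drop = FALSE],
       base_value = contrib[1L, base_col])
}
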