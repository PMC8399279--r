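## model_eval: the seven classifier families, the 80:20 + stratified 5-fold
## evaluation protocol, and the threshold-dependent/independent metrics.

MODEL_NAMES <- c("rf", "dt", "lr", "knn", "gnb", "xgb", "svc")

#' Stratified 80:20 train/validation split
#'
#' Per class, `floor(train_fraction * n)` peptides go to training (a
#' deterministic rounding rule); the split is an exact partition and is a
#' pure function of the seed. With 269 positives and 2,690 negatives at
#' 0.8 this gives 215 + 2,152 training peptides.
#'
#' @param records a peptide set data.frame with a label column, or a
#'   `b3pp_dataset`.
#' @param train_fraction fraction per class assigned to training.
#' @param seed integer seed.
#' @return list(train, validation) of peptide set data.frames.
#' @export
stratified_split <- function(records, train_fraction = 0.8, seed = 1) {
  if (inherits(records, "b3pp_dataset")) records <- dataset_records(records)
  y <- as_binary_labels(records$label)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (min(table(y)) < 5) stop("each class needs >= 5 members")
  idx_train <- integer(0)
  for (cl in c(0, 1)) {
    ix <- which(y == cl)
    n_tr <- floor(train_fraction * length(ix))
    idx_train <- c(idx_train, with_seed(seed + cl, sample(ix, n_tr)))
  }
  idx_train <- sort(idx_train)
  list(train = records[idx_train, , drop = FALSE],
       validation = records[-idx_train, , drop = FALSE])
}

## Stratified fold ids (1..k) as a pure function of (seed, labels).
fold_ids <- function(y, k = 5, seed = 1) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    ix <- which(y == cl)
    perm <- with_seed(seed + 1000L * match(cl, unique(y)), sample(ix))
    f[perm] <- rep_len(seq_len(k), length(ix))
  }
  f
}

#' Train one classifier family
#'
#' Supported families: `rf` (random forest, 500 trees, sqrt(p) features
#' per split), `dt` (CART decision tree), `lr` (ridge logistic
#' regression, lambda = 1/n), `knn` (k = 5 nearest neighbours), `gnb`
#' (Gaussian naive Bayes), `xgb` (gradient boosting, 300 rounds, depth 6,
#' eta 0.1) and `svc` (RBF support-vector classifier with Platt-scaled
#' probabilities). Features are z-scored with training statistics stored
#' in the model; every family scores peptides on the positive-class
#' probability scale in [0, 1]. With an empty feature set the model
#' degenerates to a constant 0.5 score.
#'
#' @param x numeric matrix (peptides x features).
#' @param y binary labels (0/1 or "positive"/"negative").
#' @param model one of `r toString(MODEL_NAMES)`.
#' @param seed integer seed (stochastic learners).
#' @return object of class `b3pp_model`.
#' @export
train_classifier <- function(x, y, model = "rf", seed = 1) {
  model <- match.arg(model, MODEL_NAMES)
  y <- as_binary_labels(y)
  x <- as.matrix(x)
  if (ncol(x) == 0) {
    return(structure(list(model_name = "constant", center = numeric(),
                          scale = numeric(), features = character()),
                     class = "b3pp_model"))
  }
  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- scale(x, center, scl)
  yf <- factor(y, levels = c(0, 1))
  fit <- with_seed(seed, switch(model,
    rf = randomForest::randomForest(xs, yf, ntree = 500),
    dt = rpart::rpart(y ~ ., data = data.frame(y = yf, xs),
                      method = "class"),
    lr = glmnet::glmnet(pad2(xs), yf, family = "binomial", alpha = 0,
                        lambda = 1 / nrow(xs)),
    knn = list(train = xs, cl = yf, k = 5),
    gnb = e1071::naiveBayes(xs, yf),
    xgb = xgboost::xgb.train(
      params = xgboost::xgb.params(objective = "binary:logistic",
                                   max_depth = 6, learning_rate = 0.1,
                                   nthread = 1),
      data = xgboost::xgb.DMatrix(xs, label = y, nthread = 1),
      nrounds = 300, verbose = 0),
    svc = e1071::svm(xs, yf, kernel = "radial", probability = TRUE)
  ))
  structure(list(model_name = model, fit = fit, center = center,
                 scale = scl, features = colnames(x), seed = seed),
            class = "b3pp_model")
}

## glmnet needs >= 2 columns; pad with an all-zero column when necessary.
pad2 <- function(x) {
  if (ncol(x) >= 2) x else cbind(x, .pad = 0)
}

#' Positive-class scores from a fitted classifier
#'
#' @param object a `b3pp_model`.
#' @param x numeric matrix with the model's feature columns.
#' @param ... unused.
#' @return numeric vector of scores in [0, 1].
#' @export
predict.b3pp_model <- function(object, x, ...) {
  if (object$model_name == "constant") {
    return(rep(0.5, nrow(as.matrix(x))))
  }
  x <- as.matrix(x)[, object$features, drop = FALSE]
  xs <- scale(x, object$center, object$scale)
  fit <- object$fit
  sc <- switch(object$model_name,
    rf = stats::predict(fit, xs, type = "prob")[, "1"],
    dt = stats::predict(fit, data.frame(xs), type = "prob")[, "1"],
    lr = as.numeric(stats::predict(fit, pad2(xs), type = "response")),
    knn = {
      pr <- class::knn(fit$train, xs, fit$cl, k = fit$k, prob = TRUE)
      votes <- attr(pr, "prob")
      ifelse(pr == "1", votes, 1 - votes)
    },
    gnb = stats::predict(fit, xs, type = "raw")[, "1"],
    xgb = stats::predict(fit, xs),
    svc = {
      pr <- stats::predict(fit, xs, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    })
  as.numeric(pmin(pmax(sc, 0), 1))
}

#' Confusion-matrix metrics
#'
#' Sens = TP/(TP+FN) x 100, Spec = TN/(TN+FP) x 100,
#' Acc = (TP+TN)/total x 100 and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), with
#' MCC defined as 0 when any denominator factor vanishes. Sens and Spec
#' are likewise 0 when their denominators vanish (degenerate input).
#'
#' @param tp,fp,tn,fn non-negative confusion counts (or pass a single
#'   named list/vector as `tp`).
#' @return named vector (Sens, Spec, Acc, MCC).
#' @export
compute_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.null(fp)) {
    counts <- tp
    tp <- counts[["TP"]]; fp <- counts[["FP"]]
    tn <- counts[["TN"]]; fn <- counts[["FN"]]
  }
  total <- tp + fp + tn + fn
  if (total == 0) stop("compute_metrics: no evaluated peptides")
  div0 <- function(num, den) if (den > 0) num / den else 0
  sens <- div0(tp, tp + fn) * 100
  spec <- div0(tn, tn + fp) * 100
  acc <- (tp + tn) / total * 100
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den) else 0
  c(Sens = sens, Spec = spec, Acc = acc, MCC = mcc)
}

#' Area under the ROC curve
#'
#' Computed via the Mann-Whitney rank-sum equivalence (midranks give half
#' credit to tied scores), which equals the trapezoidal area under the
#' ROC curve. Perfect ranking gives 1, reversed ranking 0, all-tied
#' scores 0.5.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels binary labels; both classes must be present.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("auroc: both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

score_metrics <- function(scores, y, threshold) {
  pred <- as.integer(scores >= threshold)
  m <- compute_metrics(tp = sum(pred == 1 & y == 1),
                       fp = sum(pred == 1 & y == 0),
                       tn = sum(pred == 0 & y == 0),
                       fn = sum(pred == 0 & y == 1))
  c(m, AUROC = auroc(scores, y))
}

#' Stratified 5-fold cross-validation of one classifier
#'
#' Each fold is used exactly once for testing; fold sizes differ by at
#' most one per class; the mean row is the arithmetic average of the
#' per-fold metrics.
#'
#' @param x numeric matrix (training split).
#' @param y binary labels.
#' @param model classifier family (see [train_classifier()]).
#' @param seed integer seed (controls fold assignment and learners).
#' @param threshold score threshold for Sens/Spec/Acc/MCC.
#' @param k number of folds.
#' @return list(per_fold data.frame, mean_internal named vector).
#' @export
five_fold_cv <- function(x, y, model = "rf", seed = 1, threshold = 0.5,
                         k = 5) {
  y <- as_binary_labels(y)
  if (min(table(y)) < k) stop("need >= ", k, " members per class")
  f <- fold_ids(y, k, seed)
  per_fold <- t(vapply(seq_len(k), function(fold) {
    tr <- f != fold
    m <- train_classifier(x[tr, , drop = FALSE], y[tr], model,
                          seed = seed + fold)
    score_metrics(predict(m, x[!tr, , drop = FALSE]), y[!tr], threshold)
  }, numeric(5)))
  per_fold <- data.frame(fold = seq_len(k), per_fold)
  list(per_fold = per_fold,
       mean_internal = colMeans(per_fold[, -1]))
}

#' Evaluate a classifier under the 80:20 + 5-fold protocol
#'
#' Splits the rows 80:20 stratified by class, runs stratified 5-fold
#' cross-validation on the training split (internal validation), refits
#' on the full training split and scores the held-out 20\% (external
#' validation).
#'
#' @param features a `b3pp_features` object or numeric matrix.
#' @param labels binary labels (one per row).
#' @param subset character vector of feature columns to use (NULL = all);
#'   an empty subset degenerates to a constant 0.5 scorer.
#' @param model classifier family.
#' @param seed integer seed.
#' @param threshold score threshold (default 0.5).
#' @param train_fraction training fraction (default 0.8).
#' @return object of class `b3pp_eval_report`: list(per_fold,
#'   mean_internal, external, threshold, model_name, model, split).
#' @export
evaluate_pipeline <- function(features, labels, subset = NULL, model = "rf",
                              seed = 1, threshold = 0.5,
                              train_fraction = 0.8) {
  x <- feature_values(features)
  y <- as_binary_labels(labels)
  if (!is.null(subset)) {
    stopifnot(all(subset %in% colnames(x)))
    x <- x[, subset, drop = FALSE]
  }
  recs <- data.frame(id = seq_len(nrow(x)),
                     label = ifelse(y == 1, "positive", "negative"))
  sp <- stratified_split(recs, train_fraction, seed)
  itr <- sp$train$id
  iva <- sp$validation$id
  cv <- five_fold_cv(x[itr, , drop = FALSE], y[itr], model, seed, threshold)
  final <- train_classifier(x[itr, , drop = FALSE], y[itr], model, seed)
  external <- score_metrics(predict(final, x[iva, , drop = FALSE]),
                            y[iva], threshold)
  structure(list(per_fold = cv$per_fold, mean_internal = cv$mean_internal,
                 external = external, threshold = threshold,
                 model_name = model, model = final,
                 split = list(train = itr, validation = iva)),
            class = "b3pp_eval_report")
}

#' @export
print.b3pp_eval_report <- function(x, ...) {
  cat("b3pp_eval_report (", x$model_name, ", threshold ", x$threshold,
      ")\n", sep = "")
  cat("internal (5-fold mean): ",
      paste(names(x$mean_internal),
            sprintf("%.2f", x$mean_internal), collapse = "  "), "\n")
  cat("external (held-out 20%):",
      paste(names(x$external),
            sprintf("%.2f", x$external), collapse = "  "), "\n")
  invisible(x)
}

#' Run the full B3PP pipeline on a labelled dataset
#'
#' Featurizes the peptides (all 9,189 descriptors), splits 80:20,
#' performs SVC-L1 selection and gradient-boosted split-count ranking on
#' the training split only (leakage-safe default), truncates to the top-k
#' features, evaluates the chosen classifier under 5-fold CV plus
#' external validation, and packages a sequence-level prediction bundle.
#'
#' @param dataset a `b3pp_dataset` (see [assemble_dataset()] /
#'   [generate_dataset()]).
#' @param C SVC-L1 regularization strength (default 0.01).
#' @param top_k number of ranked features to keep (default 80; saturates
#'   at the number selected).
#' @param model classifier family (default "rf").
#' @param seed integer seed controlling split, selection, ranking and
#'   training.
#' @param threshold score threshold (default 0.5).
#' @param config a [feature_config()].
#' @param select_on "train" (default, selection on the 80\% split) or
#'   "all".
#' @return list(report = `b3pp_eval_report`, bundle = `b3pp_bundle`,
#'   selection = `b3pp_selection`, features = `b3pp_features`).
#' @export
b3pp_pipeline <- function(dataset, C = 0.01, top_k = 80, model = "rf",
                          seed = 1, threshold = 0.5,
                          config = feature_config(),
                          select_on = c("train", "all")) {
  select_on <- match.arg(select_on)
  records <- dataset_records(dataset)
  feats <- featurize_all(records, config)
  y <- as_binary_labels(records$label)
  recs <- data.frame(id = seq_len(nrow(records)), label = records$label)
  sp <- stratified_split(recs, 0.8, seed)
  itr <- sp$train$id
  sel_rows <- if (select_on == "train") itr else seq_len(nrow(records))
  sel <- svc_l1_select(feats$values[sel_rows, , drop = FALSE], y[sel_rows],
                       C = C, seed = seed)
  subset <- character(0)
  if (length(sel$selected) > 0) {
    sel <- gbm_rank(feats$values[sel_rows, , drop = FALSE], y[sel_rows],
                    sel, seed = seed)
    subset <- top_k(sel, top_k)
  }
  report <- evaluate_pipeline(feats, y, subset = subset, model = model,
                              seed = seed, threshold = threshold)
  bundle <- structure(list(model = report$model, features = subset,
                           feature_config = config, threshold = threshold,
                           seed = seed, model_name = model,
                           manifest_version = MANIFEST_VERSION),
                      class = "b3pp_bundle")
  list(report = report, bundle = bundle, selection = sel, features = feats)
}

#' @export
print.b3pp_bundle <- function(x, ...) {
  cat("b3pp_bundle: ", x$model_name, " on ", length(x$features),
      " features, threshold ", x$threshold, " (manifest v",
      x$manifest_version, ")\n", sep = "")
  invisible(x)
}

#' Save / load a prediction bundle
#'
#' @param bundle a `b3pp_bundle`.
#' @param path file path.
#' @return `bundle_save` the path invisibly; `bundle_load` the bundle.
#' @export
bundle_save <- function(bundle, path) {
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname bundle_save
#' @export
bundle_load <- function(path) {
  bundle <- readRDS(path)
  stopifnot(inherits(bundle, "b3pp_bundle"))
  if (!identical(bundle$manifest_version, MANIFEST_VERSION)) {
    stop("bundle manifest version ", bundle$manifest_version,
         " does not match installed manifest ", MANIFEST_VERSION)
  }
  bundle
}
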