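## Tabular module classifiers -------------------------------------------------
##
## Four of the five cascade modules operate on encoded DICOM-tag features:
## Others (initial relevance filter), Weighting (T1W/T2W/DWI), Fat
## Suppression (FS/nFS), and Family (SE/GR/IR/EP). Two tree-ensemble
## backends are supported with fixed hyperparameters: a random forest
## (depth 9, log2 feature rule, no pruning) and gradient-boosted trees
## (logloss objective, depth 6, L2 regularisation 3, 64 histogram borders).

MODULE_CLASSES <- list(
  Others = c("other", "relevant"),
  Weighting = c("DWI", "T1W", "T2W"),
  FatSuppression = c("FS", "nFS"),
  Family = c("SE", "GR", "IR", "EP"))

#' Backend configuration for the tabular modules
#'
#' @param backend `"gbt"` (gradient-boosted trees, the default) or `"rf"`
#'   (random forest). Long names `"gradient-boosted-trees"` and
#'   `"random-forest"` are accepted.
#' @param class_weighting Weight classes inversely to their frequency.
#' @param seed Integer seed (both backends are single-threaded and
#'   deterministic given the seed).
#' @param n_trees Random-forest tree count.
#' @param nrounds Boosting iterations.
#' @param learning_rate Boosting learning rate.
#' @return An object of class `backend_config`. Fixed hyperparameters:
#'   random forest uses max depth 9 and floor(log2(p)) features per split
#'   with no pruning; boosting uses logarithmic loss, depth 6, L2
#'   regularisation 3, and 64 histogram border counts.
#' @export
backend_config <- function(backend = c("gbt", "rf",
                                       "gradient-boosted-trees",
                                       "random-forest"),
                           class_weighting = TRUE, seed = 1L,
                           n_trees = 500L, nrounds = 500L,
                           learning_rate = 0.1) {
  backend <- match.arg(backend)
  backend <- if (backend %in% c("rf", "random-forest")) "rf" else "gbt"
  structure(list(backend = backend,
                 class_weighting = isTRUE(class_weighting),
                 seed = as.integer(seed), n_trees = as.integer(n_trees),
                 nrounds = as.integer(nrounds),
                 learning_rate = learning_rate,
                 rf = list(max_depth = 9L, mtry_rule = "log2",
                           pruning = 0),
                 gbt = list(objective = "logloss", depth = 6L, l2 = 3,
                            border_count = 64L, scheme = "plain")),
            class = "backend_config")
}

module_truth <- function(records, module) {
  switch(module,
    Others = vapply(records, function(r)
      if (r$truth$is_other) "other" else "relevant", ""),
    Weighting = vapply(records, function(r) r$truth$weighting, ""),
    FatSuppression = vapply(records, function(r) r$truth$fat_suppressed, ""),
    Family = vapply(records, function(r) r$truth$family, ""),
    stop("unknown module: ", module))
}

## Which series a module is trained and evaluated on (ground-truth routing).
module_population <- function(records, module) {
  switch(module,
    Others = rep(TRUE, length(records)),
    Weighting = vapply(records, function(r) !r$truth$is_other, logical(1)),
    FatSuppression = vapply(records, function(r)
      !r$truth$is_other && r$truth$weighting %in% c("T1W", "T2W"),
      logical(1)),
    Family = vapply(records, function(r) !r$truth$is_other, logical(1)),
    stop("unknown module: ", module))
}

#' Train one tabular cascade module
#'
#' @param x Encoded feature matrix (training rows of the module's
#'   population).
#' @param y Labels restricted to the module's class list; every class must
#'   be present.
#' @param module Module name: `"Others"`, `"Weighting"`,
#'   `"FatSuppression"`, or `"Family"`.
#' @param subset A [select_features()] subset fitted on these rows.
#' @param config A [backend_config()].
#' @return An object of class `trained_module`.
#' @export
train_module <- function(x, y, module, subset, config = backend_config()) {
  classes <- MODULE_CLASSES[[module]]
  if (is.null(classes)) stop("unknown module: ", module, call. = FALSE)
  y <- as.character(y)
  bad <- setdiff(unique(y), classes)
  if (length(bad))
    stop("labels outside the ", module, " class list: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!all(classes %in% y))
    stop("module ", module, " is undefined: class(es) absent from training ",
         "labels: ", paste(setdiff(classes, y), collapse = ", "),
         call. = FALSE)
  feats <- subset$selected
  missing_cols <- setdiff(feats, colnames(x))
  if (length(missing_cols))
    stop("feature matrix lacks selected columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  xs <- x[, feats, drop = FALSE]
  yf <- factor(y, levels = classes)
  freq <- table(yf)
  cw <- as.numeric(length(yf) / (nlevels(yf) * freq))
  names(cw) <- levels(yf)

  if (config$backend == "rf") {
    dat <- as.data.frame(xs)
    colnames(dat) <- make.names(colnames(dat), unique = TRUE)
    fit <- ranger::ranger(
      x = dat, y = yf, probability = TRUE,
      num.trees = config$n_trees,
      mtry = max(1L, floor(log2(ncol(dat)))),
      max.depth = config$rf$max_depth,
      class.weights = if (config$class_weighting) cw else NULL,
      seed = config$seed, num.threads = 1L, verbose = FALSE)
  } else {
    w <- if (config$class_weighting) cw[as.character(yf)] else
      rep(1, length(yf))
    nc <- length(classes)
    params <- list(
      max_depth = config$gbt$depth, lambda = config$gbt$l2,
      max_bin = config$gbt$border_count, tree_method = "hist",
      eta = config$learning_rate, nthread = 1L, seed = config$seed,
      verbosity = 0)
    if (nc == 2) {
      params$objective <- "binary:logistic"
      label <- as.integer(yf) - 1L  # class 2 of the list is the positive
    } else {
      params$objective <- "multi:softprob"
      params$num_class <- nc
      label <- as.integer(yf) - 1L
    }
    dtrain <- xgboost::xgb.DMatrix(xs, label = label, weight = as.numeric(w))
    fit <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = config$nrounds, verbose = 0)
  }
  structure(list(module = module, classes = classes, backend = config$backend,
                 fit = fit, subset = subset, config = config,
                 population = module, feature_names = feats),
            class = "trained_module")
}

## Batch class-probability matrix (rows x classes); S3 so that tests can
## drive the router with stub modules.
#' Class-probability matrix for a batch of encoded rows
#' @param model A trained module (or a test stub).
#' @param x Encoded feature matrix.
#' @param ... Unused.
#' @return Numeric matrix, one row per input row, columns = class list.
#' @export
module_probs <- function(model, x, ...) UseMethod("module_probs")

#' @export
module_probs.trained_module <- function(model, x, ...) {
  missing_cols <- setdiff(model$feature_names, colnames(x))
  if (length(missing_cols))
    stop("encoded rows lack model columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  xs <- x[, model$feature_names, drop = FALSE]
  if (model$backend == "rf") {
    dat <- as.data.frame(xs)
    colnames(dat) <- make.names(colnames(dat), unique = TRUE)
    p <- stats::predict(model$fit, data = dat, num.threads = 1L,
                        verbose = FALSE)$predictions
    p <- p[, model$classes, drop = FALSE]
  } else {
    pr <- stats::predict(model$fit, xgboost::xgb.DMatrix(xs))
    if (length(model$classes) == 2) {
      p <- cbind(1 - pr, pr)
    } else if (is.matrix(pr)) {
      p <- pr
    } else {
      p <- matrix(pr, ncol = length(model$classes), byrow = TRUE)
    }
    colnames(p) <- model$classes
  }
  p <- p / rowSums(p)
  rownames(p) <- rownames(xs)
  p
}

decide_class <- function(prob) {
  cand <- names(prob)[prob >= max(prob) - 1e-12]
  sort(cand)[1]  # deterministic lexicographic tie-break
}

#' Predict one series with a trained module
#'
#' @param model A `trained_module`.
#' @param row Encoded feature row (1-row matrix) from [encode_features()]
#'   using the encoder the model was trained with.
#' @return A `module_decision`: module name, predicted class (argmax with
#'   lexicographic tie-break), and the normalized class-probability vector.
#' @export
predict_module <- function(model, row) {
  if (is.null(dim(row))) row <- matrix(row, nrow = 1,
                                       dimnames = list(NULL, names(row)))
  p <- module_probs(model, row)[1, ]
  structure(list(module = model$module, class = decide_class(p),
                 probabilities = p), class = "module_decision")
}

#' @export
print.module_decision <- function(x, ...) {
  cat("<module_decision>", x$module, "->", x$class, "(",
      paste(sprintf("%s=%.3f", names(x$probabilities), x$probabilities),
            collapse = " "), ")\n")
  invisible(x)
}

#' Patient-grouped cross-validation of one module
#'
#' Folds are patient-disjoint; within each fold the encoder and the
#' module's feature selection are re-fitted on that fold's training rows
#' only. Returns per-fold validation metrics and their mean and SD.
#'
#' @param records Cohort records carrying `patient_id` and ground truth.
#' @param module Module name.
#' @param k Number of folds.
#' @param config A [backend_config()].
#' @param seed Fold-assignment seed.
#' @param schema,lexicon Encoding configuration.
#' @return List with `folds` (per-fold metric data frame) and `summary`
#'   (mean and SD per metric).
#' @export
cv_train <- function(records, module, k = 5, config = backend_config(),
                     seed = 1L, schema = default_tag_schema(),
                     lexicon = load_lexicon()) {
  patients <- vapply(records, `[[`, "", "patient_id")
  if (length(unique(patients)) < k)
    stop("fewer patients (", length(unique(patients)),
         ") than folds (", k, ")", call. = FALSE)
  fold_of <- cv_folds(records, k = k, seed = seed)
  pop <- module_population(records, module)
  y_all <- module_truth(records, module)
  rows_all <- rows_from_records(records, schema)
  out <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold_of != f & pop)
    va <- which(fold_of == f & pop)
    enc <- fit_encoder(rows_all[tr, , drop = FALSE], schema, lexicon)
    xtr <- encode_features(enc, rows_all[tr, , drop = FALSE])
    xva <- encode_features(enc, rows_all[va, , drop = FALSE])
    sub <- select_features(xtr, y_all[tr])
    mod <- train_module(xtr, y_all[tr], module, sub, config)
    p <- module_probs(mod, xva)
    pred <- apply(p, 1, function(pr) decide_class(stats::setNames(pr, colnames(p))))
    out[[f]] <- cbind(fold = f,
                      module_metrics(y_all[va], pred, p, mod$classes))
  }
  folds <- do.call(rbind, out)
  metrics <- setdiff(colnames(folds), "fold")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(folds[[m]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL)
  list(folds = folds, summary = summary)
}

## Per-module validation metrics: accuracy, macro AUC (one-vs-rest),
## macro F1/precision/sensitivity.
module_metrics <- function(y_true, y_pred, probs, classes) {
  cm <- confusion(y_true, y_pred, classes = classes)
  rep_ <- metrics_from_confusion(cm)
  aucs <- vapply(classes, function(cl) {
    truth_bin <- as.integer(y_true == cl)
    if (length(unique(truth_bin)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(truth_bin, probs[, cl], quiet = TRUE,
                                   direction = "<")))
  }, numeric(1))
  data.frame(accuracy = rep_$accuracy, auc = mean(aucs, na.rm = TRUE),
             f1 = rep_$macro["f1"], precision = rep_$macro["precision"],
             sensitivity = rep_$macro["sensitivity"], row.names = NULL)
}
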