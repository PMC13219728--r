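## End-to-end pipeline training -----------------------------------------------

#' Train the full classifier cascade on a training cohort
#'
#' Fits the feature encoder on the training rows, then trains each tabular
#' module on its ground-truth-routed population (modules are trained on
#' clean reference routing, not on upstream predictions) with per-module
#' association-based feature selection, and finally trains the image-based
#' contrast classifier on the central slices of the training T1W series.
#'
#' @param records Training `series_record` list (use [patient_split()]
#'   first; never train and evaluate on the same patients).
#' @param config A [backend_config()] for the tabular modules.
#' @param image_config An [image_train_config()] for the contrast branch.
#' @param train_contrast_model Set `FALSE` to skip the image branch (the
#'   resulting bundle routes T1W contrast to "undetermined" unless the
#'   cohort has no pixel data at all).
#' @param schema Tag schema.
#' @param lexicon Preliminary-classifier lexicon.
#' @param alpha Feature-selection significance level.
#' @return An object of class `mrseries_bundle`.
#' @export
train_pipeline <- function(records, config = backend_config(),
                           image_config = image_train_config(),
                           train_contrast_model = TRUE,
                           schema = default_tag_schema(),
                           lexicon = load_lexicon(), alpha = 0.01) {
  rows <- rows_from_records(records, schema)
  encoder <- fit_encoder(rows, schema, lexicon)
  x <- encode_features(encoder, rows)
  modules <- list()
  for (m in names(MODULE_CLASSES)) {
    pop <- module_population(records, m)
    y <- module_truth(records, m)[pop]
    xm <- x[pop, , drop = FALSE]
    sub <- select_features(xm, y, alpha = alpha)
    modules[[m]] <- train_module(xm, y, m, sub, config)
  }
  contrast <- NULL
  if (train_contrast_model) {
    t1 <- which(vapply(records, function(r)
      !r$truth$is_other && identical(r$truth$weighting, "T1W") &&
        !is.null(r$pixel_source), logical(1)))
    if (length(t1) >= 2) {
      imgs <- lapply(records[t1], get_series_image,
                     size = image_config$input_size)
      labs <- vapply(records[t1], function(r) r$truth$contrast, "")
      contrast <- train_contrast(imgs, labs, image_config)
    }
  }
  structure(list(schema = schema, lexicon = lexicon, encoder = encoder,
                 modules = modules, contrast = contrast,
                 backend_config = config, image_config = image_config),
            class = "mrseries_bundle")
}

#' @export
print.mrseries_bundle <- function(x, ...) {
  cat("<mrseries_bundle> backend:", x$backend_config$backend,
      " modules:", paste(names(x$modules), collapse = ", "),
      if (!is.null(x$contrast)) " + contrast(small_cnn)", "\n")
  invisible(x)
}

#' Evaluate a trained bundle on a held-out cohort
#'
#' @param records Held-out `series_record` list with ground truth.
#' @param bundle A [train_pipeline()] bundle.
#' @return List with `predictions` (from [classify_cohort()]), the 8-class
#'   `confusion` matrix, its `metrics` report, and `module_accuracy`: the
#'   per-module held-out accuracy on each module's ground-truth-routed
#'   population (including the contrast branch when present).
#' @export
evaluate_pipeline <- function(records, bundle) {
  preds <- classify_cohort(records, bundle)
  truth <- cohort_truth(records)
  ## undetermined-contrast predictions ("T1W_FS"/"T1W_nFS") appear as extra
  ## prediction-only classes with zero truth support
  classes <- union(label_space(), unique(preds$label))
  cm <- confusion(truth, preds$label, classes = classes)
  rows <- rows_from_records(records, bundle$schema)
  x <- encode_features(bundle$encoder, rows)
  mod_acc <- c()
  for (m in names(bundle$modules)) {
    pop <- module_population(records, m)
    if (!any(pop)) next
    p <- module_probs(bundle$modules[[m]], x[pop, , drop = FALSE])
    pred <- apply(p, 1, function(pr)
      decide_class(stats::setNames(pr, colnames(p))))
    mod_acc[m] <- mean(pred == module_truth(records, m)[pop])
  }
  if (!is.null(bundle$contrast)) {
    t1 <- which(vapply(records, function(r)
      !r$truth$is_other && identical(r$truth$weighting, "T1W") &&
        !is.null(r$pixel_source), logical(1)))
    if (length(t1)) {
      imgs <- lapply(records[t1], get_series_image,
                     size = bundle$contrast$config$input_size)
      pr <- contrast_probs(bundle$contrast, imgs)
      pred <- ifelse(pr >= bundle$contrast$config$threshold, "CE", "nCE")
      mod_acc["Contrast"] <-
        mean(pred == vapply(records[t1], function(r) r$truth$contrast, ""))
    }
  }
  list(predictions = preds, confusion = cm,
       metrics = metrics_from_confusion(cm), module_accuracy = mod_acc)
}
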