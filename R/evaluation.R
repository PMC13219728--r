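## Evaluation: splits, confusion-matrix metrics, bootstrap CIs ----------------

#' Round half-up for display
#'
#' Matches conventional table rounding (0.8535 -> 0.854), unlike banker's
#' rounding.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 3) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Confusion matrix over an ordered class list
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Ordered class list; every label must be in it.
#' @return Integer matrix, rows = ground truth, columns = predicted, of
#'   class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred, classes) {
  stopifnot(length(y_true) == length(y_pred))
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad))
    stop("labels outside the class list: ", paste(bad, collapse = ", "),
         call. = FALSE)
  m <- table(factor(y_true, levels = classes),
             factor(y_pred, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' The published test-set confusion matrix of the PRIMAGE pipeline
#'
#' The 8x8 end-to-end confusion matrix (family excluded) reported for the
#' independent PRIMAGE test set (N = 3,639 series). Used as the exact
#' reference input for metric computations and in examples.
#'
#' @return A `confusion_matrix`.
#' @export
#' @examples
#' m <- primage_confusion()
#' metrics_from_confusion(m)$accuracy
primage_confusion <- function() {
  classes <- label_space()
  m <- rbind(
    c(306,   3,   0,   0,   0,    0,   0,   2),
    c( 67, 115,   6,  17,   5,   38,   8,   4),
    c(  0,   0, 259,  99,   4,    3,   0,   0),
    c(  0,   0,  69, 273,   6,   12,   1,   0),
    c(  0,   0,   4,   4,  28,   43,   0,   0),
    c(  0,  12,  10,  23,  42, 1004,   0,   4),
    c(  1,   0,   0,   3,   1,    0, 667,  19),
    c(  2,   0,   0,   0,   0,    1,  22, 452))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(truth = classes, predicted = classes)
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Per-class and aggregate metrics from a confusion matrix
#'
#' Precision = column-wise diagonal fraction (0, flagged, when a class is
#' never predicted), sensitivity (recall) = row-wise, F1 their harmonic mean
#' (0 when both are 0); macro aggregates are unweighted means, weighted
#' aggregates are support-weighted means, accuracy = trace / total. Display
#' rounding is half-up to 3 decimals (see [format_metrics()]); the returned
#' values are unrounded.
#'
#' @param m A [confusion()] matrix.
#' @return An object of class `metrics_report`: `per_class` data frame,
#'   `macro` and `weighted` named vectors, `accuracy`, `total`.
#' @export
metrics_from_confusion <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  total <- sum(m)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  classes <- rownames(m)
  support <- rowSums(m)
  colsum <- colSums(m)
  d <- diag(m)
  precision <- ifelse(colsum > 0, d / colsum, 0)
  sensitivity <- ifelse(support > 0, d / support, 0)
  f1 <- ifelse(precision + sensitivity > 0,
               2 * precision * sensitivity / (precision + sensitivity), 0)
  per_class <- data.frame(
    class = classes, precision = as.numeric(precision),
    sensitivity = as.numeric(sensitivity), f1 = as.numeric(f1),
    support = as.integer(support),
    never_predicted = colsum == 0, row.names = NULL,
    stringsAsFactors = FALSE)
  agg <- function(w) c(precision = sum(precision * w) / sum(w),
                       sensitivity = sum(sensitivity * w) / sum(w),
                       f1 = sum(f1 * w) / sum(w))
  structure(list(per_class = per_class,
                 macro = agg(rep(1, length(classes))),
                 weighted = agg(support),
                 accuracy = sum(d) / total,
                 total = as.integer(total)),
            class = "metrics_report")
}

#' Display-rounded metrics table
#' @param report A [metrics_from_confusion()] report.
#' @param digits Decimal places (half-up).
#' @return Data frame in table form (per-class rows plus macro/weighted
#'   aggregate rows and accuracy).
#' @export
format_metrics <- function(report, digits = 3) {
  pc <- report$per_class
  out <- data.frame(
    class = c(pc$class, "macro avg", "weighted avg", "accuracy"),
    precision = round_half_up(c(pc$precision, report$macro["precision"],
                                report$weighted["precision"], NA), digits),
    sensitivity = round_half_up(c(pc$sensitivity,
                                  report$macro["sensitivity"],
                                  report$weighted["sensitivity"], NA),
                                digits),
    f1 = round_half_up(c(pc$f1, report$macro["f1"], report$weighted["f1"],
                         NA), digits),
    support = c(pc$support, report$total, report$total, report$total),
    row.names = NULL)
  out$precision[nrow(out)] <- round_half_up(report$accuracy, digits)
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  print(format_metrics(x))
  invisible(x)
}

## Splitting ------------------------------------------------------------------

#' Split plan
#'
#' @param test_frac Series fraction targeted for the test partition.
#' @param k Cross-validation folds within the training partition.
#' @param seed Assignment seed.
#' @return An object of class `split_plan`.
#' @export
split_plan <- function(test_frac = 0.2, k = 5, seed = 1L) {
  stopifnot(test_frac > 0, test_frac < 1, k >= 2)
  structure(list(test_frac = test_frac, k = k, seed = as.integer(seed)),
            class = "split_plan")
}

## Patient-level class-count matrix (patients x classes), plus series counts.
patient_class_counts <- function(records) {
  patients <- vapply(records, `[[`, "", "patient_id")
  labels <- cohort_truth(records)
  tab <- table(patients, labels)
  matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
}

## Greedy balanced assignment of patients to partitions: patients are
## processed in decreasing series count (seeded shuffle breaks ties) and
## each goes to the partition that minimises the squared deviation of
## per-class and total series counts from their targets.
greedy_assign <- function(counts, targets, seed) {
  n_pat <- nrow(counts)
  n_bin <- nrow(targets)
  set.seed(seed)
  ord <- sample.int(n_pat)
  ord <- ord[order(-rowSums(counts)[ord])]
  bin_counts <- matrix(0, n_bin, ncol(counts))
  assign <- integer(n_pat)
  for (i in ord) {
    obj <- vapply(seq_len(n_bin), function(b) {
      bc <- bin_counts
      bc[b, ] <- bc[b, ] + counts[i, ]
      sum((bc - targets)^2 / pmax(1, targets))
    }, numeric(1))
    b <- which.min(obj)
    bin_counts[b, ] <- bin_counts[b, ] + counts[i, ]
    assign[i] <- b
  }
  assign
}

#' Patient-grouped train/test split balancing the class distribution
#'
#' Patients never span partitions; a greedy assignment balances the
#' series-level class distribution so that the test partition holds close
#' to the target fraction of every class. Deterministic per seed.
#'
#' @param records Cohort records with `patient_id` and ground truth.
#' @param plan A [split_plan()] (its `test_frac` and `seed` are used).
#' @return List with integer index vectors `train` and `test`.
#' @export
patient_split <- function(records, plan = split_plan()) {
  patients <- vapply(records, function(r) {
    if (is.null(r$patient_id) || is.na(r$patient_id) ||
        !nzchar(r$patient_id))
      stop("record ", r$series_uid, " lacks a patient_id", call. = FALSE)
    r$patient_id
  }, "")
  counts <- patient_class_counts(records)
  if (nrow(counts) == 1) {
    warning("single patient: test fraction unreachable, all series in train",
            call. = FALSE)
    return(list(train = seq_along(records), test = integer(0)))
  }
  tot <- colSums(counts)
  targets <- rbind(train = (1 - plan$test_frac) * tot,
                   test = plan$test_frac * tot)
  assign <- greedy_assign(counts, targets, plan$seed)
  test_patients <- rownames(counts)[assign == 2]
  idx_test <- which(patients %in% test_patients)
  list(train = setdiff(seq_along(records), idx_test), test = idx_test)
}

#' Patient-grouped cross-validation fold assignment
#'
#' @param records Cohort records.
#' @param k Number of folds.
#' @param seed Assignment seed.
#' @return Integer vector of fold ids (1..k), one per record;
#'   patient-disjoint across folds.
#' @export
cv_folds <- function(records, k = 5, seed = 1L) {
  patients <- vapply(records, `[[`, "", "patient_id")
  if (length(unique(patients)) < k)
    stop("fewer patients than folds", call. = FALSE)
  counts <- patient_class_counts(records)
  tot <- colSums(counts)
  targets <- matrix(rep(tot / k, each = k), nrow = k)
  assign <- greedy_assign(counts, targets, seed)
  fold_of_patient <- stats::setNames(assign, rownames(counts))
  unname(fold_of_patient[patients])
}

## Bootstrap ------------------------------------------------------------------

metric_fun <- function(metric, classes) {
  if (is.function(metric)) return(metric)
  switch(metric,
    accuracy = function(t, p) mean(t == p),
    macro_f1 = function(t, p)
      metrics_from_confusion(confusion(t, p, classes))$macro["f1"],
    weighted_f1 = function(t, p)
      metrics_from_confusion(confusion(t, p, classes))$weighted["f1"],
    macro_precision = function(t, p)
      metrics_from_confusion(confusion(t, p, classes))$macro["precision"],
    macro_sensitivity = function(t, p)
      metrics_from_confusion(confusion(t, p, classes))$macro["sensitivity"],
    weighted_precision = function(t, p)
      metrics_from_confusion(confusion(t, p, classes))$weighted["precision"],
    weighted_sensitivity = function(t, p)
      metrics_from_confusion(confusion(t, p, classes))$weighted["sensitivity"],
    stop("unknown metric: ", metric))
}

#' Percentile bootstrap confidence interval for a classification metric
#'
#' Resamples series indices (paired truth/prediction) with replacement.
#' Deterministic per seed; the interval always contains the point estimate
#' (it is widened to include it in the rare degenerate case).
#'
#' @param y_true,y_pred Label vectors.
#' @param metric Metric name (`"accuracy"`, `"macro_f1"`, `"weighted_f1"`,
#'   `"macro_precision"`, `"macro_sensitivity"`, `"weighted_precision"`,
#'   `"weighted_sensitivity"`) or a function `(truth, pred) -> numeric`.
#' @param n_boot Number of resamples.
#' @param level Confidence level.
#' @param seed Resampling seed.
#' @param classes Class list (defaults to observed labels, sorted).
#' @return List with `estimate`, `lower`, `upper`, `level`, `n_boot`.
#' @export
bootstrap_ci <- function(y_true, y_pred, metric = "accuracy",
                         n_boot = 2000, level = 0.95, seed = 1L,
                         classes = sort(unique(c(y_true, y_pred)))) {
  n <- length(y_true)
  stopifnot(n >= 2, length(y_pred) == n)
  f <- metric_fun(metric, classes)
  est <- as.numeric(f(y_true, y_pred))
  set.seed(seed)
  stats <- vapply(seq_len(n_boot), function(b) {
    ix <- sample.int(n, n, replace = TRUE)
    as.numeric(f(y_true[ix], y_pred[ix]))
  }, numeric(1))
  if (length(unique(stats)) == 1)
    warning("metric is degenerate on all resamples; returning a collapsed ",
            "interval", call. = FALSE)
  a <- (1 - level) / 2
  q <- stats::quantile(stats, c(a, 1 - a), names = FALSE, na.rm = TRUE)
  list(estimate = est, lower = min(q[1], est), upper = max(q[2], est),
       level = level, n_boot = n_boot)
}

## Subgroups ------------------------------------------------------------------

#' Per-level metrics by scanner vendor, field strength, or country
#'
#' @param records Cohort records carrying the factor values.
#' @param predictions Character vector of predicted canonical labels
#'   (aligned with `records`).
#' @param factor_name `"manufacturer"`, `"field_strength"`, or `"country"`.
#' @param ci Attach bootstrap CIs (accuracy) per level.
#' @param min_n Levels with fewer series are flagged unstable.
#' @param seed Bootstrap seed.
#' @return Data frame, one row per factor level, with N, accuracy, macro
#'   and weighted F1, optional CI bounds, and an `unstable` flag.
#' @export
subgroup_report <- function(records, predictions,
                            factor_name = c("manufacturer",
                                            "field_strength", "country"),
                            ci = TRUE, min_n = 30, seed = 1L) {
  factor_name <- match.arg(factor_name)
  field <- switch(factor_name, manufacturer = "vendor",
                  field_strength = "field_strength", country = "country")
  vals <- vapply(records, function(r) {
    v <- r[[field]]
    if (is.null(v) || is.na(v)) "unknown" else as.character(v)
  }, "")
  truth <- cohort_truth(records)
  stopifnot(length(predictions) == length(truth))
  classes <- label_space()
  rows <- lapply(sort(unique(vals)), function(lv) {
    ix <- which(vals == lv)
    rep_ <- metrics_from_confusion(
      confusion(truth[ix], predictions[ix], classes))
    out <- data.frame(
      level = lv, n = length(ix), accuracy = rep_$accuracy,
      macro_f1 = rep_$macro["f1"], weighted_f1 = rep_$weighted["f1"],
      unstable = length(ix) < min_n, row.names = NULL,
      stringsAsFactors = FALSE)
    if (ci && length(ix) >= 2) {
      b <- bootstrap_ci(truth[ix], predictions[ix], "accuracy",
                        seed = seed, classes = classes)
      out$accuracy_lo <- b$lower
      out$accuracy_hi <- b$upper
    } else if (ci) {
      out$accuracy_lo <- NA_real_
      out$accuracy_hi <- NA_real_
    }
    out
  })
  do.call(rbind, rows)
}
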