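## Hierarchical conditional routing -------------------------------------------
##
## Activation rules of the five-classifier cascade:
##   Others      -> if "other", classification stops (label OTHERS).
##   Weighting   -> only for relevant series; if DWI, the top branch stops.
##   FatSup      -> only if Weighting says T1W or T2W.
##   Contrast    -> only if Weighting says T1W (image-based).
##   Family      -> for every relevant series; the Scanning Sequence tag is
##                  used directly unless it is empty or "Mode Research", in
##                  which case the Family model is invoked.

FAMILY_PRIORITY <- c("IR", "EP", "GR", "SE")

## Family from the Scanning Sequence tag, or NA when the tag is unusable.
family_from_tag <- function(tags) {
  ss <- toupper(trimws(as.character(unlist(tags$ScanningSequence))))
  ss <- ss[nzchar(ss)]
  if (!length(ss)) return(NA_character_)
  if (any(ss == "MODE RESEARCH")) return(NA_character_)
  for (fam in FAMILY_PRIORITY) if (fam %in% ss) return(fam)
  NA_character_
}

#' Resolve the pulse-sequence family of a relevant series
#'
#' If the Scanning Sequence tag is present and is not "Mode Research", its
#' codes are mapped directly to SE/GR/IR/EP (multi-valued tags resolve by
#' the priority IR > EP > GR > SE) and the Family model is not invoked.
#' Otherwise the Family model predicts from the encoded tag features.
#'
#' @param record A `series_record` (classified relevant).
#' @param bundle A trained [train_pipeline()] bundle.
#' @return List with `family` (`"SE"/"GR"/"IR"/"EP"` or `NA` if
#'   undeterminable), and `source` (`"tag"` or `"model"`).
#' @export
resolve_family <- function(record, bundle) {
  fam <- family_from_tag(record$tags)
  if (!is.na(fam)) return(list(family = fam, source = "tag"))
  if (is.null(bundle$modules$Family)) {
    warning("Scanning Sequence unusable and no Family model available for ",
            record$series_uid, call. = FALSE)
    return(list(family = NA_character_, source = "model"))
  }
  rows <- rows_from_records(list(record), bundle$schema)
  x <- encode_features(bundle$encoder, rows)
  dec <- predict_module(bundle$modules$Family, x)
  list(family = dec$class, source = "model")
}

#' Classify a whole cohort through the cascade
#'
#' Batch counterpart of [classify_series()]: encodes all series once and
#' runs each module on exactly the subset its activation rule selects.
#'
#' @param records List of `series_record`.
#' @param bundle A [train_pipeline()] bundle.
#' @return Data frame with one row per series: `series_uid`, canonical
#'   `label`, `family`, `family_source`, `contrast_undetermined`, and
#'   per-module predictions/probabilities where executed. The per-series
#'   routing traces are in attribute `"traces"` (list of character vectors
#'   of executed modules, with skip reasons in attribute `"skipped"`).
#' @export
classify_cohort <- function(records, bundle) {
  n <- length(records)
  rows <- rows_from_records(records, bundle$schema)
  x <- encode_features(bundle$encoder, rows)
  uid <- vapply(records, `[[`, "", "series_uid")

  need <- function(m) if (is.null(bundle$modules[[m]]))
    stop("bundle lacks the ", m, " module required by the routing rules",
         call. = FALSE)
  need("Others")
  p_oth <- module_probs(bundle$modules$Others, x)
  pred_oth <- apply(p_oth, 1, function(p)
    decide_class(stats::setNames(p, colnames(p_oth))))

  pred_w <- rep(NA_character_, n)
  rel <- which(pred_oth == "relevant")
  if (length(rel)) {
    need("Weighting")
    p_w <- module_probs(bundle$modules$Weighting, x[rel, , drop = FALSE])
    pred_w[rel] <- apply(p_w, 1, function(p)
      decide_class(stats::setNames(p, colnames(p_w))))
  }

  pred_fs <- rep(NA_character_, n)
  fsx <- which(pred_w %in% c("T1W", "T2W"))
  if (length(fsx)) {
    need("FatSuppression")
    p_fs <- module_probs(bundle$modules$FatSuppression,
                         x[fsx, , drop = FALSE])
    pred_fs[fsx] <- apply(p_fs, 1, function(p)
      decide_class(stats::setNames(p, colnames(p_fs))))
  }

  pred_ce <- rep(NA_character_, n)
  cex <- which(pred_w == "T1W")
  if (length(cex)) {
    has_px <- vapply(records[cex], function(r) !is.null(r$pixel_source),
                     logical(1))
    if (any(has_px)) {
      if (is.null(bundle$contrast))
        stop("bundle lacks the Contrast model required by the routing rules",
             call. = FALSE)
      imgs <- lapply(records[cex[has_px]], get_series_image,
                     size = bundle$contrast$config$input_size)
      pr <- contrast_probs(bundle$contrast, imgs)
      pred_ce[cex[has_px]] <- ifelse(pr >= bundle$contrast$config$threshold,
                                     "CE", "nCE")
    }
    pred_ce[cex[!has_px]] <- "undetermined"
  }

  fam <- rep(NA_character_, n)
  fam_src <- rep(NA_character_, n)
  fam_model_ix <- integer(0)
  if (length(rel)) {
    for (i in rel) {
      f <- family_from_tag(records[[i]]$tags)
      if (!is.na(f)) {
        fam[i] <- f
        fam_src[i] <- "tag"
      } else fam_model_ix <- c(fam_model_ix, i)
    }
    if (length(fam_model_ix)) {
      need("Family")
      p_f <- module_probs(bundle$modules$Family,
                          x[fam_model_ix, , drop = FALSE])
      fam[fam_model_ix] <- apply(p_f, 1, function(p)
        decide_class(stats::setNames(p, colnames(p_f))))
      fam_src[fam_model_ix] <- "model"
    }
  }

  labels <- character(n)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    executed <- "Others"
    skipped <- character(0)
    if (pred_oth[i] == "other") {
      labels[i] <- "OTHERS"
      skipped <- c(Weighting = "series classified as other",
                   FatSuppression = "series classified as other",
                   Contrast = "series classified as other",
                   Family = "series classified as other")
    } else {
      executed <- c(executed, "Weighting")
      executed <- c(executed,
                    if (fam_src[i] %in% "model") "Family" else character(0))
      if (pred_w[i] == "DWI") {
        labels[i] <- "DWI"
        skipped <- c(skipped, FatSuppression = "weighting is DWI",
                     Contrast = "weighting is DWI")
      } else {
        executed <- c(executed, "FatSuppression")
        if (pred_w[i] == "T1W") {
          executed <- c(executed, "Contrast")
          lab <- composite_label("T1W", pred_fs[i],
                                 contrast = pred_ce[i])
          labels[i] <- compose_label(lab)
        } else {
          skipped <- c(skipped, Contrast = "weighting is T2W")
          labels[i] <- compose_label(composite_label("T2W", pred_fs[i]))
        }
      }
    }
    tr <- executed
    attr(tr, "skipped") <- skipped
    traces[[i]] <- tr
  }
  out <- data.frame(series_uid = uid, label = labels, family = fam,
                    family_source = fam_src,
                    contrast_undetermined = pred_ce %in% "undetermined",
                    others_pred = pred_oth, weighting_pred = pred_w,
                    fs_pred = pred_fs, contrast_pred = pred_ce,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "traces") <- traces
  out
}

#' Classify one series through the cascade
#'
#' @param record A `series_record`.
#' @param bundle A [train_pipeline()] bundle.
#' @return A `pipeline_result`: the executed module decisions, the final
#'   [composite_label()], its canonical string, and the routing trace.
#' @export
classify_series <- function(record, bundle) {
  df <- classify_cohort(list(record), bundle)
  tr <- attr(df, "traces")[[1]]
  lab <- parse_label(df$label[1],
                     family = if (df$label[1] == "OTHERS") NA_character_
                              else df$family[1])
  if (identical(df$contrast_pred[1], "undetermined"))
    lab$contrast <- "undetermined"
  structure(list(series_uid = df$series_uid[1], label = lab,
                 canonical = df$label[1], family = df$family[1],
                 family_source = df$family_source[1],
                 executed = as.character(tr),
                 skipped = attr(tr, "skipped"),
                 decisions = df[1, ]),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$series_uid, "->", x$canonical,
      if (!is.na(x$family)) paste0("[", x$family, " via ", x$family_source,
                                   "]"), "\n")
  cat("  executed:", paste(x$executed, collapse = " > "), "\n")
  invisible(x)
}

## The module set the activation rules imply for a given set of decisions;
## used by tests and by the routing-soundness check.
expected_modules <- function(others_pred, weighting_pred, family_source) {
  if (others_pred == "other") return("Others")
  out <- c("Others", "Weighting")
  if (identical(family_source, "model")) out <- c(out, "Family")
  if (weighting_pred %in% c("T1W", "T2W")) out <- c(out, "FatSuppression")
  if (identical(weighting_pred, "T1W")) out <- c(out, "Contrast")
  out
}
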