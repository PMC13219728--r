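## Feature encoding and association-based selection ---------------------------

sanitize_level <- function(x) gsub("[^A-Za-z0-9.|]+", "_", x)

#' Fit the feature encoder on training rows
#'
#' Learns the categorical level sets (one-hot groups are fixed to the levels
#' observed in training; unseen predict-time levels encode as an all-zero
#' group) and freezes the column order. Numeric tags encode as value
#' (missing as 0) plus a missingness indicator; text tags as a presence
#' indicator; the preliminary text category and its contrast/fat-suppression
#' marker flags are appended, together with diffusion-derived numerics
#' (maximum b-value and b-value count).
#'
#' @param rows Raw tag rows from [rows_from_records()] (training rows only).
#' @param schema Tag schema, see [default_tag_schema()].
#' @param lexicon Preliminary-classifier lexicon.
#' @return An object of class `feature_encoder`.
#' @export
fit_encoder <- function(rows, schema = default_tag_schema(),
                        lexicon = load_lexicon()) {
  levels <- list()
  for (i in seq_len(nrow(schema))) {
    if (schema$kind[i] %in% c("categorical", "multi_valued")) {
      nm <- schema$name[i]
      lv <- sort(unique(rows[[nm]][!is.na(rows[[nm]])]))
      levels[[nm]] <- lv
    }
  }
  structure(list(schema = schema, levels = levels, lexicon = lexicon,
                 categories = lexicon_categories(lexicon)),
            class = "feature_encoder")
}

#' Encode raw tag rows into a numeric feature matrix
#'
#' Deterministic given the encoder: identical inputs give identical
#' matrices regardless of row order of fitting data. Missing numeric values
#' encode as 0 with their indicator set to 1; a categorical level unseen at
#' fit time leaves its one-hot group all zero.
#'
#' @param encoder A [fit_encoder()] object.
#' @param rows Raw tag rows (any split).
#' @return Numeric matrix with series UIDs as row names; column metadata in
#'   attribute `"columns"` (source tag and encoding per column).
#' @export
encode_features <- function(encoder, rows) {
  stopifnot(inherits(encoder, "feature_encoder"))
  schema <- encoder$schema
  unknown <- setdiff(names(rows), schema$name)
  if (length(unknown))
    stop("rows contain tags not in the schema: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  n <- nrow(rows)
  cols <- list()
  meta <- list()
  add <- function(name, values, source, encoding) {
    cols[[name]] <<- as.numeric(values)
    meta[[name]] <<- data.frame(column = name, source = source,
                                encoding = encoding,
                                stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    kind <- schema$kind[i]
    v <- rows[[nm]]
    if (is.null(v)) v <- rep(NA, n)
    if (kind == "numeric") {
      num <- vapply(v, parse_numeric_cell, numeric(1))
      add(nm, ifelse(is.na(num), 0, num), nm, "numeric")
      add(paste0(nm, "__missing"), as.numeric(is.na(num)), nm,
          "missing-indicator")
    } else if (kind %in% c("categorical", "multi_valued")) {
      for (lv in encoder$levels[[nm]]) {
        add(paste0(nm, "..", sanitize_level(lv)),
            as.numeric(!is.na(v) & v == lv), nm, "one-hot level")
      }
      add(paste0(nm, "__missing"), as.numeric(is.na(v)), nm,
          "missing-indicator")
    } else {  # text
      add(paste0(nm, "__present"), as.numeric(!is.na(v) & nzchar(v)), nm,
          "presence-indicator")
    }
  }
  ## diffusion-derived numerics from the joined b-value list
  bv <- rows[["DiffusionBValue"]]
  if (!is.null(bv)) {
    parts <- lapply(as.character(bv), function(x)
      if (is.na(x)) numeric(0)
      else suppressWarnings(as.numeric(strsplit(x, "|", fixed = TRUE)[[1]])))
    add("bval_max", vapply(parts, function(p)
      if (length(p)) max(p, na.rm = TRUE) else 0, numeric(1)),
      "DiffusionBValue", "numeric")
    add("bval_n", vapply(parts, length, integer(1)),
        "DiffusionBValue", "numeric")
  }
  ## preliminary text classifier output
  pc <- preclass_rows(rows, encoder$lexicon)
  for (cat in encoder$categories) {
    add(paste0("preclass..", sanitize_level(cat)),
        as.numeric(pc$category == cat), "preclass", "preclass one-hot")
  }
  add("preclass__ce_marker", as.numeric(pc$ce_marker), "preclass",
      "marker flag")
  add("preclass__fs_marker", as.numeric(pc$fs_marker), "preclass",
      "marker flag")

  m <- do.call(cbind, cols)
  rownames(m) <- rownames(rows)
  attr(m, "columns") <- do.call(rbind, meta)
  m
}

## 32-bit FNV-1a hash of the sorted row identifiers; fingerprints the split
## a feature subset was fitted on so that leakage is detectable.
fingerprint_rows <- function(ids) {
  s <- paste(sort(ids), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Association-based feature selection
#'
#' Tests every encoded column against the target with a per-column
#' association test: chi-square test of independence (no continuity
#' correction) for indicator/one-hot columns, Kruskal-Wallis for numeric
#' columns. Columns with p <= alpha are retained; constant columns are
#' dropped with p recorded as 1. Selection must be fitted on training rows
#' only; the returned subset carries a fingerprint of the rows it saw.
#'
#' @param x Feature matrix from [encode_features()] (training rows only).
#' @param y Target labels (length `nrow(x)`, at least 2 classes).
#' @param alpha Per-test significance level.
#' @param correction Multiple-testing correction passed to
#'   [stats::p.adjust()]; `"none"` by default (a flat per-test level).
#' @return An object of class `feature_subset` with the per-column test
#'   table, selected column names, alpha, and split fingerprint.
#' @export
select_features <- function(x, y, alpha = 0.01, correction = "none") {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2)
    stop("feature selection requires at least 2 target classes",
         call. = FALSE)
  stopifnot(nrow(x) == length(y))
  res <- lapply(colnames(x), function(cn) {
    v <- x[, cn]
    u <- unique(v)
    if (length(u) <= 1)
      return(data.frame(column = cn, test = "constant", statistic = NA_real_,
                        p = 1, stringsAsFactors = FALSE))
    if (all(u %in% c(0, 1))) {
      ct <- suppressWarnings(stats::chisq.test(table(v, y), correct = FALSE))
      data.frame(column = cn, test = "chi-square",
                 statistic = unname(ct$statistic), p = unname(ct$p.value),
                 stringsAsFactors = FALSE)
    } else {
      kt <- stats::kruskal.test(v, y)
      data.frame(column = cn, test = "kruskal-wallis",
                 statistic = unname(kt$statistic), p = unname(kt$p.value),
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, res)
  if (!identical(correction, "none"))
    tab$p <- stats::p.adjust(tab$p, method = correction)
  selected <- tab$column[tab$test != "constant" & !is.na(tab$p) &
                           tab$p <= alpha]
  structure(list(table = tab, selected = selected, alpha = alpha,
                 correction = correction,
                 fingerprint = fingerprint_rows(rownames(x))),
            class = "feature_subset")
}

#' Verify that a feature subset was fitted on the same rows
#'
#' Guards against information leakage: re-using a subset fitted on one split
#' with rows from another split is flagged.
#'
#' @param subset A [select_features()] object.
#' @param x Feature matrix whose rows should match the fitting split.
#' @return `TRUE` if the fingerprints match, else `FALSE` (with a warning).
#' @export
check_split_fingerprint <- function(subset, x) {
  ok <- identical(subset$fingerprint, fingerprint_rows(rownames(x)))
  if (!ok)
    warning("feature subset was fitted on a different row set ",
            "(possible train/test leakage)", call. = FALSE)
  ok
}

#' @export
print.feature_subset <- function(x, ...) {
  cat("<feature_subset>", length(x$selected), "of", nrow(x$table),
      "columns at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Serialize a feature-subset report to JSON
#' @param subset A [select_features()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_subset_report <- function(subset, path) {
  jsonlite::write_json(
    list(alpha = subset$alpha, correction = subset$correction,
         fingerprint = subset$fingerprint, selected = subset$selected,
         tests = subset$table),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
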