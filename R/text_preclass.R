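## Preliminary text classifier ------------------------------------------------
##
## A coarse keyword classifier over the three descriptive tags (Series
## Description, Sequence Name, Protocol Name). Its output is never a final
## prediction: it is an engineered feature concatenated with the encoded tag
## features for every downstream tabular module. The routing logic never
## reads it.

#' Normalize descriptive tag text
#'
#' Lower-cases, turns punctuation and underscores into single spaces, and
#' collapses whitespace. Missing input becomes the empty string.
#'
#' @param raw Character vector (or `NULL`).
#' @return Character vector of normalized token strings.
#' @export
#' @examples
#' normalize_text("T1_TSE_SAG+C")
normalize_text <- function(raw) {
  if (is.null(raw) || !length(raw)) return("")
  x <- tolower(as.character(raw))
  x[is.na(x)] <- ""
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub("[ ]+", " ", x))
}

#' Load a preliminary-classifier lexicon
#'
#' The lexicon is a versioned plain-text configuration: an ordered list of
#' coarse categories with keyword patterns (order defines match priority;
#' UNKNOWN is the implicit pattern-free fallback) plus independent
#' contrast-marker and fat-suppression-marker keyword lists.
#'
#' @param path YAML file; defaults to the lexicon shipped with the package.
#' @return An object of class `lexicon`.
#' @export
load_lexicon <- function(path = system.file("extdata", "lexicon.yaml",
                                            package = "mrseries")) {
  raw <- yaml::read_yaml(path)
  cats <- lapply(raw$categories, function(cc)
    list(name = cc$name, patterns = normalize_text(unlist(cc$patterns))))
  structure(list(version = raw$version, categories = cats,
                 ce_markers = normalize_text(unlist(raw$ce_markers)),
                 fs_markers = normalize_text(unlist(raw$fs_markers))),
            class = "lexicon")
}

#' Category names of a lexicon (UNKNOWN last)
#' @param lexicon A [load_lexicon()] object.
#' @return Character vector of category names.
#' @export
lexicon_categories <- function(lexicon) {
  c(vapply(lexicon$categories, `[[`, "", "name"), "UNKNOWN")
}

match_any <- function(text, patterns) {
  if (!nzchar(text) || !length(patterns)) return(FALSE)
  ## patterns are already normalized ([a-z0-9 ] only); word-bounded match
  any(vapply(patterns, function(p)
    grepl(paste0("\\b", p, "\\b"), text), logical(1)))
}

#' Classify the descriptive tags into a coarse textual category
#'
#' Concatenates the normalized Series Description, Sequence Name, and
#' Protocol Name and matches the lexicon categories in priority order;
#' returns the first matching category plus independent contrast-marker and
#' fat-suppression-marker flags. All-empty input yields UNKNOWN with both
#' flags `FALSE`.
#'
#' @param series_description,sequence_name,protocol_name Raw tag values
#'   (missing as `NULL` or `NA`).
#' @param lexicon A [load_lexicon()] object.
#' @return List with `category`, `ce_marker`, `fs_marker`.
#' @export
#' @examples
#' lex <- load_lexicon()
#' classify_text("t1 vibe fs +c", NULL, NULL, lex)
classify_text <- function(series_description = NULL, sequence_name = NULL,
                          protocol_name = NULL, lexicon = load_lexicon()) {
  txt <- trimws(paste(normalize_text(series_description),
                      normalize_text(sequence_name),
                      normalize_text(protocol_name)))
  category <- "UNKNOWN"
  for (cc in lexicon$categories) {
    if (match_any(txt, cc$patterns)) { category <- cc$name; break }
  }
  list(category = category,
       ce_marker = match_any(txt, lexicon$ce_markers),
       fs_marker = match_any(txt, lexicon$fs_markers))
}

## Vectorized preclass over a raw tag-row data frame.
preclass_rows <- function(rows, lexicon) {
  out <- lapply(seq_len(nrow(rows)), function(i)
    classify_text(rows$SeriesDescription[i], rows$SequenceName[i],
                  rows$ProtocolName[i], lexicon))
  data.frame(category = vapply(out, `[[`, "", "category"),
             ce_marker = vapply(out, `[[`, logical(1), "ce_marker"),
             fs_marker = vapply(out, `[[`, logical(1), "fs_marker"),
             row.names = rownames(rows), stringsAsFactors = FALSE)
}
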