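#' @keywords internal
"_PACKAGE"

## Composite label space ------------------------------------------------------

#' The eight end-to-end composite classes
#'
#' Ordered class list used for end-to-end evaluation. The pulse-sequence
#' family (SE/GR/IR/EP) is reported separately and is not part of this space.
#'
#' @return Character vector of the eight canonical labels.
#' @export
label_space <- function() {
  c("DWI", "OTHERS", "T1W_nFS_nCE", "T1W_nFS_CE",
    "T1W_FS_nCE", "T1W_FS_CE", "T2W_nFS", "T2W_FS")
}

WEIGHTINGS <- c("T1W", "T2W", "DWI")
FAMILIES   <- c("SE", "GR", "IR", "EP")

#' Construct a composite series label
#'
#' A composite label captures the joint output of the classifier cascade:
#' whether the series is non-diagnostic ("Others"), its weighting
#' (T1W/T2W/DWI), fat suppression (FS/nFS), contrast status (CE/nCE, assessed
#' only for T1W; `"undetermined"` when no pixel data was available), and the
#' pulse-sequence family (SE/GR/IR/EP).
#'
#' Structural invariants are enforced: an Others label carries no other
#' fields; DWI carries neither fat-suppression nor contrast status; contrast
#' status other than `NA` is only legal for T1W.
#'
#' @param weighting One of `"T1W"`, `"T2W"`, `"DWI"`, or `NA`.
#' @param fat_suppressed `"FS"`, `"nFS"`, or `NA`.
#' @param contrast `"CE"`, `"nCE"`, `"undetermined"`, or `NA`.
#' @param family `"SE"`, `"GR"`, `"IR"`, `"EP"`, or `NA`.
#' @param is_other Logical; `TRUE` for non-diagnostic series.
#' @return An object of class `composite_label`.
#' @export
#' @examples
#' composite_label("T1W", "FS", "CE", "SE")
#' composite_label(is_other = TRUE)
composite_label <- function(weighting = NA_character_,
                            fat_suppressed = NA_character_,
                            contrast = NA_character_,
                            family = NA_character_,
                            is_other = FALSE) {
  lab <- structure(
    list(is_other = isTRUE(is_other),
         weighting = as.character(weighting),
         fat_suppressed = as.character(fat_suppressed),
         contrast = as.character(contrast),
         family = as.character(family)),
    class = "composite_label")
  validate_label(lab)
  lab
}

validate_label <- function(lab) {
  chk <- function(x, allowed, what) {
    if (!is.na(x) && !x %in% allowed)
      stop(sprintf("invalid %s: '%s'", what, x), call. = FALSE)
  }
  chk(lab$weighting, WEIGHTINGS, "weighting")
  chk(lab$fat_suppressed, c("FS", "nFS"), "fat_suppressed")
  chk(lab$contrast, c("CE", "nCE", "undetermined"), "contrast")
  chk(lab$family, FAMILIES, "family")
  if (lab$is_other) {
    if (!is.na(lab$weighting) || !is.na(lab$fat_suppressed) ||
        !is.na(lab$contrast) || !is.na(lab$family))
      stop("an Others label carries no weighting/FS/contrast/family fields",
           call. = FALSE)
    return(invisible(lab))
  }
  if (is.na(lab$weighting))
    stop("a relevant series label requires a weighting", call. = FALSE)
  if (identical(lab$weighting, "DWI") &&
      (!is.na(lab$fat_suppressed) || !is.na(lab$contrast)))
    stop("DWI labels carry neither fat-suppression nor contrast status",
         call. = FALSE)
  if (!is.na(lab$contrast) && !identical(lab$weighting, "T1W"))
    stop("contrast status is only assessed for T1W series", call. = FALSE)
  if (lab$weighting %in% c("T1W", "T2W") && is.na(lab$fat_suppressed))
    stop("T1W/T2W labels require a fat-suppression status", call. = FALSE)
  invisible(lab)
}

#' Render the canonical label string
#'
#' Grammar: `OTHERS | DWI | (T1W|T2W)_(FS|nFS)[_(CE|nCE)]`. The family is
#' deliberately excluded; undetermined contrast is rendered without a
#' contrast suffix (callers should inspect the `contrast` field).
#'
#' @param label A [composite_label()].
#' @return A single canonical string.
#' @export
#' @examples
#' compose_label(composite_label("T2W", "FS"))
compose_label <- function(label) {
  stopifnot(inherits(label, "composite_label"))
  validate_label(label)
  if (label$is_other) return("OTHERS")
  if (label$weighting == "DWI") return("DWI")
  out <- paste(label$weighting, label$fat_suppressed, sep = "_")
  if (label$weighting == "T1W" && !is.na(label$contrast) &&
      label$contrast %in% c("CE", "nCE"))
    out <- paste(out, label$contrast, sep = "_")
  out
}

#' Parse a canonical label string
#'
#' Inverse of [compose_label()] over the eight-class space.
#'
#' @param x Canonical label string, e.g. `"T1W_FS_CE"`.
#' @param family Optional family annotation to attach.
#' @return A [composite_label()].
#' @export
parse_label <- function(x, family = NA_character_) {
  stopifnot(is.character(x), length(x) == 1)
  if (x == "OTHERS") return(composite_label(is_other = TRUE))
  if (x == "DWI") return(composite_label("DWI", family = family))
  parts <- strsplit(x, "_", fixed = TRUE)[[1]]
  if (length(parts) < 2 || !parts[1] %in% c("T1W", "T2W"))
    stop(sprintf("unparseable label '%s'", x), call. = FALSE)
  composite_label(parts[1], parts[2],
                  contrast = if (length(parts) >= 3) parts[3] else NA_character_,
                  family = family)
}

#' @export
format.composite_label <- function(x, ...) {
  s <- compose_label(x)
  if (!is.na(x$family)) s <- paste0(s, " [", x$family, "]")
  if (identical(x$contrast, "undetermined")) s <- paste0(s, " [contrast?]")
  s
}

#' @export
print.composite_label <- function(x, ...) {
  cat("<composite_label>", format(x), "\n")
  invisible(x)
}
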