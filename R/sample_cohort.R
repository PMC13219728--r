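## Synthetic cohort sampling --------------------------------------------------

UID_ROOT <- "1.2.826.0.1.3680043.9.7156"

## Draw a composite ground-truth label: 8-class label from the class mix,
## then a weighting-conditional pulse-sequence family.
sample_truth <- function(class_mix) {
  lab8 <- sample(names(class_mix), 1, prob = class_mix)
  attach_family(lab8)
}

attach_family <- function(lab8) {
  if (lab8 == "OTHERS") return(composite_label(is_other = TRUE))
  if (lab8 == "DWI") return(parse_label(lab8, family = "EP"))
  w <- substr(lab8, 1, 3)
  fam <- if (w == "T1W")
    sample(c("SE", "GR", "IR"), 1, prob = c(0.40, 0.57, 0.03))
  else
    sample(c("SE", "IR"), 1, prob = c(0.96, 0.04))
  parse_label(lab8, family = fam)
}

## Truncated geometric series-per-patient counts.
sample_patient_size <- function(spp) {
  s <- stats::rgeom(1, 1 / spp$mean) + 1L
  min(s, spp$max)
}

#' Sample a synthetic multi-vendor MR cohort
#'
#' Generates `n_series` series records grouped into patients and studies.
#' Each record carries a ground-truth [composite_label()], identifiers,
#' vendor, field strength, country, and a header tag map produced by the
#' label-conditional generation rules and then corrupted according to the
#' spec's `missingness`, `text_noise`, and `label_noise`. Identical seeds
#' give identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return List of `series_record` objects (class `series_cohort`).
#' @export
#' @examples
#' cohort <- sample_cohort(default_primage_spec(n_series = 20, seed = 1))
#' table(vapply(cohort, function(r) compose_label(r$truth), ""))
sample_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- as.integer(spec$n_series)

  sizes <- integer(0)
  while (sum(sizes) < n) sizes <- c(sizes, sample_patient_size(spec$series_per_patient))
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
  sizes <- sizes[sizes > 0]

  records <- vector("list", n)
  idx <- 0L
  for (p in seq_along(sizes)) {
    patient_id <- sprintf("P%05d", p)
    country <- sample(names(spec$country_mix), 1, prob = spec$country_mix)
    n_studies <- max(1L, min(sizes[p], 1L + stats::rpois(1, 0.7)))
    study_of <- sort(sample.int(n_studies, sizes[p], replace = TRUE))
    for (st in unique(study_of)) {
      vendor <- sample(names(spec$vendor_mix), 1, prob = spec$vendor_mix)
      field <- as.numeric(sample(names(spec$field_mix), 1,
                                 prob = spec$field_mix))
      study_uid <- paste(UID_ROOT, spec$seed, p, st, sep = ".")
      for (s in seq_len(sum(study_of == st))) {
        idx <- idx + 1L
        truth <- sample_truth(spec$class_mix)
        gen <- generate_series_tags(truth, vendor, field)
        rec <- structure(list(
          patient_id = patient_id,
          study_uid = study_uid,
          series_uid = paste(study_uid, s, sep = "."),
          tags = gen$tags,
          n_instances = as.integer(gen$n_slices * max(1L, length(gen$bvalues))),
          volumes = NULL,
          vendor = vendor,
          field_strength = field,
          country = country,
          truth = truth,
          pixel_source = if (spec$with_pixels) list(
            type = "phantom",
            seed = sample.int(.Machine$integer.max, 1),
            n_slices = gen$n_slices,
            bvalues = gen$bvalues) else NULL,
          .gen_label = truth), class = "series_record")
        records[[idx]] <- rec
      }
    }
  }
  records <- apply_corruption(records, spec$missingness, spec$text_noise,
                              spec$label_noise)
  structure(records, class = "series_cohort")
}

miss_prob <- function(tag, missingness) {
  if (length(missingness) == 1 && is.null(names(missingness)))
    return(unname(missingness))
  if (tag %in% names(missingness)) return(unname(missingness[[tag]]))
  if ("default" %in% names(missingness))
    return(unname(missingness[["default"]]))
  0
}

TEXT_TAGS <- c("SeriesDescription", "SequenceName", "ProtocolName")

#' Corrupt a cohort's headers and labels
#'
#' Applies per-tag missingness (tags are removed, never replaced by
#' placeholder strings), text garbling of the descriptive tags, and
#' ground-truth label noise. Exposed so that the same underlying cohort can
#' be compared across corruption levels.
#'
#' @param records List of `series_record`.
#' @param missingness Per-tag drop probability (scalar or named vector with
#'   optional `"default"` entry).
#' @param text_noise Probability each descriptive tag is garbled or emptied.
#' @param label_noise Probability the recorded truth label is wrong.
#' @return The corrupted record list.
#' @export
apply_corruption <- function(records, missingness = 0, text_noise = 0,
                             label_noise = 0) {
  gibberish <- function() paste(sample(letters, sample(3:8, 1), replace = TRUE),
                                collapse = "")
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (label_noise > 0 && stats::runif(1) < label_noise) {
      wrong <- sample(setdiff(label_space(), compose_label(rec$truth)), 1)
      rec$truth <- attach_family(wrong)
    }
    if (text_noise > 0) {
      for (tg in intersect(TEXT_TAGS, names(rec$tags))) {
        if (stats::runif(1) < text_noise) {
          if (stats::runif(1) < 0.5) rec$tags[[tg]] <- NULL
          else rec$tags[[tg]] <- paste(replicate(sample(1:3, 1), gibberish()),
                                       collapse = " ")
        }
      }
    }
    if (any(missingness > 0)) {
      for (tg in names(rec$tags)) {
        if (stats::runif(1) < miss_prob(tg, missingness))
          rec$tags[[tg]] <- NULL
      }
    }
    records[[i]] <- rec
  }
  records
}

#' @export
print.series_record <- function(x, ...) {
  cat("<series_record>", x$series_uid, "\n")
  cat("  patient:", x$patient_id, " vendor:", x$vendor,
      " field:", x$field_strength, "T  country:", x$country, "\n")
  if (!is.null(x$truth)) cat("  truth:", format(x$truth), "\n")
  cat("  tags:", paste(names(x$tags), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.series_cohort <- function(x, ...) {
  cat("<series_cohort>", length(x), "series,",
      length(unique(vapply(x, `[[`, "", "patient_id"))), "patients\n")
  truths <- vapply(x, function(r) compose_label(r$truth), "")
  print(table(truths))
  invisible(x)
}

#' Ground-truth canonical labels of a cohort
#' @param records List of `series_record`.
#' @return Character vector of canonical 8-class labels.
#' @export
cohort_truth <- function(records) {
  vapply(records, function(r) compose_label(r$truth), "")
}
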