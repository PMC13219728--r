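## Synthetic cohort specification ---------------------------------------------

#' Define a synthetic cohort
#'
#' A cohort spec declares the marginal composition of a synthetic multi-vendor
#' MR cohort: the composite-class mix over the eight end-to-end labels, the
#' scanner vendor mix, field-strength mix, country mix, header corruption
#' rates, and the per-patient series-count distribution.
#'
#' @param n_series Number of series to generate (>= 1).
#' @param class_mix Named probabilities over [label_space()]; must sum to 1.
#' @param vendor_mix Named probabilities over vendors.
#' @param field_mix Named probabilities over field strengths (names "1.5", "3").
#' @param country_mix Named probabilities over countries.
#' @param missingness Per-tag probability that a generated tag is dropped.
#'   Either a single number applied to all corruptible tags, or a named vector
#'   with an optional `"default"` entry plus per-tag overrides.
#' @param text_noise Probability that each descriptive text tag (Series
#'   Description, Sequence Name, Protocol Name) is garbled or emptied.
#' @param label_noise Probability that the recorded ground-truth label is
#'   replaced by a different class (annotation error).
#' @param series_per_patient List with `mean` and `max` of the truncated
#'   geometric distribution of series per patient.
#' @param with_pixels Logical; attach renderable phantom pixel data.
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @return An object of class `cohort_spec`.
#' @seealso [default_primage_spec()], [sample_cohort()]
#' @export
cohort_spec <- function(n_series,
                        class_mix,
                        vendor_mix,
                        field_mix,
                        country_mix,
                        missingness = 0,
                        text_noise = 0,
                        label_noise = 0,
                        series_per_patient = list(mean = 15, max = 60),
                        with_pixels = FALSE,
                        seed = 1L) {
  spec <- structure(
    list(n_series = n_series, class_mix = class_mix, vendor_mix = vendor_mix,
         field_mix = field_mix, country_mix = country_mix,
         missingness = missingness, text_noise = text_noise,
         label_noise = label_noise, series_per_patient = series_per_patient,
         with_pixels = isTRUE(with_pixels), seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (!is.numeric(spec$n_series) || length(spec$n_series) != 1 ||
      is.na(spec$n_series) || spec$n_series < 1)
    stop("invalid cohort spec: n_series must be a positive integer",
         call. = FALSE)
  for (nm in c("class_mix", "vendor_mix", "field_mix", "country_mix")) {
    mx <- spec[[nm]]
    if (is.null(names(mx)) || any(!nzchar(names(mx))))
      stop(sprintf("invalid cohort spec: %s must be a named vector", nm),
           call. = FALSE)
    if (any(mx < 0) || any(mx > 1))
      stop(sprintf("invalid cohort spec: %s probabilities must lie in [0, 1]",
                   nm), call. = FALSE)
    if (abs(sum(mx) - 1) > 1e-9)
      stop(sprintf("invalid cohort spec: %s must sum to 1 (got %.12f)",
                   nm, sum(mx)), call. = FALSE)
  }
  if (!all(names(spec$class_mix) %in% label_space()))
    stop("invalid cohort spec: class_mix names must come from label_space()",
         call. = FALSE)
  for (nm in c("text_noise", "label_noise")) {
    p <- spec[[nm]]
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
      stop(sprintf("invalid cohort spec: %s must be a probability", nm),
           call. = FALSE)
  }
  if (any(spec$missingness < 0) || any(spec$missingness > 1))
    stop("invalid cohort spec: missingness probabilities must lie in [0, 1]",
         call. = FALSE)
  spp <- spec$series_per_patient
  if (!is.list(spp) || is.null(spp$mean) || spp$mean < 1 ||
      is.null(spp$max) || spp$max < 1)
    stop("invalid cohort spec: series_per_patient needs mean >= 1 and max >= 1",
         call. = FALSE)
  invisible(spec)
}

## Published cohort composition (series counts per category).
PRIMAGE_COUNTS <- list(
  total = 18181, others = 1310, analysed = 16871,
  t1w = 9489, t2w = 5832, dwi = 1550,
  fs = 8249, nfs = 7072,           # within T1W + T2W (15,321)
  ce = 7272, nce = 2217,           # within T1W
  family = c(SE = 7637, GR = 6647, IR = 425, EP = 761),
  vendors = c(SIEMENS = 10734, PHILIPS = 4182, GE = 3162, TOSHIBA = 103),
  field = c("1.5" = 2745, "3" = 894),
  countries = c(Austria = 958, Spain = 706, Italy = 30,
                Lithuania = 40, Romania = 21, Germany = 1884))

primage_class_mix <- function() {
  k <- PRIMAGE_COUNTS
  p_other <- k$others / k$total
  p_w <- c(T1W = k$t1w, T2W = k$t2w, DWI = k$dwi) / k$total
  p_fs <- k$fs / (k$fs + k$nfs)       # FS rate within T1W/T2W
  p_ce <- k$ce / (k$ce + k$nce)       # CE rate within T1W
  mix <- c(
    DWI         = unname(p_w["DWI"]),
    OTHERS      = p_other,
    T1W_nFS_nCE = unname(p_w["T1W"] * (1 - p_fs) * (1 - p_ce)),
    T1W_nFS_CE  = unname(p_w["T1W"] * (1 - p_fs) * p_ce),
    T1W_FS_nCE  = unname(p_w["T1W"] * p_fs * (1 - p_ce)),
    T1W_FS_CE   = unname(p_w["T1W"] * p_fs * p_ce),
    T2W_nFS     = unname(p_w["T2W"] * (1 - p_fs)),
    T2W_FS      = unname(p_w["T2W"] * p_fs))
  mix / sum(mix)
}

#' Default cohort spec emulating the PRIMAGE repository composition
#'
#' Class, vendor, field-strength, and country mixes are taken from the
#' published composition of the PRIMAGE neuroblastoma repository (18,181 MR
#' series): Others 1,310/18,181; within the analysed series T1W 9,489,
#' T2W 5,832, DWI 1,550; fat suppression 8,249 vs 7,072 within T1W/T2W;
#' contrast 7,272 vs 2,217 within T1W; vendors Siemens 10,734 / Philips 4,182 /
#' GE 3,162 / Toshiba 103; field strength and country from the test-set
#' breakdown (2,745 at 1.5 T vs 894 at 3 T).
#'
#' Default corruption rates emulate realistic header quality (mild tag
#' missingness, heavier dropout of Sequence Name / Protocol Name, occasional
#' garbled text, 1% annotation noise). Pass zeros for a clean cohort.
#'
#' @param n_series Number of series (default 2000).
#' @param seed Integer seed.
#' @param missingness,text_noise,label_noise Override corruption rates.
#' @param with_pixels Attach phantom pixel data.
#' @return A [cohort_spec()].
#' @export
#' @examples
#' spec <- default_primage_spec(n_series = 50, seed = 1)
#' round(spec$class_mix, 3)
default_primage_spec <- function(n_series = 2000, seed = 1L,
                                 missingness = c(default = 0.05,
                                                 SequenceName = 0.30,
                                                 ProtocolName = 0.20),
                                 text_noise = 0.05,
                                 label_noise = 0.01,
                                 with_pixels = FALSE) {
  k <- PRIMAGE_COUNTS
  cohort_spec(
    n_series = n_series,
    class_mix = primage_class_mix(),
    vendor_mix = k$vendors / sum(k$vendors),
    field_mix = k$field / sum(k$field),
    country_mix = k$countries / sum(k$countries),
    missingness = missingness, text_noise = text_noise,
    label_noise = label_noise,
    series_per_patient = list(mean = 15, max = 60),
    with_pixels = with_pixels, seed = seed)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_series, "series, seed", x$seed, "\n")
  cat("  class_mix:", paste(sprintf("%s=%.3f", names(x$class_mix),
                                    x$class_mix), collapse = " "), "\n")
  cat("  vendors:", paste(sprintf("%s=%.3f", names(x$vendor_mix),
                                  x$vendor_mix), collapse = " "), "\n")
  cat("  corruption: missingness",
      paste(sprintf("%s=%.2f", names(x$missingness), x$missingness),
            collapse = " "),
      "text_noise", x$text_noise, "label_noise", x$label_noise, "\n")
  invisible(x)
}
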