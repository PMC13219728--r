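## Label-conditional header generation rules ----------------------------------
##
## The generator emulates the header heterogeneity of a real multi-vendor
## paediatric MR repository: label-conditional acquisition-physics ranges
## (textbook values chosen so that labels are recoverable from headers),
## four vendor dialects for the descriptive text tags, and redundant
## encoding of fat suppression and contrast in flags and keywords.

VENDOR_DIALECTS <- list(
  SIEMENS = list(manufacturer = "SIEMENS",
                 models = c("Avanto", "Aera", "Skyra"),
                 sep = "_", tse = "tse", gre = "vibe",
                 fs_words = c("fs", "spair"), ce_words = c("+c", "km"),
                 has_seqname = TRUE, p_protocol = 0.7),
  PHILIPS = list(manufacturer = "Philips Medical Systems",
                 models = c("Achieva", "Ingenia"),
                 sep = " ", tse = "TSE", gre = "THRIVE",
                 fs_words = c("SPIR", "SPAIR"), ce_words = c("gd", "post"),
                 has_seqname = FALSE, p_protocol = 0.9),
  GE      = list(manufacturer = "GE MEDICAL SYSTEMS",
                 models = c("SIGNA HDxt", "Optima MR450w"),
                 sep = " ", tse = "FSE", gre = "LAVA",
                 fs_words = c("fatsat", "FS"), ce_words = c("+C", "GAD"),
                 has_seqname = FALSE, p_protocol = 0.9),
  TOSHIBA = list(manufacturer = "TOSHIBA_MEC",
                 models = c("Vantage Titan"),
                 sep = "_", tse = "fse", gre = "ffe",
                 fs_words = c("fs"), ce_words = c("post"),
                 has_seqname = TRUE, p_protocol = 0.5))

ORIENTATIONS <- c("tra", "sag", "cor", "ax")

runif1 <- function(lo, hi) stats::runif(1, lo, hi)

## Build a vendor-dialect series description from tokens.
make_description <- function(tokens, dialect) {
  tokens <- tokens[nzchar(tokens)]
  paste(tokens, collapse = dialect$sep)
}

## Sample the acquisition-physics tags for one relevant series.
## Ranges are disjoint across labels so that a rule classifier inverting
## them recovers the label exactly on uncorrupted headers.
physics_for <- function(weighting, family) {
  if (weighting == "DWI")
    return(list(tr = runif1(3000, 8000), te = runif1(60, 100),
                ti = NULL, flip = 90, etl = round(runif1(40, 80)),
                ss = c("SE", "EP"), acq = "2D"))
  if (weighting == "T1W") {
    switch(family,
      SE = list(tr = runif1(400, 800), te = runif1(8, 20), ti = NULL,
                flip = runif1(70, 90), etl = round(runif1(1, 4)),
                ss = "SE", acq = "2D"),
      GR = list(tr = runif1(100, 400), te = runif1(2, 10), ti = NULL,
                flip = runif1(10, 35), etl = 1, ss = "GR", acq = "3D"),
      IR = list(tr = runif1(1500, 2500), te = runif1(2, 5),
                ti = runif1(800, 1200), flip = runif1(8, 15), etl = 1,
                ss = c("GR", "IR"), acq = "3D"),
      stop("no T1W rule for family ", family))
  } else {
    switch(family,
      SE = list(tr = runif1(2000, 6000), te = runif1(80, 120), ti = NULL,
                flip = 90, etl = round(runif1(12, 32)), ss = "SE",
                acq = "2D"),
      IR = list(tr = runif1(6000, 10000), te = runif1(80, 120),
                ti = runif1(1800, 2800), flip = 90,
                etl = round(runif1(12, 32)), ss = c("SE", "IR"),
                acq = "2D"),
      stop("no T2W rule for family ", family))
  }
}

## Non-diagnostic ("Others") sub-types with their own signatures.
OTHERS_SUBTYPES <- c("localizer", "adc_map", "screenshot", "resp_curve",
                     "swi", "pd", "perfusion")

others_tags <- function(dialect) {
  sub <- sample(OTHERS_SUBTYPES, 1,
                prob = c(0.35, 0.2, 0.1, 0.05, 0.1, 0.1, 0.1))
  ori <- sample(ORIENTATIONS, 1)
  t <- switch(sub,
    localizer = list(
      desc = make_description(c(sample(c("localizer", "scout", "survey"), 1),
                                ori), dialect),
      image_type = c("ORIGINAL", "PRIMARY", "LOCALIZER"),
      tr = runif1(5, 20), te = runif1(1, 5), flip = runif1(15, 30),
      ss = "GR", n_slices = 3),
    adc_map = list(
      desc = make_description(c(sample(c("adc", "trace adc", "dwi adc"), 1)),
                              dialect),
      image_type = c("DERIVED", "SECONDARY"),
      tr = runif1(3000, 8000), te = runif1(60, 100), flip = 90,
      ss = c("SE", "EP"), n_slices = round(runif1(10, 24))),
    screenshot = list(
      desc = make_description("screenshot", dialect),
      image_type = c("DERIVED", "SECONDARY", "SCREEN SAVE"),
      tr = NULL, te = NULL, flip = NULL, ss = NULL, n_slices = 1),
    resp_curve = list(
      desc = make_description(c("resp", "curve"), dialect),
      image_type = c("ORIGINAL", "PRIMARY", "OTHER"),
      tr = NULL, te = NULL, flip = NULL, ss = NULL, n_slices = 1),
    swi = list(
      desc = make_description(c("swi", ori), dialect),
      image_type = c("ORIGINAL", "PRIMARY"),
      tr = runif1(25, 50), te = runif1(20, 40), flip = runif1(10, 20),
      ss = "GR", n_slices = round(runif1(20, 40))),
    pd = list(
      desc = make_description(c("pd", dialect$tse, ori), dialect),
      image_type = c("ORIGINAL", "PRIMARY"),
      tr = runif1(2000, 4000), te = runif1(15, 30), flip = 90,
      ss = "SE", n_slices = round(runif1(10, 24))),
    perfusion = list(
      desc = make_description(c(sample(c("perf", "dsc"), 1), ori), dialect),
      image_type = c("ORIGINAL", "PRIMARY"),
      tr = runif1(1000, 2000), te = runif1(30, 50), flip = runif1(60, 90),
      ss = c("GR", "EP"), n_slices = round(runif1(20, 40)))
  )
  t$subtype <- sub
  t
}

#' Generate the header tag map for one synthetic series
#'
#' Deterministic given the RNG state: label-conditional acquisition ranges,
#' vendor-dialect descriptive text, redundant fat-suppression encoding
#' (Scan Options flag and description keyword, with at least one guaranteed),
#' and partially filled Contrast Bolus Agent (40% fill-in even for enhanced
#' series, with the description keyword guaranteed when the agent tag is
#' absent).
#'
#' @param truth A [composite_label()] (ground truth for the series).
#' @param vendor One of `"SIEMENS"`, `"PHILIPS"`, `"GE"`, `"TOSHIBA"`.
#' @param field Field strength in tesla (1.5 or 3).
#' @return List with `tags` (named list of raw tag values), `n_slices`,
#'   and `bvalues` (non-NULL for DWI).
#' @keywords internal
generate_series_tags <- function(truth, vendor, field) {
  dialect <- VENDOR_DIALECTS[[vendor]]
  if (is.null(dialect)) stop("unknown vendor: ", vendor)
  tags <- list(
    Manufacturer = dialect$manufacturer,
    ManufacturerModelName = sample(dialect$models, 1),
    MagneticFieldStrength = field,
    PhotometricInterpretation = "MONOCHROME2",
    Rows = sample(c(256, 320, 384, 512), 1),
    Columns = sample(c(256, 320, 384, 512), 1),
    PixelSpacing = round(runif1(0.4, 1.5), 3),
    SliceThickness = round(runif1(3, 6), 1),
    SpacingBetweenSlices = round(runif1(3, 7), 1),
    NumberOfAverages = sample(1:4, 1),
    PixelBandwidth = round(runif1(100, 500)))
  bvalues <- NULL

  if (truth$is_other) {
    ot <- others_tags(dialect)
    tags$SeriesDescription <- ot$desc
    tags$ImageType <- ot$image_type
    if (!is.null(ot$tr)) tags$RepetitionTime <- round(ot$tr, 2)
    if (!is.null(ot$te)) tags$EchoTime <- round(ot$te, 2)
    if (!is.null(ot$flip)) tags$FlipAngle <- round(ot$flip, 1)
    if (!is.null(ot$ss)) tags$ScanningSequence <- ot$ss
    tags$MRAcquisitionType <- "2D"
    n_slices <- ot$n_slices
  } else {
    ph <- physics_for(truth$weighting, truth$family)
    tags$RepetitionTime <- round(ph$tr, 2)
    tags$EchoTime <- round(ph$te, 2)
    if (!is.null(ph$ti)) tags$InversionTime <- round(ph$ti, 2)
    tags$FlipAngle <- round(ph$flip, 1)
    tags$EchoTrainLength <- ph$etl
    tags$MRAcquisitionType <- ph$acq
    tags$ImageType <- c("ORIGINAL", "PRIMARY")
    ## occasional vendor quirk: Scanning Sequence carries no usable code
    tags$ScanningSequence <-
      if (vendor %in% c("TOSHIBA", "GE") && stats::runif(1) < 0.05)
        "Mode Research" else ph$ss
    tags$SequenceVariant <- switch(truth$family,
      SE = "NONE", GR = c("SP", "OSP"), IR = c("SK", "MP"), EP = "SK")
    ori <- sample(ORIENTATIONS, 1)
    fs <- identical(truth$fat_suppressed, "FS")
    ce <- identical(truth$contrast, "CE")

    ## fat suppression: Scan Options flag and/or description keyword;
    ## at least one present on uncorrupted headers
    fs_flag <- fs && stats::runif(1) < 0.85
    fs_word <- fs && (!fs_flag || stats::runif(1) < 0.9)
    opts <- character(0)
    if (stats::runif(1) < 0.3) opts <- c(opts, "PFP")
    if (fs_flag) opts <- c(opts, if (vendor == "PHILIPS") "SPIR" else "FS")
    if (length(opts)) tags$ScanOptions <- opts

    ## contrast: bolus-agent tag filled only 40% of the time even when
    ## enhanced; the description keyword covers the remainder
    ce_tag <- ce && stats::runif(1) < 0.4
    ce_word <- ce && (!ce_tag || stats::runif(1) < 0.85)
    if (ce_tag)
      tags$ContrastBolusAgent <- sample(c("GADOVIST", "DOTAREM", "MAGNEVIST",
                                          "15 ML GADOVIST"), 1)

    wtok <- switch(truth$weighting, T1W = "t1", T2W = "t2", DWI = "dwi")
    if (truth$weighting == "DWI") {
      bhigh <- sample(seq(800, 1000, by = 50), 1)
      bvalues <- c(0, bhigh)
      tags$DiffusionBValue <- bvalues
      tags$SeriesDescription <- make_description(
        c(sample(c("ep2d diff", "dwi", "diff"), 1),
          paste0("b", bhigh), ori), dialect)
    } else {
      tech <- switch(truth$family, SE = dialect$tse, GR = dialect$gre,
                     IR = if (truth$weighting == "T2W") "flair" else "mprage")
      tags$SeriesDescription <- make_description(
        c(wtok, tech, ori,
          if (fs_word) sample(dialect$fs_words, 1) else "",
          if (ce_word) sample(dialect$ce_words, 1) else ""), dialect)
    }
    if (dialect$has_seqname)
      tags$SequenceName <- paste0("*", tolower(truth$family),
                                  sample(1:3, 1), "d1_", tags$EchoTrainLength)
    if (stats::runif(1) < dialect$p_protocol)
      tags$ProtocolName <- toupper(tags$SeriesDescription)
    n_slices <- round(runif1(8, 30))
  }
  list(tags = tags, n_slices = n_slices, bvalues = bvalues)
}

## Rule-based oracle ----------------------------------------------------------

OTHERS_IMAGETYPE_MARKERS <- c("LOCALIZER", "SECONDARY", "DERIVED",
                              "SCREEN", "OTHER")
OTHERS_DESC_RE <- paste0(
  "\\b(loc|localizer|localiser|scout|survey|smartbrain|cal|calibration|",
  "screenshot|screen|resp|curve|adc|trace|map|mpr|sub|swi|pd|perf|dsc)\\b")
FS_DESC_RE <- "\\b(fs|fatsat|spair|spir|stir)\\b"
CE_DESC_RE <- "\\b(c|gd|km|post|gad)\\b"

#' Rule-based classifier inverting the header generation rules
#'
#' A hand-written deterministic classifier that recovers the composite label
#' from header tags alone. On an uncorrupted synthetic cohort it recovers
#' 100% of labels, which certifies that the generator's headers carry the
#' label signal before any learning experiment is interpreted. It is also a
#' useful fallback baseline on corrupted headers.
#'
#' @param record A `series_record`.
#' @return A [composite_label()].
#' @export
rule_classify <- function(record) {
  tags <- record$tags
  txt <- normalize_text(paste(
    if (is.null(tags$SeriesDescription)) "" else tags$SeriesDescription,
    if (is.null(tags$SequenceName)) "" else tags$SequenceName,
    if (is.null(tags$ProtocolName)) "" else tags$ProtocolName))
  it <- toupper(paste(unlist(tags$ImageType), collapse = " "))
  is_other <- any(vapply(OTHERS_IMAGETYPE_MARKERS,
                         function(m) grepl(m, it, fixed = TRUE), logical(1))) ||
    grepl(OTHERS_DESC_RE, txt)
  if (is_other) return(composite_label(is_other = TRUE))

  ss <- toupper(unlist(tags$ScanningSequence))
  bmax <- suppressWarnings(max(as.numeric(unlist(tags$DiffusionBValue)), -Inf))
  is_dwi <- (is.finite(bmax) && bmax >= 50) ||
    ("EP" %in% ss && grepl("\\b(diff|dwi)\\b", txt))
  te <- suppressWarnings(as.numeric(tags$EchoTime)[1])
  ti <- suppressWarnings(as.numeric(tags$InversionTime)[1])
  flip <- suppressWarnings(as.numeric(tags$FlipAngle)[1])
  tr <- suppressWarnings(as.numeric(tags$RepetitionTime)[1])

  weighting <- if (is_dwi) "DWI" else if (!is.na(te) && te >= 50) "T2W"
    else if (!is.na(te)) "T1W"
    else if (grepl("\\bt2\\b", txt)) "T2W" else "T1W"

  family <- if (weighting == "DWI") "EP"
    else if (!is.na(ti) && length(ti)) "IR"
    else if (!is.na(flip) && flip < 50 && weighting == "T1W") "GR"
    else "SE"

  if (weighting == "DWI")
    return(composite_label("DWI", family = family))

  opts <- toupper(unlist(tags$ScanOptions))
  fs <- any(c("FS", "SPIR", "SPAIR") %in% opts) || grepl(FS_DESC_RE, txt)
  lab_fs <- if (fs) "FS" else "nFS"
  if (weighting == "T2W")
    return(composite_label("T2W", lab_fs, family = family))
  ce <- !is.null(tags$ContrastBolusAgent) || grepl(CE_DESC_RE, txt)
  composite_label("T1W", lab_fs, if (ce) "CE" else "nCE", family = family)
}
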