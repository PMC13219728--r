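## DICOM tree ingestion and per-series tag extraction -------------------------

#' Default tag extraction schema
#'
#' The acquisition-physics and descriptive tags the five classification
#' targets depend on. Kinds drive both the per-instance-to-per-series
#' reduction rule and the feature encoding: `numeric` (median if constant
#' within tolerance, else sorted-unique joined), `categorical` (single code),
#' `multi_valued` (joined code list), `text` (free text; feeds the
#' preliminary text classifier, encoded as a presence indicator).
#'
#' @return Data frame with columns `name`, `group`, `element`, `kind`.
#' @export
default_tag_schema <- function() {
  kinds <- c(
    ScanningSequence = "multi_valued", SequenceVariant = "multi_valued",
    ScanOptions = "multi_valued", MRAcquisitionType = "categorical",
    RepetitionTime = "numeric", EchoTime = "numeric",
    InversionTime = "numeric", FlipAngle = "numeric",
    EchoTrainLength = "numeric", NumberOfAverages = "numeric",
    PixelBandwidth = "numeric", SliceThickness = "numeric",
    SpacingBetweenSlices = "numeric", PixelSpacing = "numeric",
    Rows = "numeric", Columns = "numeric",
    MagneticFieldStrength = "numeric",
    Manufacturer = "categorical", ManufacturerModelName = "categorical",
    ContrastBolusAgent = "text", DiffusionBValue = "multi_valued",
    ImageType = "multi_valued", PhotometricInterpretation = "categorical",
    SeriesDescription = "text", SequenceName = "text", ProtocolName = "text")
  d <- DICOM_DICT[match(names(kinds), DICOM_DICT$name), ]
  data.frame(name = names(kinds), group = d$group, element = d$element,
             kind = unname(kinds), stringsAsFactors = FALSE)
}

## Reduce per-instance values of one tag to a series-level value.
reduce_tag <- function(values, kind) {
  values <- values[!vapply(values, is.null, logical(1))]
  if (!length(values)) return(NULL)
  if (kind == "numeric") {
    vs <- suppressWarnings(as.numeric(unlist(values)))
    vs <- vs[!is.na(vs)]
    if (!length(vs)) return(NULL)
    if (max(vs) - min(vs) <= 1e-6 * max(1, abs(stats::median(vs))))
      return(stats::median(vs))
    return(paste(sort(unique(vs)), collapse = "|"))
  }
  if (kind %in% c("categorical", "multi_valued")) {
    if (kind == "multi_valued") {
      parts <- unique(unlist(lapply(values, as.character)))
      parts <- parts[nzchar(parts)]
      if (!length(parts)) return(NULL)
      ## numeric code lists (e.g. b-values) sort numerically
      nums <- suppressWarnings(as.numeric(parts))
      if (!anyNA(nums)) parts <- as.character(sort(nums))
      return(paste(parts, collapse = "|"))
    }
    for (v in values) {
      s <- paste(as.character(v), collapse = "|")
      if (nzchar(s)) return(s)
    }
    return(NULL)
  }
  ## text: first non-empty
  for (v in values) {
    s <- paste(as.character(v), collapse = " ")
    if (nzchar(trimws(s))) return(s)
  }
  NULL
}

#' Extract the schema tag row for one series
#'
#' Reduces per-instance tag values to one value per schema tag. Absent tags
#' stay absent (`NULL` in the returned list); missingness is data here, not
#' an error.
#'
#' @param record A `series_record` (in-memory or scanned).
#' @param schema A tag schema, see [default_tag_schema()].
#' @return Named list with one entry per schema tag (absent tags `NULL`).
#' @export
extract_tags <- function(record, schema = default_tag_schema()) {
  out <- stats::setNames(vector("list", nrow(schema)), schema$name)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    values <- if (!is.null(record$instances)) {
      lapply(record$instances, function(inst) inst$tags[[nm]])
    } else {
      list(record$tags[[nm]])
    }
    out[[nm]] <- reduce_tag(values, schema$kind[i])
  }
  out
}

## Parse a reduced numeric cell that may be a joined multi-value string.
parse_numeric_cell <- function(x) {
  if (is.null(x) || (length(x) == 1 && is.na(x))) return(NA_real_)
  v <- suppressWarnings(as.numeric(x))
  if (!is.na(v)) return(v)
  parts <- suppressWarnings(as.numeric(strsplit(as.character(x), "|",
                                                fixed = TRUE)[[1]]))
  if (all(is.na(parts))) return(NA_real_)
  stats::median(parts, na.rm = TRUE)
}

#' Tabulate raw tag rows for a cohort
#'
#' One row per series, one column per schema tag; numeric-kind columns are
#' numeric (a non-constant joined value is reduced to the median of its
#' parts), all others character. Missing values are `NA`. Row names are
#' series UIDs.
#'
#' @inheritParams extract_tags
#' @param records List of `series_record`.
#' @return A data frame.
#' @export
rows_from_records <- function(records, schema = default_tag_schema()) {
  cells <- lapply(records, extract_tags, schema = schema)
  cols <- stats::setNames(vector("list", nrow(schema)), schema$name)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    vals <- lapply(cells, `[[`, nm)
    if (schema$kind[i] == "numeric") {
      cols[[nm]] <- vapply(vals, parse_numeric_cell, numeric(1))
    } else {
      cols[[nm]] <- vapply(vals, function(v) {
        if (is.null(v)) NA_character_ else paste(as.character(v),
                                                 collapse = "|")
      }, character(1))
    }
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  rownames(df) <- vapply(records, `[[`, "", "series_uid")
  df
}

## Cohort writer --------------------------------------------------------------

quantize16 <- function(img, max_val = 4095) {
  rng <- range(img)
  if (diff(rng) <= 0) return(matrix(0L, nrow(img), ncol(img)))
  round((img - rng[1]) / diff(rng) * max_val)
}

#' Write a cohort to a DICOM directory tree
#'
#' One file per slice; multi-volume series (e.g. multi-b-value diffusion)
#' share a Series Instance UID with distinct per-volume tag values and
#' consecutive Instance Numbers; slice position is encoded in Image Position
#' (Patient). Tags absent from a record are absent from the files. Ground
#' truth and country are stored in a private group so that a round trip
#' through [scan_directory()] recovers them.
#'
#' @param records List of `series_record` from [sample_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Number of files written, invisibly.
#' @export
write_dicom <- function(records, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  n_files <- 0L
  for (rec in records) {
    ps <- rec$pixel_source
    with_pixels <- !is.null(ps) && identical(ps$type, "phantom")
    bvols <- if (with_pixels && length(ps$bvalues)) ps$bvalues else NA
    n_slices <- if (with_pixels) ps$n_slices else 1L
    base <- rec$tags
    base$PatientID <- rec$patient_id
    base$PatientName <- rec$patient_id
    base$StudyInstanceUID <- rec$study_uid
    base$SeriesInstanceUID <- rec$series_uid
    base$StudyDate <- "20240101"
    base$ImageOrientationPatient <- c(1, 0, 0, 0, 1, 0)
    if (!is.null(rec$truth))
      base$TruthLabel <- paste(compose_label(rec$truth),
                               ifelse(is.na(rec$truth$family), "",
                                      rec$truth$family), sep = "|")
    if (!is.null(rec$country)) base$Country <- rec$country
    gen_label <- if (!is.null(rec$.gen_label)) rec$.gen_label else rec$truth
    inst_no <- 0L
    for (vi in seq_along(bvols)) {
      for (j in seq_len(n_slices)) {
        inst_no <- inst_no + 1L
        el <- base
        el$SOPInstanceUID <- paste(rec$series_uid, vi, j, sep = ".")
        el$InstanceNumber <- inst_no
        thick <- if (!is.null(el$SliceThickness)) el$SliceThickness else 5
        el$ImagePositionPatient <- c(0, 0, (j - 1) * thick)
        if (!is.na(bvols[vi])) el$DiffusionBValue <- bvols[vi]
        px <- NULL
        if (with_pixels) {
          sd_seed <- (ps$seed + 131 * vi + j) %% .Machine$integer.max
          img <- if (gen_label$is_other)
            render_other_image(seed = sd_seed, size = 128L)
          else
            render_phantom(gen_label, vendor = rec$vendor, seed = sd_seed,
                           size = 128L,
                           slice_frac = if (n_slices > 1)
                             (2 * j - n_slices - 1) / n_slices else 0)
          px <- quantize16(img)
        }
        dcm_write(file.path(out_dir, paste0(el$SOPInstanceUID, ".dcm")),
                  el, pixels = px)
        n_files <- n_files + 1L
      }
    }
  }
  invisible(n_files)
}

## Directory scanner ----------------------------------------------------------

#' Scan a directory tree into series records
#'
#' Every readable DICOM instance is assigned to exactly one series record
#' keyed by Series Instance UID; unreadable files are skipped with a warning.
#' Records are returned in deterministic order (study UID, then series UID),
#' independent of file order on disk.
#'
#' @param root Directory to scan recursively.
#' @return List of `series_record` (class `series_cohort`).
#' @export
scan_directory <- function(root) {
  if (!dir.exists(root)) stop("path does not exist: ", root, call. = FALSE)
  files <- list.files(root, recursive = TRUE, full.names = TRUE)
  insts <- list()
  for (f in files) {
    parsed <- tryCatch(dcm_read(f), error = function(e) {
      warning("skipping unreadable file ", f, ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(parsed)) next
    uid <- parsed$tags$SeriesInstanceUID
    if (is.null(uid)) next
    insts[[length(insts) + 1L]] <-
      list(file = f, tags = parsed$tags, has_pixels = parsed$has_pixels)
  }
  if (!length(insts)) return(structure(list(), class = "series_cohort"))
  uids <- vapply(insts, function(x) x$tags$SeriesInstanceUID[1], "")
  records <- lapply(split(insts, uids), build_scanned_record)
  key <- vapply(records, function(r) paste(r$study_uid, r$series_uid), "")
  structure(unname(records[order(key)]), class = "series_cohort")
}

build_scanned_record <- function(instances) {
  schema <- default_tag_schema()
  t1 <- instances[[1]]$tags
  first <- function(nm) {
    for (inst in instances) if (!is.null(inst$tags[[nm]]))
      return(inst$tags[[nm]][1])
    NULL
  }
  truth <- NULL
  tl <- first("TruthLabel")
  if (!is.null(tl)) {
    parts <- strsplit(tl, "|", fixed = TRUE)[[1]]
    fam <- if (length(parts) >= 2 && nzchar(parts[2])) parts[2]
           else NA_character_
    truth <- parse_label(parts[1],
                         family = if (parts[1] == "OTHERS") NA_character_
                                  else fam)
  }
  rec <- structure(list(
    patient_id = first("PatientID"),
    study_uid = first("StudyInstanceUID"),
    series_uid = first("SeriesInstanceUID"),
    tags = list(), n_instances = length(instances),
    volumes = NULL,
    vendor = vendor_from_manufacturer(first("Manufacturer")),
    field_strength = {
      f <- first("MagneticFieldStrength")
      if (is.null(f)) NA_real_ else as.numeric(f)
    },
    country = {
      cn <- first("Country")
      if (is.null(cn)) NA_character_ else cn
    },
    truth = truth,
    instances = instances,
    pixel_source = if (any(vapply(instances, `[[`, logical(1), "has_pixels")))
      list(type = "files") else NULL,
    .gen_label = truth), class = "series_record")
  rec$tags <- extract_tags_raw(instances, schema)
  if (!is.null(rec$pixel_source))
    rec$volumes <- split_volumes(rec)
  rec
}

## Series-level raw tag map for scanned records: reduction per kind but
## keeping native types (vectors for multi-valued codes).
extract_tags_raw <- function(instances, schema) {
  tags <- list()
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    values <- lapply(instances, function(inst) inst$tags[[nm]])
    values <- values[!vapply(values, is.null, logical(1))]
    if (!length(values)) next
    if (schema$kind[i] %in% c("multi_valued", "categorical")) {
      parts <- unique(unlist(values))
      tags[[nm]] <- parts
    } else {
      red <- reduce_tag(values, schema$kind[i])
      if (!is.null(red)) tags[[nm]] <- red
    }
  }
  tags
}

vendor_from_manufacturer <- function(m) {
  if (is.null(m) || !nzchar(m)) return(NA_character_)
  mu <- toupper(m)
  if (grepl("SIEMENS", mu)) "SIEMENS"
  else if (grepl("PHILIPS", mu)) "PHILIPS"
  else if (grepl("GE ", mu) || grepl("^GE", mu)) "GE"
  else if (grepl("TOSHIBA|CANON", mu)) "TOSHIBA"
  else mu
}

## Volume splitting -----------------------------------------------------------

DERIVED_IMAGETYPE_RE <- "DERIVED|SUBTRACT|PROJECTION|MPR|SCREEN|SECONDARY"

#' Split a series into volumes
#'
#' Partitions the instances of a series by, in precedence order: image-type
#' class (original vs derived/secondary), diffusion b-value, echo time, and
#' temporal position. Within each volume, slices are ordered by Image
#' Position (Patient) projected on the slice normal, falling back to
#' Instance Number, so the result is invariant to file order on disk.
#'
#' @param record A scanned `series_record` with pixel data, or a synthetic
#'   record with a phantom pixel source.
#' @return List of `volume_ref` objects.
#' @export
split_volumes <- function(record) {
  ps <- record$pixel_source
  if (is.null(ps))
    stop("series ", record$series_uid,
         " has no pixel data; the contrast branch cannot run",
         call. = FALSE)
  if (identical(ps$type, "phantom")) {
    bvs <- if (length(ps$bvalues)) sort(ps$bvalues) else NA
    return(lapply(seq_along(bvs), function(i) {
      structure(list(
        n_slices = ps$n_slices, files = NULL, order = seq_len(ps$n_slices),
        image_type_class = "ORIGINAL", bvalue = bvs[i],
        echo_time = NA_real_, temporal = NA_integer_,
        discriminator = if (!is.na(bvs[i]))
          list(attribute = "bvalue", value = bvs[i]) else NULL,
        source = list(type = "phantom", seed = ps$seed, volume_index = i,
                      label = record$.gen_label, vendor = record$vendor)),
        class = "volume_ref")
    }))
  }
  instances <- record$instances
  if (is.null(instances) || !length(instances))
    stop("series ", record$series_uid, " carries no instances",
         call. = FALSE)
  num1 <- function(inst, nm) {
    v <- suppressWarnings(as.numeric(inst$tags[[nm]][1]))
    if (!length(v) || is.na(v)) NA_real_ else v
  }
  itc <- vapply(instances, function(i) {
    it <- toupper(paste(unlist(i$tags$ImageType), collapse = "\\"))
    if (grepl(DERIVED_IMAGETYPE_RE, it)) "DERIVED" else "ORIGINAL"
  }, "")
  bval <- vapply(instances, num1, numeric(1), nm = "DiffusionBValue")
  te <- vapply(instances, num1, numeric(1), nm = "EchoTime")
  tp <- vapply(instances, num1, numeric(1), nm = "TemporalPositionIdentifier")
  key <- paste(itc, bval, te, tp, sep = "/")
  groups <- split(seq_along(instances), key)
  ## deterministic volume order by the stated precedence
  ord <- order(vapply(groups, function(ix) itc[ix[1]], ""),
               vapply(groups, function(ix) bval[ix[1]], numeric(1)),
               vapply(groups, function(ix) te[ix[1]], numeric(1)),
               vapply(groups, function(ix) tp[ix[1]], numeric(1)),
               method = "radix")
  groups <- groups[ord]
  lapply(groups, function(ix) {
    sub <- instances[ix]
    pos <- vapply(sub, function(i) {
      ipp <- suppressWarnings(as.numeric(i$tags$ImagePositionPatient))
      iop <- suppressWarnings(as.numeric(i$tags$ImageOrientationPatient))
      if (length(ipp) == 3 && length(iop) == 6) {
        normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
                    iop[3] * iop[4] - iop[1] * iop[6],
                    iop[1] * iop[5] - iop[2] * iop[4])
        sum(ipp * normal)
      } else NA_real_
    }, numeric(1))
    instno <- vapply(sub, num1, numeric(1), nm = "InstanceNumber")
    o <- if (anyNA(pos)) order(instno) else order(pos, instno)
    i1 <- ix[1]
    disc <- if (!is.na(bval[i1])) list(attribute = "bvalue", value = bval[i1])
      else if (!is.na(te[i1])) list(attribute = "echo_time", value = te[i1])
      else if (!is.na(tp[i1])) list(attribute = "temporal", value = tp[i1])
      else NULL
    structure(list(
      n_slices = length(sub),
      files = vapply(sub, `[[`, "", "file")[o],
      order = o,
      image_type_class = itc[i1], bvalue = bval[i1], echo_time = te[i1],
      temporal = tp[i1], discriminator = disc,
      source = list(type = "files")), class = "volume_ref")
  })
}
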