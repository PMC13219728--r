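## Minimal DICOM codec: explicit VR little endian -----------------------------
##
## Covers exactly what this package needs: single-frame MR instances with
## uncompressed 16-bit monochrome pixel data and the acquisition tags in the
## default schema. Not a general-purpose DICOM implementation (no sequences,
## no compressed transfer syntaxes, no implicit VR).

DICOM_DICT <- local({
  d <- rbind(
    c("ImageType",                 0x0008, 0x0008, "CS"),
    c("SOPClassUID",               0x0008, 0x0016, "UI"),
    c("SOPInstanceUID",            0x0008, 0x0018, "UI"),
    c("StudyDate",                 0x0008, 0x0020, "DA"),
    c("Modality",                  0x0008, 0x0060, "CS"),
    c("Manufacturer",              0x0008, 0x0070, "LO"),
    c("SeriesDescription",         0x0008, 0x103E, "LO"),
    c("ManufacturerModelName",     0x0008, 0x1090, "LO"),
    c("PatientName",               0x0010, 0x0010, "PN"),
    c("PatientID",                 0x0010, 0x0020, "LO"),
    c("PrivateCreator",            0x0011, 0x0010, "LO"),
    c("TruthLabel",                0x0011, 0x1001, "LO"),
    c("Country",                   0x0011, 0x1002, "LO"),
    c("ContrastBolusAgent",        0x0018, 0x0010, "LO"),
    c("ScanningSequence",          0x0018, 0x0020, "CS"),
    c("SequenceVariant",           0x0018, 0x0021, "CS"),
    c("ScanOptions",               0x0018, 0x0022, "CS"),
    c("MRAcquisitionType",         0x0018, 0x0023, "CS"),
    c("SequenceName",              0x0018, 0x0024, "SH"),
    c("SliceThickness",            0x0018, 0x0050, "DS"),
    c("RepetitionTime",            0x0018, 0x0080, "DS"),
    c("EchoTime",                  0x0018, 0x0081, "DS"),
    c("InversionTime",             0x0018, 0x0082, "DS"),
    c("NumberOfAverages",          0x0018, 0x0083, "DS"),
    c("MagneticFieldStrength",     0x0018, 0x0087, "DS"),
    c("SpacingBetweenSlices",      0x0018, 0x0088, "DS"),
    c("EchoTrainLength",           0x0018, 0x0091, "IS"),
    c("PixelBandwidth",            0x0018, 0x0095, "DS"),
    c("ProtocolName",              0x0018, 0x1030, "LO"),
    c("FlipAngle",                 0x0018, 0x1314, "DS"),
    c("DiffusionBValue",           0x0018, 0x9087, "FD"),
    c("StudyInstanceUID",          0x0020, 0x000D, "UI"),
    c("SeriesInstanceUID",         0x0020, 0x000E, "UI"),
    c("InstanceNumber",            0x0020, 0x0013, "IS"),
    c("TemporalPositionIdentifier", 0x0020, 0x0100, "IS"),
    c("ImagePositionPatient",      0x0020, 0x0032, "DS"),
    c("ImageOrientationPatient",   0x0020, 0x0037, "DS"),
    c("SamplesPerPixel",           0x0028, 0x0002, "US"),
    c("PhotometricInterpretation", 0x0028, 0x0004, "CS"),
    c("Rows",                      0x0028, 0x0010, "US"),
    c("Columns",                   0x0028, 0x0011, "US"),
    c("PixelSpacing",              0x0028, 0x0030, "DS"),
    c("BitsAllocated",             0x0028, 0x0100, "US"),
    c("BitsStored",                0x0028, 0x0101, "US"),
    c("HighBit",                   0x0028, 0x0102, "US"),
    c("PixelRepresentation",       0x0028, 0x0103, "US"),
    c("PixelData",                 0x7FE0, 0x0010, "OW"))
  data.frame(name = d[, 1], group = as.integer(d[, 2]),
             element = as.integer(d[, 3]), vr = d[, 4],
             stringsAsFactors = FALSE)
})

MR_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.4"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
LONG_LEN_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

encode_value <- function(vr, value) {
  if (vr %in% c("UI", "CS", "LO", "SH", "PN", "DA", "TM", "LT")) {
    s <- paste(as.character(value), collapse = "\\")
    r <- charToRaw(s)
    if (length(r) %% 2 == 1)
      r <- c(r, if (vr == "UI") as.raw(0) else charToRaw(" "))
    r
  } else if (vr %in% c("DS", "IS")) {
    s <- paste(vapply(value, function(v)
      formatC(v, format = "fg", digits = 8, flag = "-"), ""), collapse = "\\")
    s <- gsub(" ", "", s)
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
    r
  } else if (vr == "US") {
    u16(value)
  } else if (vr == "UL") {
    u32(value)
  } else if (vr == "FD") {
    writeBin(as.numeric(value), raw(), size = 8, endian = "little")
  } else if (vr == "OB") {
    r <- as.raw(value)
    if (length(r) %% 2 == 1) r <- c(r, as.raw(0))
    r
  } else if (vr == "OW") {
    writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else stop("unsupported VR for writing: ", vr)
}

encode_element <- function(group, element, vr, value) {
  body <- encode_value(vr, value)
  head <- c(u16(group), u16(element), charToRaw(vr))
  if (vr %in% LONG_LEN_VRS) {
    c(head, raw(2), u32(length(body)), body)
  } else {
    if (length(body) > 65534) stop("value too long for short-form VR ", vr)
    c(head, u16(length(body)), body)
  }
}

#' Write one DICOM instance (explicit VR little endian)
#'
#' @param path Output file path.
#' @param elements Named list of tag values; names must exist in the
#'   internal dictionary. `NULL` entries are omitted entirely (a missing tag
#'   is absent from the file, never written as an empty string).
#' @param pixels Optional integer matrix (rows x columns) of 16-bit pixel
#'   values; Rows/Columns and the pixel-description tags are derived from it.
#' @return `path`, invisibly.
#' @keywords internal
dcm_write <- function(path, elements, pixels = NULL) {
  elements <- elements[!vapply(elements, is.null, logical(1))]
  if (is.null(elements$SOPClassUID)) elements$SOPClassUID <- MR_SOP_CLASS
  if (is.null(elements$Modality)) elements$Modality <- "MR"
  if (!is.null(pixels)) {
    pixels <- round(pixels)
    elements$SamplesPerPixel <- 1L
    if (is.null(elements$PhotometricInterpretation))
      elements$PhotometricInterpretation <- "MONOCHROME2"
    elements$Rows <- nrow(pixels)
    elements$Columns <- ncol(pixels)
    elements$BitsAllocated <- 16L
    elements$BitsStored <- 16L
    elements$HighBit <- 15L
    elements$PixelRepresentation <- 0L
    elements$PixelData <- as.integer(t(pixels))  # row-major, as stored
  }
  if (any(grepl("^Truth|^Country", names(elements))))
    elements$PrivateCreator <- "MRSERIES"

  dict <- DICOM_DICT[match(names(elements), DICOM_DICT$name), ]
  if (anyNA(dict$group))
    stop("unknown DICOM tag name(s): ",
         paste(names(elements)[is.na(dict$group)], collapse = ", "))
  ord <- order(dict$group, dict$element)

  body <- raw(0)
  for (i in ord) {
    body <- c(body, encode_element(dict$group[i], dict$element[i],
                                   dict$vr[i], elements[[i]]))
  }

  sop_uid <- if (!is.null(elements$SOPInstanceUID)) elements$SOPInstanceUID
             else paste(UID_ROOT, "0", sep = ".")
  meta <- c(
    encode_element(0x0002, 0x0001, "OB", c(0L, 1L)),
    encode_element(0x0002, 0x0002, "UI", MR_SOP_CLASS),
    encode_element(0x0002, 0x0003, "UI", sop_uid),
    encode_element(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
    encode_element(0x0002, 0x0012, "UI", UID_ROOT))
  meta <- c(encode_element(0x0002, 0x0000, "UL", length(meta)), meta)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

decode_value <- function(vr, bytes) {
  if (vr %in% c("UI", "CS", "LO", "SH", "PN", "DA", "TM", "LT", "UT")) {
    s <- rawToChar(bytes[bytes != as.raw(0)])
    s <- sub("[ ]+$", "", s)
    v <- strsplit(s, "\\", fixed = TRUE)[[1]]
    if (length(v) == 0) v <- ""
    v
  } else if (vr == "DS") {
    as.numeric(strsplit(sub("[ ]+$", "", rawToChar(bytes)), "\\",
                        fixed = TRUE)[[1]])
  } else if (vr == "IS") {
    as.integer(as.numeric(strsplit(sub("[ ]+$", "", rawToChar(bytes)), "\\",
                                   fixed = TRUE)[[1]]))
  } else if (vr == "US") {
    readBin(bytes, integer(), n = length(bytes) / 2, size = 2,
            endian = "little", signed = FALSE)
  } else if (vr == "UL") {
    readBin(bytes, integer(), n = length(bytes) / 4, size = 4,
            endian = "little")
  } else if (vr == "FD") {
    readBin(bytes, numeric(), n = length(bytes) / 8, size = 8,
            endian = "little")
  } else if (vr == "OW") {
    readBin(bytes, integer(), n = length(bytes) / 2, size = 2,
            endian = "little", signed = FALSE)
  } else {
    NULL  # unparsed VR: caller skips
  }
}

#' Read one DICOM instance
#'
#' Parses an explicit-VR little-endian file and returns the dictionary tags
#' it contains. Unknown tags are skipped. Raises an error for files without
#' the DICM magic or with a truncated element stream.
#'
#' @param path File path.
#' @param read_pixels Logical; decode PixelData into an integer matrix.
#' @return List with `tags` (named list) and `pixels` (matrix or NULL).
#' @keywords internal
dcm_read <- function(path, read_pixels = FALSE) {
  bytes <- readBin(path, raw(), file.size(path))
  if (length(bytes) < 140 ||
      !identical(rawToChar(bytes[129:132]), "DICM"))
    stop("not a DICOM file: ", path, call. = FALSE)
  pos <- 133L
  n <- length(bytes)
  tags <- list()
  pixels <- NULL
  has_pixels <- FALSE
  rows <- cols <- NA_integer_
  while (pos + 7L <= n) {
    grp <- readBin(bytes[pos:(pos + 1)], integer(), size = 2,
                   endian = "little", signed = FALSE)
    ele <- readBin(bytes[(pos + 2):(pos + 3)], integer(), size = 2,
                   endian = "little", signed = FALSE)
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported or corrupt element at byte ", pos, " in ", path,
           call. = FALSE)
    if (vr %in% LONG_LEN_VRS) {
      len <- readBin(bytes[(pos + 8):(pos + 11)], integer(), size = 4,
                     endian = "little")
      pos <- pos + 12L
    } else {
      len <- readBin(bytes[(pos + 6):(pos + 7)], integer(), size = 2,
                     endian = "little", signed = FALSE)
      pos <- pos + 8L
    }
    if (len < 0 || pos + len - 1L > n)
      stop("truncated DICOM element in ", path, call. = FALSE)
    val_bytes <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    hit <- which(DICOM_DICT$group == grp & DICOM_DICT$element == ele)
    if (!length(hit)) next
    name <- DICOM_DICT$name[hit[1]]
    if (name == "PixelData") {
      has_pixels <- TRUE
      if (read_pixels) {
        v <- decode_value("OW", val_bytes)
        if (!is.na(rows) && !is.na(cols) && length(v) == rows * cols)
          pixels <- matrix(v, nrow = rows, byrow = TRUE)
      }
      next
    }
    val <- decode_value(DICOM_DICT$vr[hit[1]], val_bytes)
    if (is.null(val)) next
    if (name == "Rows") rows <- val[1]
    if (name == "Columns") cols <- val[1]
    tags[[name]] <- val
  }
  list(tags = tags, pixels = pixels, has_pixels = has_pixels)
}
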