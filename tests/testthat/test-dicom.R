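write_fixture_cohort <- function(n = 6, seed = 5, dir_name = "dcm") {
  d <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
                 dir_name)
  cohort <- sample_cohort(default_primage_spec(
    n_series = n, seed = seed, missingness = 0, text_noise = 0,
    label_noise = 0, with_pixels = TRUE))
  n_files <- write_dicom(cohort, d)
  list(dir = d, cohort = cohort, n_files = n_files)
}

test_that("write/scan round trip preserves series, truth, and tag values", {
  fx <- write_fixture_cohort(n = 6, seed = 5)
  expect_identical(fx$n_files,
                   sum(vapply(fx$cohort, `[[`, 0L, "n_instances")))
  sc <- scan_directory(fx$dir)
  expect_length(sc, 6L)
  orig <- fx$cohort[order(vapply(fx$cohort, `[[`, "", "series_uid"))]
  resc <- sc[order(vapply(sc, `[[`, "", "series_uid"))]
  for (i in seq_along(orig)) {
    o <- orig[[i]]; r <- resc[[i]]
    expect_identical(compose_label(r$truth), compose_label(o$truth))
    expect_identical(r$truth$family, o$truth$family)
    expect_identical(r$patient_id, o$patient_id)
    expect_identical(r$country, o$country)
    expect_identical(r$vendor, o$vendor)
    for (tg in c("RepetitionTime", "EchoTime", "FlipAngle",
                 "SliceThickness")) {
      if (!is.null(o$tags[[tg]]))
        expect_equal(as.numeric(r$tags[[tg]]), as.numeric(o$tags[[tg]]),
                     tolerance = 1e-6, label = tg)
    }
    if (!is.null(o$tags$SeriesDescription))
      expect_identical(r$tags$SeriesDescription, o$tags$SeriesDescription)
  }
})

test_that("a record lacking a tag produces a file lacking that tag", {
  rec <- clean_cohort(n = 20, seed = 6)[[1]]
  rec$tags$EchoTime <- NULL
  d <- withr::local_tempdir()
  write_dicom(list(rec), d)
  f <- list.files(d, full.names = TRUE)[1]
  parsed <- dcm_read(f)
  expect_false("EchoTime" %in% names(parsed$tags))
  expect_true("RepetitionTime" %in% names(parsed$tags))
  # and the byte stream never contains the EchoTime tag (0018,0081)
  bytes <- readBin(f, raw(), file.size(f))
  expect_length(grepRaw(as.raw(c(0x18, 0x00, 0x81, 0x00)), bytes,
                        fixed = TRUE, all = TRUE), 0L)
})

test_that("a corrupt file is skipped with a warning, valid series survive", {
  fx <- write_fixture_cohort(n = 3, seed = 9)
  files <- list.files(fx$dir, full.names = TRUE)
  # truncate one file and drop a text file next to it
  f <- files[1]
  writeBin(readBin(f, raw(), 200), f)
  writeLines("not dicom", file.path(fx$dir, "notes.txt"))
  w <- capture_warnings(sc <- scan_directory(fx$dir))
  expect_length(w, 2L)                  # one per unreadable file
  expect_true(all(grepl("skipping", w)))
  expect_length(sc, 3L)  # remaining slices still carry every series
})

test_that("scanning is invariant to file order / names on disk", {
  fx <- write_fixture_cohort(n = 4, seed = 10)
  sc1 <- scan_directory(fx$dir)
  files <- list.files(fx$dir, full.names = TRUE)
  set.seed(1)
  new_names <- file.path(fx$dir, sprintf("zz%03d.dcm", sample(length(files))))
  file.rename(files, new_names)
  sc2 <- scan_directory(fx$dir)
  strip_files <- function(recs) lapply(recs, function(r) {
    r$instances <- NULL; r$volumes <- NULL; r
  })
  expect_equal(strip_files(sc1), strip_files(sc2))
})

test_that("missing path errors and an empty directory yields an empty list", {
  expect_error(scan_directory(file.path(tempdir(), "no-such-dir")),
               "does not exist")
  d <- withr::local_tempdir()
  expect_identical(length(scan_directory(d)), 0L)
})

test_that("pydicom independently parses our explicit-VR output", {
  py <- Sys.which("python")
  fx <- write_fixture_cohort(n = 2, seed = 12)
  f <- sort(list.files(fx$dir, full.names = TRUE))[1]
  script <- paste(
    "import pydicom, sys",
    "ds = pydicom.dcmread(sys.argv[1])",
    "print(ds.SeriesInstanceUID)",
    "print(float(ds.RepetitionTime) if 'RepetitionTime' in ds else 'NA')",
    "print(ds.pixel_array.shape[0])",
    sep = "\n")
  out <- system2(py, c("-c", shQuote(script), shQuote(f)), stdout = TRUE)
  parsed <- dcm_read(f, read_pixels = TRUE)
  expect_identical(out[1], parsed$tags$SeriesInstanceUID)
  if (out[2] != "NA")
    expect_equal(as.numeric(out[2]), as.numeric(parsed$tags$RepetitionTime),
                 tolerance = 1e-6)
  expect_identical(as.integer(out[3]), nrow(parsed$pixels))
})

test_that("per-instance values reduce to series-level values as specified", {
  mk <- function(tags) list(tags = tags, has_pixels = FALSE, file = "f")
  rec <- structure(list(series_uid = "s", instances = list(
    mk(list(EchoTime = 90, DiffusionBValue = 0)),
    mk(list(EchoTime = 90, DiffusionBValue = 800)),
    mk(list(EchoTime = 90))
  )), class = "series_record")
  row <- extract_tags(rec)
  expect_equal(row$EchoTime, 90)                 # constant -> median
  expect_identical(row$DiffusionBValue, "0|800") # sorted-unique joined
  expect_null(row$RepetitionTime)                # absent stays absent
})

test_that("volumes split by image type, b-value, and echo time", {
  mk <- function(i, b = NULL, it = c("ORIGINAL", "PRIMARY"), te = 90,
                 z = i) {
    list(file = paste0("f", i), has_pixels = TRUE,
         tags = list(ImageType = it, DiffusionBValue = b, EchoTime = te,
                     InstanceNumber = i,
                     ImagePositionPatient = c(0, 0, z),
                     ImageOrientationPatient = c(1, 0, 0, 0, 1, 0)))
  }
  # 20 slices, b in {0, 800}, 10 each -> 2 volumes of 10
  rec <- structure(list(series_uid = "s",
                        pixel_source = list(type = "files"),
                        instances = c(lapply(1:10, mk, b = 0),
                                      lapply(11:20, mk, b = 800))),
                   class = "series_record")
  vols <- split_volumes(rec)
  expect_length(vols, 2L)
  expect_equal(unname(vapply(vols, `[[`, 0, "n_slices")), c(10, 10))
  expect_equal(sort(unname(vapply(vols, `[[`, 0, "bvalue"))), c(0, 800))
  # single volume stays one volume
  rec1 <- structure(list(series_uid = "s", pixel_source = list(type = "files"),
                         instances = lapply(1:24, mk)),
                    class = "series_record")
  expect_length(split_volumes(rec1), 1L)
  # ORIGINAL vs DERIVED\SUBTRACTION discriminate by image type
  rec2 <- structure(list(series_uid = "s", pixel_source = list(type = "files"),
                         instances = c(lapply(1:5, mk),
                                       lapply(6:10, mk,
                                              it = c("DERIVED",
                                                     "SUBTRACTION")))),
                    class = "series_record")
  vols2 <- split_volumes(rec2)
  expect_length(vols2, 2L)
  expect_setequal(vapply(vols2, `[[`, "", "image_type_class"),
                  c("ORIGINAL", "DERIVED"))
  # no pixel data: the contrast branch cannot run
  rec3 <- structure(list(series_uid = "s", pixel_source = NULL),
                    class = "series_record")
  expect_error(split_volumes(rec3), "contrast branch")
})
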