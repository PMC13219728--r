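# A stub bundle whose module outputs are fixed per series, to isolate the
# activation logic from any learned model.
stub_bundle <- function(records, others, weighting, fatsup, family) {
  rows <- rows_from_records(records)
  enc <- fit_encoder(rows)
  uids <- vapply(records, `[[`, "", "series_uid")
  fixed <- function(x) stats::setNames(rep_len(x, length(uids)), uids)
  structure(list(
    schema = default_tag_schema(), lexicon = load_lexicon(), encoder = enc,
    modules = list(Others = stub_module("Others", fixed(others)),
                   Weighting = stub_module("Weighting", fixed(weighting)),
                   FatSuppression = stub_module("FatSuppression",
                                                fixed(fatsup)),
                   Family = stub_module("Family", fixed(family))),
    contrast = NULL), class = "mrseries_bundle")
}

test_that("an 'other' decision stops the cascade", {
  recs <- clean_cohort(n = 30, seed = 51)[1:5]
  b <- stub_bundle(recs, "other", "T1W", "FS", "SE")
  res <- classify_series(recs[[1]], b)
  expect_identical(res$canonical, "OTHERS")
  expect_identical(res$executed, "Others")
  expect_setequal(names(res$skipped),
                  c("Weighting", "FatSuppression", "Contrast", "Family"))
})

test_that("a DWI decision stops the top branch after Weighting", {
  recs <- clean_cohort(n = 30, seed = 51)[1:5]
  b <- stub_bundle(recs, "relevant", "DWI", "FS", "SE")
  res <- classify_series(recs[[1]], b)
  expect_identical(res$canonical, "DWI")
  expect_true(all(c("Others", "Weighting") %in% res$executed))
  expect_false("FatSuppression" %in% res$executed)
  expect_false("Contrast" %in% res$executed)
})

test_that("T2W activates fat suppression but never contrast", {
  recs <- clean_cohort(n = 30, seed = 51)[1:5]
  b <- stub_bundle(recs, "relevant", "T2W", "FS", "SE")
  res <- classify_series(recs[[1]], b)
  expect_identical(res$canonical, "T2W_FS")
  expect_true("FatSuppression" %in% res$executed)
  expect_false("Contrast" %in% res$executed)
})

test_that("T1W without pixel data yields an undetermined, flagged contrast", {
  recs <- clean_cohort(n = 30, seed = 51)[1:5]   # no pixel source
  b <- stub_bundle(recs, "relevant", "T1W", "nFS", "GR")
  res <- classify_series(recs[[1]], b)
  expect_identical(res$canonical, "T1W_nFS")
  expect_identical(res$label$contrast, "undetermined")
  expect_true(res$decisions$contrast_undetermined)
  expect_true("Contrast" %in% res$executed)
})

test_that("family resolves from the tag when usable, from the model otherwise", {
  recs <- clean_cohort(n = 40, seed = 52)[1:3]
  b <- stub_bundle(recs, "relevant", "T2W", "nFS", "EP")
  r <- recs[[1]]
  r$tags$ScanningSequence <- "SE"
  expect_identical(resolve_family(r, b),
                   list(family = "SE", source = "tag"))
  # multi-valued tags resolve by priority IR > EP > GR > SE
  r$tags$ScanningSequence <- c("SE", "IR")
  expect_identical(resolve_family(r, b)$family, "IR")
  r$tags$ScanningSequence <- c("GR", "EP")
  expect_identical(resolve_family(r, b)$family, "EP")
  # empty or research-mode tags invoke the model
  r$tags$ScanningSequence <- NULL
  out <- resolve_family(r, b)
  expect_identical(out$source, "model")
  expect_identical(out$family, "EP")   # the stub's fixed answer
  r$tags$ScanningSequence <- "mode research"  # case-insensitive
  expect_identical(resolve_family(r, b)$source, "model")
})

test_that("compose errors propagate for invariant-violating combinations", {
  expect_error(compose_label(structure(
    list(is_other = FALSE, weighting = "T2W", fat_suppressed = "FS",
         contrast = "CE", family = NA_character_),
    class = "composite_label")), "T1W")
})

test_that("every series yields exactly one canonical label", {
  recs <- clean_cohort(n = 100, seed = 53)
  b <- cached("router_real_bundle",
              train_pipeline(clean_cohort(n = 400, seed = 54),
                             config = backend_config("gbt", nrounds = 120),
                             train_contrast_model = FALSE))
  out <- classify_cohort(recs, b)
  expect_identical(nrow(out), 100L)
  legal <- c(label_space(), "T1W_FS", "T1W_nFS")  # undetermined contrast
  expect_true(all(out$label %in% legal))
  expect_false(any(is.na(out$label)))
})
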