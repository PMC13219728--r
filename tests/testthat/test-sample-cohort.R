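test_that("identical seeds give identical cohorts", {
  spec <- default_primage_spec(n_series = 60, seed = 7)
  expect_identical(sample_cohort(spec), sample_cohort(spec))
})

test_that("empirical marginals match the spec within binomial tolerance", {
  cohort <- cached("big_default_cohort",
                   sample_cohort(default_primage_spec(n_series = 10000,
                                                      seed = 1)))
  truth <- cohort_truth(cohort)
  analysed <- truth[truth != "OTHERS"]
  # T1W fraction among analysed series: within +/- 0.02 of 9489/16871
  p_t1w <- mean(startsWith(analysed, "T1W"))
  expect_lt(abs(p_t1w - 9489 / 16871), 0.02)
  # every marginal within 3 binomial SEs at the level it is sampled:
  # class per series, vendor/field per study, country per patient
  spec <- default_primage_spec(n_series = 10000, seed = 1)
  check_mix <- function(observed, mix) {
    n <- length(observed)
    for (nm in names(mix)) {
      se <- sqrt(mix[[nm]] * (1 - mix[[nm]]) / n)
      expect_lt(abs(mean(observed == nm) - mix[[nm]]), 3 * se + 1e-9,
                label = paste("marginal for", nm))
    }
  }
  check_mix(truth, spec$class_mix)
  study <- vapply(cohort, `[[`, "", "study_uid")
  first_per <- function(values, groups) vapply(split(values, groups),
                                               `[`, values[1], 1)
  check_mix(first_per(vapply(cohort, `[[`, "", "vendor"), study),
            spec$vendor_mix)
  check_mix(first_per(as.character(vapply(cohort, `[[`, 0,
                                          "field_strength")), study),
            spec$field_mix)
  check_mix(first_per(vapply(cohort, `[[`, "", "country"),
                      vapply(cohort, `[[`, "", "patient_id")),
            spec$country_mix)
})

test_that("patients carry multiple series and never exceed the size cap", {
  cohort <- clean_cohort(n = 400, seed = 42)
  sizes <- table(vapply(cohort, `[[`, "", "patient_id"))
  expect_true(all(sizes >= 1))
  expect_true(all(sizes <= 60))
  expect_gt(mean(sizes), 5)  # truncated geometric with mean about 15
})

test_that("corruption removes tags rather than writing placeholders", {
  cohort <- clean_cohort(n = 200, seed = 8)
  set.seed(1)
  corrupted <- apply_corruption(cohort, missingness = 0.5)
  n_tags <- function(recs) sum(vapply(recs, function(r) length(r$tags), 0L))
  expect_lt(n_tags(corrupted), n_tags(cohort))
  for (r in corrupted[1:20]) {
    expect_false(any(vapply(r$tags, function(v)
      is.character(v) && all(!nzchar(v)), logical(1))))
  }
})

test_that("label noise changes the recorded truth at the requested rate", {
  cohort <- clean_cohort(n = 1000, seed = 3)
  set.seed(2)
  noisy <- apply_corruption(cohort, label_noise = 0.2)
  flipped <- mean(cohort_truth(noisy) != cohort_truth(cohort))
  expect_gt(flipped, 0.12)
  expect_lt(flipped, 0.28)
})

test_that("invalid spec fields are named in the validation error", {
  expect_error(sample_cohort(structure(list(n_series = 0), class = "cohort_spec")),
               "n_series")
})
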