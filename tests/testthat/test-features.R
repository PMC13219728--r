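test_that("encoding widths and the missingness protocol are as specified", {
  cohort <- clean_cohort(n = 120, seed = 21)
  rows <- rows_from_records(cohort)
  enc <- fit_encoder(rows)
  x <- encode_features(enc, rows)
  # one-hot groups sum to <= 1 per row, 0 exactly when the tag is missing
  manu_cols <- grep("^Manufacturer\\.\\.", colnames(x))
  expect_true(all(rowSums(x[, manu_cols, drop = FALSE]) <= 1))
  # numeric missing -> value 0 with indicator 1
  rows2 <- rows
  rows2$EchoTime[1] <- NA
  x2 <- encode_features(enc, rows2)
  expect_identical(unname(x2[1, "EchoTime"]), 0)
  expect_identical(unname(x2[1, "EchoTime__missing"]), 1)
  # categorical with k training levels -> k indicators + 1 missing column
  expect_identical(sum(grepl("^Manufacturer\\.\\.", colnames(x))),
                   length(enc$levels$Manufacturer))
  expect_true("Manufacturer__missing" %in% colnames(x))
})

test_that("an unseen predict-time level encodes as an all-zero group", {
  cohort <- clean_cohort(n = 80, seed = 22)
  rows <- rows_from_records(cohort)
  enc <- fit_encoder(rows)
  rows$Manufacturer[1] <- "TOSHIBA-X NEW MODEL"
  x <- encode_features(enc, rows)
  manu_cols <- grep("^Manufacturer\\.\\.", colnames(x))
  expect_identical(unname(sum(x[1, manu_cols])), 0)
  expect_identical(unname(x[1, "Manufacturer__missing"]), 0)
})

test_that("encoding is deterministic and row-permutation equivariant", {
  cohort <- clean_cohort(n = 60, seed = 23)
  rows <- rows_from_records(cohort)
  enc <- fit_encoder(rows)
  x1 <- encode_features(enc, rows)
  expect_identical(x1, encode_features(enc, rows))
  perm <- sample(nrow(rows))
  x2 <- encode_features(enc, rows[perm, , drop = FALSE])
  expect_identical(x1[rownames(x2), ], x2[, ])
})

test_that("the chi-square selection reproduces the closed-form 2x2 case", {
  # perfectly aligned binary column, 50/50 over n = 100
  x <- matrix(rep(c(1, 0), each = 50), ncol = 1,
              dimnames = list(paste0("s", 1:100), "probe"))
  y <- rep(c("a", "b"), each = 50)
  sub <- select_features(x, y)
  row <- sub$table[sub$table$column == "probe", ]
  expect_equal(row$statistic, 100, tolerance = 1e-9)  # no continuity corr.
  expect_equal(row$p, 1.52e-23, tolerance = 0.01)
  expect_true("probe" %in% sub$selected)
})

test_that("constant columns are dropped and single-class targets rejected", {
  x <- cbind(const = rep(1, 40), var = rep(c(0, 1), 20))
  rownames(x) <- paste0("s", 1:40)
  y <- rep(c("a", "b"), 20)
  sub <- select_features(x, y)
  expect_false("const" %in% sub$selected)
  expect_identical(sub$table$p[sub$table$column == "const"], 1)
  expect_error(select_features(x, rep("a", 40)), "2 target classes")
})

test_that("the split fingerprint flags re-selection on different rows", {
  cohort <- clean_cohort(n = 100, seed = 24)
  rows <- rows_from_records(cohort)
  enc <- fit_encoder(rows[1:60, ])
  xtr <- encode_features(enc, rows[1:60, ])
  sub <- select_features(xtr, cohort_truth(cohort)[1:60])
  expect_true(check_split_fingerprint(sub, xtr))
  xall <- encode_features(enc, rows)
  expect_warning(ok <- check_split_fingerprint(sub, xall), "leakage")
  expect_false(ok)
})
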