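# Shared encoded training data on a clean, header-separable cohort.
module_data <- function(module, n = 500, seed = 31) {
  cached(sprintf("moddata_%s_%d_%d", module, n, seed), {
    cohort <- clean_cohort(n = n, seed = seed)
    sp <- patient_split(cohort, split_plan(seed = seed))
    rows <- rows_from_records(cohort)
    pop_tr <- intersect(sp$train, which(module_population(cohort, module)))
    pop_te <- intersect(sp$test, which(module_population(cohort, module)))
    enc <- fit_encoder(rows[pop_tr, , drop = FALSE])
    xtr <- encode_features(enc, rows[pop_tr, , drop = FALSE])
    xte <- encode_features(enc, rows[pop_te, , drop = FALSE])
    y <- module_truth(cohort, module)
    list(xtr = xtr, xte = xte, ytr = y[pop_tr], yte = y[pop_te],
         sub = select_features(xtr, y[pop_tr]))
  })
}

test_that("both backends recover the weighting perfectly on clean headers", {
  d <- module_data("Weighting")
  for (be in c("gbt", "rf")) {
    mod <- train_module(d$xtr, d$ytr, "Weighting", d$sub,
                        backend_config(be, seed = 1, nrounds = 200,
                                       n_trees = 300))
    p <- module_probs(mod, d$xte)
    pred <- apply(p, 1, function(pr)
      decide_class(stats::setNames(pr, colnames(p))))
    expect_identical(unname(mean(pred == d$yte)), 1, label = be)
  }
})

test_that("training is deterministic given seed, config, and data", {
  d <- module_data("FatSuppression")
  for (be in c("gbt", "rf")) {
    m1 <- train_module(d$xtr, d$ytr, "FatSuppression", d$sub,
                       backend_config(be, seed = 9, nrounds = 60,
                                      n_trees = 100))
    m2 <- train_module(d$xtr, d$ytr, "FatSuppression", d$sub,
                       backend_config(be, seed = 9, nrounds = 60,
                                      n_trees = 100))
    expect_equal(module_probs(m1, d$xte), module_probs(m2, d$xte),
                 tolerance = 1e-12, label = be)
  }
})

test_that("label and column contracts are enforced", {
  d <- module_data("Weighting")
  expect_error(train_module(d$xtr, rep("FLAIR", length(d$ytr)), "Weighting",
                            d$sub), "outside the Weighting class list")
  y2 <- d$ytr
  y2[y2 == "DWI"] <- "T1W"
  expect_error(train_module(d$xtr, y2, "Weighting", d$sub),
               "absent from training labels")
  mod <- train_module(d$xtr, d$ytr, "Weighting", d$sub,
                      backend_config("gbt", nrounds = 40))
  expect_error(module_probs(mod, d$xte[, 1:4, drop = FALSE]),
               "lack model columns")
})

test_that("predictions are normalized probability vectors with a stable argmax", {
  d <- module_data("Weighting")
  mod <- train_module(d$xtr, d$ytr, "Weighting", d$sub,
                      backend_config("gbt", nrounds = 60))
  dec <- predict_module(mod, d$xte[1, , drop = FALSE])
  expect_s3_class(dec, "module_decision")
  expect_equal(sum(dec$probabilities), 1, tolerance = 1e-9)
  expect_true(all(dec$probabilities >= 0))
  expect_identical(dec$class, decide_class(dec$probabilities))
  # argmax ties break to the lexicographically first class
  expect_identical(decide_class(c(T2W = 0.4, DWI = 0.4, T1W = 0.2)), "DWI")
})

test_that("a duplicated pure training point predicts its class with high confidence", {
  d <- module_data("Weighting")
  probe <- which(d$ytr == "DWI")[1]
  mod <- train_module(d$xtr, d$ytr, "Weighting", d$sub,
                      backend_config("rf", n_trees = 200))
  dec <- predict_module(mod, d$xtr[probe, , drop = FALSE])
  expect_identical(dec$class, "DWI")
  expect_gt(dec$probabilities["DWI"], 0.99)
})

test_that("class weighting does not hurt minority sensitivity (95:5 task)", {
  minority_sens <- function(seed, weighted) {
    set.seed(seed)
    n <- 600
    y <- c(rep("FS", round(0.05 * n)), rep("nFS", n - round(0.05 * n)))
    x <- cbind(sig1 = rnorm(n, ifelse(y == "FS", 0.8, 0)),
               sig2 = rnorm(n, ifelse(y == "FS", 0.8, 0)),
               noise = rnorm(n))
    rownames(x) <- paste0("s", seq_len(n))
    tr <- sample(n, 400)
    sub <- select_features(x[tr, ], y[tr], alpha = 0.05)
    mod <- train_module(x[tr, ], y[tr], "FatSuppression", sub,
                        backend_config("rf", class_weighting = weighted,
                                       seed = seed, n_trees = 200))
    p <- module_probs(mod, x[-tr, ])
    pred <- apply(p, 1, function(pr)
      decide_class(stats::setNames(pr, colnames(p))))
    mean(pred[y[-tr] == "FS"] == "FS")
  }
  gains <- vapply(1:5, function(s)
    minority_sens(s, TRUE) - minority_sens(s, FALSE), numeric(1))
  expect_gte(mean(gains), 0)
})

test_that("cross-validation is patient-grouped and re-selects per fold", {
  cohort <- clean_cohort(n = 400, seed = 33)
  cv <- cv_train(cohort, "Weighting", k = 5,
                 config = backend_config("gbt", nrounds = 80), seed = 2)
  expect_identical(nrow(cv$folds), 5L)
  expect_true(all(c("accuracy", "auc", "f1") %in% cv$summary$metric))
  # clean separable task: mean accuracy 1, SD 0
  acc <- cv$summary[cv$summary$metric == "accuracy", ]
  expect_equal(acc$mean, 1, tolerance = 1e-12)
  expect_equal(acc$sd, 0, tolerance = 1e-12)
  # every patient lands in exactly one validation fold
  fold_of <- cv_folds(cohort, k = 5, seed = 2)
  pat <- vapply(cohort, `[[`, "", "patient_id")
  expect_true(all(vapply(split(fold_of, pat),
                         function(f) length(unique(f)) == 1, logical(1))))
  # fewer patients than folds is an error
  few <- cohort[pat %in% unique(pat)[1:3]]
  expect_error(cv_train(few, "Weighting", k = 5), "fewer patients")
})
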