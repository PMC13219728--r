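test_that("representative-volume selection follows the stated precedence", {
  vol <- function(n, itc = "ORIGINAL", b = NA, te = NA)
    structure(list(n_slices = n, image_type_class = itc, bvalue = b,
                   echo_time = te, temporal = NA,
                   source = list(type = "files")), class = "volume_ref")
  rec <- function(...) structure(list(series_uid = "s", volumes = list(...)),
                                 class = "series_record")
  # derived volumes are dropped even with equal slice counts
  r <- select_representative_volume(rec(vol(24, "DERIVED"), vol(24)))
  expect_identical(r$image_type_class, "ORIGINAL")
  # a single volume is returned as is
  v1 <- vol(10)
  expect_identical(select_representative_volume(rec(v1))$n_slices, 10)
  # most slices wins among originals
  expect_identical(
    select_representative_volume(rec(vol(8), vol(20)))$n_slices, 20)
  # equal slices: lowest echo time wins
  expect_identical(
    select_representative_volume(rec(vol(10, te = 90),
                                     vol(10, te = 10)))$echo_time, 10)
  # lowest b-value wins for diffusion
  expect_identical(
    select_representative_volume(rec(vol(10, b = 800),
                                     vol(10, b = 0)))$bvalue, 0)
  # all volumes derived: fall back to the first with a warning
  expect_warning(
    f <- select_representative_volume(rec(vol(5, "DERIVED"),
                                          vol(7, "DERIVED"))),
    "derived")
  expect_identical(f$n_slices, 5)
  expect_error(select_representative_volume(rec()), "zero volumes")
})

test_that("central slice is floor(N/2) of the spatial order", {
  mkvol <- function(n) structure(
    list(n_slices = n, order = seq_len(n), files = NULL,
         image_type_class = "ORIGINAL", bvalue = NA, echo_time = NA,
         temporal = NA, discriminator = NULL,
         source = list(type = "phantom", seed = 1, volume_index = 1,
                       label = parse_label("T2W_nFS"), vendor = "SIEMENS")),
    class = "volume_ref")
  for (case in list(c(7, 3), c(1, 0), c(24, 12))) {
    img <- central_slice(mkvol(case[1]))
    expect_identical(attr(img, "slice_index"), as.integer(case[2]))
  }
})

test_that("preprocessing clips, rescales, resizes, and ignores global scale", {
  img <- render_phantom("T2W_nFS", seed = 4)
  p <- preprocess_image(img)
  expect_identical(dim(p), c(224L, 224L))
  expect_true(all(p >= 0 & p <= 1))
  # constant image -> all zeros
  expect_identical(preprocess_image(matrix(5, 64, 64)),
                   matrix(0, 224, 224))
  # intensity scaling (vendor scale factors) leaves the output unchanged
  expect_equal(preprocess_image(unclass(img) * 10), p, tolerance = 1e-9)
})

test_that("the plateau scheduler reduces once after the patience runs out", {
  s <- plateau_scheduler(lr = 1e-5, factor = 0.8, patience = 10,
                         min_lr = 1e-7)
  lrs <- numeric(12)
  for (ep in 1:12) {
    s <- scheduler_step(s, 1)  # no improvement in any epoch
    lrs[ep] <- s$lr
  }
  expect_equal(lrs[10], 1e-5)
  expect_equal(lrs[11], 8e-6)          # reduced exactly at epoch 11
  expect_equal(lrs[12], 8e-6)
  expect_identical(s$reductions, 1)
  # the floor is respected
  s2 <- plateau_scheduler(lr = 2e-7, factor = 0.5, patience = 1,
                          min_lr = 1e-7)
  s2 <- scheduler_step(scheduler_step(s2, 1), 1)
  expect_gte(s2$lr, 1e-7)
})

test_that("training validates inputs and the residual backbone is declared unavailable", {
  d <- phantom_set(24, cnr = 5, seed = 77)
  expect_error(train_contrast(d$imgs, rep("CE", 24)),
               "both CE and nCE")
  expect_error(
    train_contrast(d$imgs, d$labs,
                   image_train_config(backbone = "resnet50")),
    "deep-learning runtime")
  expect_error(image_train_config(lr = 1e-8, min_lr = 1e-7))
})

test_that("inference is deterministic, bounded, and batch-consistent", {
  d <- phantom_set(40, cnr = 5, seed = 78)
  m <- cached("tiny_contrast_model",
              train_contrast(d$imgs, d$labs,
                             image_train_config(epochs = 3, batch_size = 8,
                                                lr = 2e-3, seed = 1)))
  p1 <- contrast_probs(m, d$imgs[1:8])
  p2 <- contrast_probs(m, d$imgs[1:8])
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  singles <- vapply(d$imgs[1:8], function(im)
    predict_contrast(m, im)$probabilities[["CE"]], numeric(1))
  expect_equal(unname(singles), p1, tolerance = 1e-9)
  expect_error(predict_contrast(m, matrix(0, 64, 64)), "input size")
})

test_that("retraining with the same seed reproduces the model", {
  d <- phantom_set(24, cnr = 5, seed = 77)
  cfg <- image_train_config(epochs = 2, batch_size = 8, lr = 2e-3, seed = 5)
  m1 <- train_contrast(d$imgs, d$labs, cfg)
  m2 <- train_contrast(d$imgs, d$labs, cfg)
  expect_equal(contrast_probs(m1, d$imgs[1:6]),
               contrast_probs(m2, d$imgs[1:6]), tolerance = 1e-12)
})
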