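## Image-based contrast branch ------------------------------------------------

#' Training configuration for the contrast image classifier
#'
#' Defaults follow the reference training schedule: 224x224 inputs, batch
#' size 128, 100 epochs, binary cross-entropy, Adam at an initial learning
#' rate of 1e-5, and a reduce-on-plateau scheduler (factor 0.8, patience 10,
#' minimum learning rate 1e-7). That schedule suits fine-tuning a pretrained
#' deep residual backbone; when training the `small_cnn` backbone from
#' scratch, pass a larger learning rate and fewer epochs (see the package
#' vignette).
#'
#' @param input_size Square input size in pixels.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param lr Initial learning rate.
#' @param scheduler_factor,scheduler_patience,min_lr Plateau scheduler
#'   parameters.
#' @param backbone `"small_cnn"` (3 conv blocks, runnable on one CPU) or
#'   `"resnet50"` (pretrained deep residual; requires a deep-learning
#'   runtime that this package does not bundle, so training with it raises
#'   an informative error).
#' @param val_frac Fraction of training images held out to monitor the
#'   scheduler and checkpoint the best weights.
#' @param threshold Decision threshold on the enhanced-class probability.
#' @param seed Integer seed.
#' @return An object of class `image_train_config`.
#' @export
image_train_config <- function(input_size = 224L, batch_size = 128L,
                               epochs = 100L, lr = 1e-5,
                               scheduler_factor = 0.8,
                               scheduler_patience = 10L, min_lr = 1e-7,
                               backbone = c("small_cnn", "resnet50"),
                               val_frac = 0.15, threshold = 0.5,
                               seed = 1L) {
  backbone <- match.arg(backbone)
  stopifnot(min_lr <= lr, scheduler_factor > 0, scheduler_factor < 1)
  structure(list(input_size = as.integer(input_size),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 scheduler_factor = scheduler_factor,
                 scheduler_patience = as.integer(scheduler_patience),
                 min_lr = min_lr, backbone = backbone,
                 val_frac = val_frac, threshold = threshold,
                 seed = as.integer(seed),
                 loss = "binary cross-entropy", optimiser = "adam"),
            class = "image_train_config")
}

#' Select the representative volume of a series
#'
#' Precedence: volumes whose image type carries derived/secondary keywords
#' (DERIVED, SUBTRACT, PROJECTION, MPR, SCREEN) are dropped; among the
#' survivors the volume with the most slices wins; ties go to the lowest
#' discriminator value (lowest b-value, then lowest echo time, then lowest
#' temporal position). If every volume is derived, the first volume is used
#' with a warning.
#'
#' @param record A `series_record` with at least one volume (scanned with
#'   pixel data, or synthetic with a phantom pixel source).
#' @return A `volume_ref`.
#' @export
select_representative_volume <- function(record) {
  vols <- record$volumes
  if (is.null(vols)) vols <- split_volumes(record)
  if (!length(vols))
    stop("series ", record$series_uid, " has zero volumes", call. = FALSE)
  keep <- vapply(vols, function(v)
    !identical(v$image_type_class, "DERIVED"), logical(1))
  if (!any(keep)) {
    warning("all volumes of ", record$series_uid,
            " are derived; falling back to the first volume",
            call. = FALSE)
    return(vols[[1]])
  }
  vols <- vols[keep]
  nsl <- vapply(vols, `[[`, numeric(1), "n_slices")
  key_b <- vapply(vols, function(v) ifelse(is.na(v$bvalue), Inf, v$bvalue),
                  numeric(1))
  key_te <- vapply(vols, function(v)
    ifelse(is.na(v$echo_time), Inf, v$echo_time), numeric(1))
  key_tp <- vapply(vols, function(v)
    ifelse(is.na(v$temporal), Inf, v$temporal), numeric(1))
  ## most slices first; ties by lowest discriminator
  ord <- order(-nsl, key_b, key_te, key_tp)
  vols[[ord[1]]]
}

#' Extract the central slice of a volume
#'
#' Returns the slice at index `floor(N/2)` (0-based) of the spatial order,
#' i.e. element `floor(N/2) + 1`; invariant to file order on disk.
#'
#' @param volume A `volume_ref`.
#' @return An `image_2d`: intensity matrix plus provenance attributes.
#' @export
central_slice <- function(volume) {
  n <- as.integer(volume$n_slices)
  stopifnot(n >= 1)
  idx0 <- n %/% 2L                    # 0-based central index
  if (identical(volume$source$type, "phantom")) {
    src <- volume$source
    j <- idx0 + 1L
    sd_seed <- (src$seed + 131 * src$volume_index + j) %%
      .Machine$integer.max
    img <- if (src$label$is_other)
      render_other_image(seed = sd_seed, size = 128L)
    else
      render_phantom(src$label, vendor = src$vendor, seed = sd_seed,
                     size = 128L,
                     slice_frac = if (n > 1) (2 * j - n - 1) / n else 0)
  } else {
    f <- volume$files[idx0 + 1L]
    parsed <- dcm_read(f, read_pixels = TRUE)
    if (is.null(parsed$pixels))
      stop("no decodable pixel data in ", f, call. = FALSE)
    img <- parsed$pixels
  }
  structure(img, class = c("image_2d", class(img)),
            slice_index = idx0, n_slices = n,
            discriminator = volume$discriminator)
}

#' Normalize and resize an image for the contrast classifier
#'
#' Clips intensities to the 1st-99th percentile window, rescales to [0, 1],
#' and bilinearly resizes to `size` x `size`. A constant image maps to all
#' zeros. Invariant to global intensity scaling (vendor scale factors).
#'
#' @param img Numeric matrix.
#' @param size Output side length (default 224).
#' @return `size` x `size` matrix with values in [0, 1].
#' @export
preprocess_image <- function(img, size = 224L) {
  img <- unclass(img)
  attributes(img) <- list(dim = dim(img))
  stopifnot(all(is.finite(img)))
  q <- stats::quantile(img, c(0.01, 0.99), names = FALSE)
  if (q[2] - q[1] <= 0) return(matrix(0, size, size))
  img <- pmin(pmax(img, q[1]), q[2])
  img <- (img - q[1]) / (q[2] - q[1])
  out <- EBImage::resize(img, w = size, h = size)
  matrix(as.numeric(out), size, size)
}

## Stack preprocessed images into the network's working-resolution tensor
## (average-pooled to 32x32, per-image mean-centred).
images_to_tensor <- function(imgs, input_size = 224L, pool = 7L) {
  n <- length(imgs)
  x <- array(0, c(n, input_size, input_size, 1))
  for (i in seq_len(n)) x[i, , , 1] <- imgs[[i]] - mean(imgs[[i]])
  avg_pool_factor(x, pool)
}

#' Train the binary contrast classifier on single-slice images
#'
#' @param images List of preprocessed images ([preprocess_image()]).
#' @param ce_labels Binary labels: `"CE"`/`"nCE"`, logical, or 0/1 (1 = CE).
#' @param config An [image_train_config()].
#' @return An object of class `contrast_model`.
#' @export
train_contrast <- function(images, ce_labels,
                           config = image_train_config()) {
  if (identical(config$backbone, "resnet50"))
    stop("the pretrained residual backbone requires a deep-learning ",
         "runtime that this package does not bundle; use the small_cnn ",
         "backbone", call. = FALSE)
  y <- ce_to_binary(ce_labels)
  if (length(unique(y)) < 2)
    stop("contrast training requires both CE and nCE examples",
         call. = FALSE)
  stopifnot(length(images) == length(y))
  x <- images_to_tensor(images, config$input_size)
  fit <- cnn_train(x, y, epochs = config$epochs,
                   batch_size = config$batch_size, lr = config$lr,
                   factor = config$scheduler_factor,
                   patience = config$scheduler_patience,
                   min_lr = config$min_lr, val_frac = config$val_frac,
                   seed = config$seed)
  structure(list(fit = fit, config = config, classes = c("CE", "nCE")),
            class = "contrast_model")
}

ce_to_binary <- function(labels) {
  if (is.character(labels)) as.integer(labels == "CE")
  else as.integer(as.numeric(labels) != 0)
}

#' Enhanced-class probabilities for preprocessed images
#' @param model A [train_contrast()] model.
#' @param images List of preprocessed images.
#' @return Numeric vector of P(CE).
#' @export
contrast_probs <- function(model, images) {
  x <- images_to_tensor(images, model$config$input_size)
  cnn_predict(model$fit, x, batch_size = model$config$batch_size)
}

#' Predict contrast status of one image
#'
#' @param model A [train_contrast()] model.
#' @param img A preprocessed image ([preprocess_image()]).
#' @return A `module_decision` over `{CE, nCE}` (threshold
#'   `model$config$threshold` on P(CE)).
#' @export
predict_contrast <- function(model, img) {
  if (!all(dim(img) == model$config$input_size))
    stop("image shape ", paste(dim(img), collapse = "x"),
         " does not match the configured input size ",
         model$config$input_size, call. = FALSE)
  p <- contrast_probs(model, list(img))
  cls <- if (p >= model$config$threshold) "CE" else "nCE"
  structure(list(module = "Contrast", class = cls,
                 probabilities = c(CE = p, nCE = 1 - p)),
            class = "module_decision")
}

## Resolve the representative image of a record (render or read + preprocess).
get_series_image <- function(record, size = 224L) {
  vol <- select_representative_volume(record)
  preprocess_image(central_slice(vol), size = size)
}
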