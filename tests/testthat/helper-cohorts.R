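# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Uncorrupted cohort: headers fully determine the labels.
clean_cohort <- function(n = 400, seed = 42, pixels = FALSE) {
  cached(sprintf("clean_%d_%d_%d", n, seed, pixels),
         sample_cohort(default_primage_spec(
           n_series = n, seed = seed, missingness = 0, text_noise = 0,
           label_noise = 0, with_pixels = pixels)))
}

# Phantom image set for contrast-branch experiments.
phantom_set <- function(n, cnr, seed) {
  cached(sprintf("phantoms_%d_%g_%d", n, cnr, seed), {
    set.seed(seed + 1000)
    labs <- sample(c("CE", "nCE"), n, TRUE)
    imgs <- lapply(seq_len(n), function(i) {
      fs <- sample(c("FS", "nFS"), 1)
      preprocess_image(render_phantom(
        composite_label("T1W", fs, labs[i]),
        seed = seed * 100000 + i, vessel_cnr = cnr))
    })
    list(imgs = imgs, labs = labs)
  })
}

auc_of <- function(truth01, probs) {
  as.numeric(pROC::auc(pROC::roc(truth01, probs, quiet = TRUE,
                                 direction = "<")))
}

# Fixed-output stand-in for a trained module, for routing-logic tests:
# `mapping` is a named vector series_uid -> class.
stub_module <- function(module, mapping) {
  structure(list(module = module, classes = MODULE_CLASSES[[module]],
                 mapping = mapping),
            class = c("stub_module", "trained_module_like"))
}

module_probs.stub_module <- function(model, x, ...) {
  cls <- model$classes
  p <- matrix(0, nrow(x), length(cls), dimnames = list(rownames(x), cls))
  for (i in seq_len(nrow(x))) p[i, model$mapping[[rownames(x)[i]]]] <- 1
  p
}

registerS3method("module_probs", "stub_module", module_probs.stub_module,
                 envir = asNamespace("mrseries"))
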