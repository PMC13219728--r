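## Body phantom renderer ------------------------------------------------------
##
## An elliptical body phantom with tissue compartments whose mean intensities
## depend on the composite label: weighting sets the base tissue contrast
## (T1W: bright fat; T2W: bright fluid; DWI: blurred, noisy, low resolution),
## fat suppression attenuates the subcutaneous fat ring, and contrast
## enhancement adds bright vessels, an enhancing rim, and a lesion blob at a
## configurable contrast-to-noise ratio. This gives the image-based contrast
## classifier a learnable signal without attempting physical MR simulation.

#' Render a single-slice body phantom for a composite label
#'
#' @param label A [composite_label()] or canonical label string; weighting
#'   must not be Others.
#' @param vendor Vendor name; only affects a global intensity scale factor,
#'   emulating vendor-dependent scanner scaling.
#' @param seed Integer seed; identical seeds give identical pixel arrays.
#' @param size Output grid size in pixels (square).
#' @param vessel_cnr Contrast-to-noise ratio of the enhancement signal, in
#'   units of the noise SD. Enhanced and non-enhanced phantoms differ in mean
#'   vessel-mask intensity by `vessel_cnr * noise_sd`; 0 disables the
#'   enhancement signal entirely.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param slice_frac Position of the slice along the body axis in `[-1, 1]`;
#'   scales the body ellipse so that multi-slice volumes vary anatomically.
#' @return A `size` x `size` numeric matrix with attributes `fat_mask`,
#'   `vessel_mask` (logical matrices) and `noise_sd`.
#' @export
#' @examples
#' img <- render_phantom("T1W_FS_CE", seed = 3)
#' mean(img[attr(img, "vessel_mask")])
render_phantom <- function(label, vendor = "SIEMENS", seed = 1L,
                           size = 256L, vessel_cnr = 5, noise_sd = 0.05,
                           slice_frac = 0) {
  if (is.character(label)) label <- parse_label(label)
  stopifnot(inherits(label, "composite_label"))
  if (label$is_other || is.na(label$weighting))
    stop("no phantom is defined for Others-type series", call. = FALSE)

  set.seed(as.integer(seed))
  w <- label$weighting
  fs <- identical(label$fat_suppressed, "FS")
  ce <- identical(label$contrast, "CE")

  g <- seq(-1, 1, length.out = size)
  X <- matrix(g, size, size)              # column coordinate
  Y <- matrix(g, size, size, byrow = TRUE)
  th <- stats::runif(1, -0.3, 0.3)
  Xr <- cos(th) * X + sin(th) * Y
  Yr <- -sin(th) * X + cos(th) * Y
  shrink <- 1 - 0.25 * abs(slice_frac)

  a <- stats::runif(1, 0.75, 0.88) * shrink
  b <- stats::runif(1, 0.55, 0.68) * shrink
  body <- (Xr / a)^2 + (Yr / b)^2 <= 1
  inner <- (Xr / (0.8 * a))^2 + (Yr / (0.78 * b))^2 <= 1
  fat <- body & !inner

  circ <- function(cx, cy, r) (Xr - cx)^2 + (Yr - cy)^2 <= r^2
  fluid  <- circ(0.25, 0.12, 0.17)
  lesion <- circ(-0.30, -0.14, 0.14)
  rim <- ((Xr + 0.30)^2 + (Yr + 0.14)^2 <= 0.20^2) & !lesion
  vessel <- circ(0.10, -0.32, 0.06) | circ(-0.05, -0.36, 0.05) |
    (abs(Yr - 0.35) < 0.035 & abs(Xr) < 0.45 & inner)

  base <- switch(w,
    T1W = list(fat = 0.90, tissue = 0.50, fluid = 0.20, vessel = 0.45),
    T2W = list(fat = 0.80, tissue = 0.35, fluid = 0.95, vessel = 0.30),
    DWI = list(fat = 0.30, tissue = 0.60, fluid = 0.85, vessel = 0.55))

  img <- matrix(0.02, size, size)
  img[inner] <- base$tissue
  img[fluid & inner] <- base$fluid
  img[lesion & inner] <- base$tissue * 0.8
  img[vessel] <- base$vessel
  img[fat] <- base$fat
  if (fs) img[fat] <- img[fat] * 0.25     # >= 60% fat attenuation

  if (ce) {
    boost <- vessel_cnr * noise_sd
    img[vessel] <- img[vessel] + boost
    img[rim & inner] <- img[rim & inner] + 0.8 * boost
    img[lesion & inner] <- img[lesion & inner] + 0.5 * boost
  }

  if (w == "DWI") {
    small <- EBImage::resize(img, w = size %/% 4)
    img <- EBImage::resize(small, w = size)
    noise_sd <- noise_sd * 3
  }
  img <- img + stats::rnorm(size * size, sd = noise_sd)

  scale <- switch(vendor, SIEMENS = 1, PHILIPS = 400, GE = 0.8,
                  TOSHIBA = 1.6, 1)
  structure(img * scale, fat_mask = fat, vessel_mask = vessel,
            noise_sd = noise_sd * scale)
}

## Simple non-diagnostic image (localiser-like gradient pattern); used when
## the routing pipeline requests pixels for a series whose generating label
## is Others.
render_other_image <- function(seed = 1L, size = 256L) {
  set.seed(as.integer(seed))
  g <- seq(0, 1, length.out = size)
  outer(g, g, function(x, y) 0.5 * x + 0.2 * sin(8 * y)) +
    stats::rnorm(size * size, sd = 0.05)
}
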