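# Colour calibration: gamma linearisation, grey-card white balance, CIELAB.
#
# Images are H x W x 3 numeric arrays with channel values in [0, 1], wrapped
# in a light S3 class that records whether the pixel values are still
# gamma-encoded (as stored in a PNG) or linear (proportional to scene
# radiance). All calibration arithmetic happens on linear values.

#' Construct an RGB image object
#'
#' @param pixels numeric H x W x 3 array with values in \[0, 1\].
#' @param encoding `"srgb_gamma"` for display-encoded values (as read from a
#'   PNG), `"linear"` for scene-linear values.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, encoding = c("srgb_gamma", "linear")) {
  encoding <- match.arg(encoding)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one pixel")
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1 + 1e-12)
    stop("channel values must lie in [0, 1]")
  structure(list(pixels = pixels, encoding = encoding), class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image %d x %d, %s>\n", d[1], d[2], x$encoding))
  invisible(x)
}

#' Read a PNG photograph as a gamma-encoded RGB image
#'
#' 8- or 16-bit PNGs are mapped to \[0, 1\]; greyscale images are replicated
#' across channels and any alpha channel is dropped.
#'
#' @param path path to a PNG file.
#' @return An `rgb_image` with `srgb_gamma` encoding.
#' @export
read_photo <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 3L))
  if (dim(px)[3] >= 4L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] == 2L) px <- array(px[, , 1L], c(dim(px)[1:2], 3L))
  rgb_image(px, "srgb_gamma")
}

#' Write an RGB image to PNG
#'
#' @param image an `rgb_image`; linear images are gamma-encoded first so the
#'   file is display-referred.
#' @param path output path.
#' @param gamma encoding exponent used if the image is linear.
#' @export
write_photo <- function(image, path, gamma = 2.2) {
  stopifnot(inherits(image, "rgb_image"))
  if (image$encoding == "linear") image <- srgb_encode(image, gamma)
  png::writePNG(image$pixels, path)
  invisible(path)
}

#' Undo display gamma encoding
#'
#' Recovers scene-linear intensities from display-encoded pixel values by
#' raising each value to `gamma`. A pure power law is used rather than the
#' piecewise sRGB transfer curve; 2.2 is a close approximation for
#' phone-camera output.
#'
#' @param image an `rgb_image` with `srgb_gamma` encoding.
#' @param gamma decoding exponent (> 0), default 2.2.
#' @return An `rgb_image` with `linear` encoding.
#' @export
srgb_decode <- function(image, gamma = 2.2) {
  stopifnot(inherits(image, "rgb_image"), gamma > 0)
  if (image$encoding != "srgb_gamma")
    stop("srgb_decode expects a gamma-encoded image")
  rgb_image(image$pixels^gamma, "linear")
}

#' Apply display gamma encoding
#'
#' Inverse of [srgb_decode()]: raises linear values to `1/gamma`.
#'
#' @inheritParams srgb_decode
#' @param image an `rgb_image` with `linear` encoding.
#' @return An `rgb_image` with `srgb_gamma` encoding.
#' @export
srgb_encode <- function(image, gamma = 2.2) {
  stopifnot(inherits(image, "rgb_image"), gamma > 0)
  if (image$encoding != "linear")
    stop("srgb_encode expects a linear image")
  rgb_image(image$pixels^(1 / gamma), "srgb_gamma")
}

#' Estimate the grey-card colour from a rectangular region
#'
#' The card colour is the per-channel median over the region, which is
#' robust to small specks, glare points and region-boundary slop.
#'
#' @param image an `rgb_image` with `linear` encoding.
#' @param roi integer vector `c(x, y, w, h)` in 0-based pixel coordinates
#'   with top-left origin (`x` = column, `y` = row).
#' @return A list of class `card_estimate` with elements `colour`
#'   (length-3 linear RGB), `roi`, and `n_pixels`.
#' @export
estimate_card_colour <- function(image, roi) {
  stopifnot(inherits(image, "rgb_image"))
  if (image$encoding != "linear")
    stop("estimate_card_colour expects a linear image")
  roi <- as.integer(round(roi))
  if (length(roi) != 4L) stop("`roi` must be c(x, y, w, h)")
  x <- roi[1]; y <- roi[2]; w <- roi[3]; h <- roi[4]
  d <- dim(image$pixels)
  if (w < 1L || h < 1L) stop("card roi is empty")
  if (x < 0L || y < 0L || x + w > d[2] || y + h > d[1])
    stop("card roi falls outside the image")
  block <- image$pixels[(y + 1L):(y + h), (x + 1L):(x + w), , drop = FALSE]
  colour <- apply(block, 3L, stats::median)
  if (any(colour <= 0))
    stop("card estimate has a zero channel; card unusable for calibration")
  structure(list(colour = colour, roi = roi, n_pixels = w * h),
            class = "card_estimate")
}

#' White-balance a linear image against its grey-card estimate
#'
#' Per-channel gains `m / g_k` (with `m` the mean of the card channels)
#' neutralise the illuminant tint so the card maps to an equal-channel grey.
#' With `normalize_exposure = TRUE` (default) a further scalar maps the card
#' to the canonical 18\% grey reflectance, making brightness comparable
#' across exposures. Post-gain values are clipped to \[0, 1\]; the clipped
#' fraction is recorded and a warning is raised when it exceeds 1\%.
#'
#' @param image an `rgb_image` with `linear` encoding.
#' @param card a `card_estimate` from [estimate_card_colour()].
#' @param normalize_exposure also rescale so the card lands on reflectance
#'   0.18.
#' @param target_reflectance canonical card reflectance (default 0.18).
#' @return A list with `image` (calibrated `rgb_image`) and `calibration`
#'   (class `calibration_result`: `gains`, `exposure_scale`, `gamma`,
#'   `clipped_fraction`).
#' @export
white_balance <- function(image, card, normalize_exposure = TRUE,
                          target_reflectance = 0.18) {
  stopifnot(inherits(image, "rgb_image"), inherits(card, "card_estimate"))
  if (image$encoding != "linear")
    stop("white_balance expects a linear image")
  g <- card$colour
  if (any(g <= 0)) stop("card estimate has a zero channel")
  m <- mean(g)
  gains <- m / g
  scale <- if (normalize_exposure) target_reflectance / m else 1
  px <- image$pixels
  for (k in 1:3) px[, , k] <- px[, , k] * gains[k] * scale
  clipped <- mean(px > 1)
  px[px > 1] <- 1
  px[px < 0] <- 0
  if (clipped > 0.01)
    warning(sprintf("white_balance clipped %.1f%% of channel values",
                    100 * clipped))
  list(
    image = rgb_image(px, "linear"),
    calibration = structure(
      list(gains = gains, exposure_scale = scale, gamma = 2.2,
           clipped_fraction = clipped),
      class = "calibration_result")
  )
}

# sRGB (D65) linear RGB -> XYZ matrix; rows sum to the D65 whitepoint so
# equal-channel greys map exactly onto the achromatic axis.
.rgb2xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
.xyz2rgb <- solve(.rgb2xyz)
.d65 <- rowSums(.rgb2xyz)  # (Xn, Yn, Zn)

.lab_f <- function(t) {
  d <- 6 / 29
  lo <- t <= d^3
  out <- t
  out[!lo] <- t[!lo]^(1 / 3)
  out[lo] <- t[lo] / (3 * d^2) + 4 / 29
  out
}
.lab_finv <- function(u) {
  d <- 6 / 29
  lo <- u <= d
  out <- u
  out[!lo] <- u[!lo]^3
  out[lo] <- 3 * d^2 * (u[lo] - 4 / 29)
  out
}

#' Convert a linear RGB image to CIELAB
#'
#' Uses sRGB primaries and the D65 whitepoint. L* is in \[0, 100\]; a* and b*
#' are the green-red and blue-yellow opponent axes (steatotic livers shift
#' toward lower a* and higher b*).
#'
#' @param image an `rgb_image` with `linear` encoding.
#' @return A `lab_image`: list with `L`, `a`, `b` (H x W matrices) and
#'   `whitepoint = "D65"`.
#' @export
rgb_to_lab <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  if (image$encoding != "linear")
    stop("rgb_to_lab expects a linear image; call srgb_decode first")
  d <- dim(image$pixels)
  rgbm <- matrix(image$pixels, ncol = 3L)      # pixels x 3
  xyz <- rgbm %*% t(.rgb2xyz)
  fx <- .lab_f(xyz[, 1] / .d65[1])
  fy <- .lab_f(xyz[, 2] / .d65[2])
  fz <- .lab_f(xyz[, 3] / .d65[3])
  L <- pmin(pmax(116 * fy - 16, 0), 100)
  a <- 500 * (fx - fy)
  b <- 200 * (fy - fz)
  structure(list(L = matrix(L, d[1], d[2]),
                 a = matrix(a, d[1], d[2]),
                 b = matrix(b, d[1], d[2]),
                 whitepoint = "D65"),
            class = "lab_image")
}

#' Convert a CIELAB image back to linear RGB
#'
#' Inverse of [rgb_to_lab()]; out-of-gamut values are clipped to \[0, 1\].
#' Used mainly by the synthetic-scene renderer.
#'
#' @param lab a `lab_image`.
#' @return An `rgb_image` with `linear` encoding.
#' @export
lab_to_rgb <- function(lab) {
  stopifnot(inherits(lab, "lab_image"))
  fy <- (as.vector(lab$L) + 16) / 116
  fx <- fy + as.vector(lab$a) / 500
  fz <- fy - as.vector(lab$b) / 200
  xyz <- cbind(.lab_finv(fx) * .d65[1],
               .lab_finv(fy) * .d65[2],
               .lab_finv(fz) * .d65[3])
  rgbm <- xyz %*% t(.xyz2rgb)
  rgbm[rgbm < 0] <- 0
  rgbm[rgbm > 1] <- 1
  d <- dim(lab$L)
  rgb_image(array(rgbm, c(d[1], d[2], 3L)), "linear")
}

#' Luminance quartiles over a masked region
#'
#' Computes the first quartile, median and third quartile of L* over the
#' pixels selected by `mask`; the interquartile range drives specular-patch
#' rejection.
#'
#' @param lab a `lab_image`.
#' @param mask logical H x W matrix (same size as `lab`).
#' @return Named numeric vector `c(q1, median, q3)`.
#' @export
luminance_stats <- function(lab, mask) {
  stopifnot(inherits(lab, "lab_image"), is.logical(mask))
  if (!all(dim(mask) == dim(lab$L)))
    stop("mask size does not match image")
  v <- lab$L[mask]
  if (length(v) == 0L) stop("mask selects no pixels")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

#' One-call calibration of a photograph
#'
#' Convenience wrapper: gamma decode, estimate the card colour from the ROI,
#' white balance, and convert to CIELAB.
#'
#' @param image an `rgb_image` (`srgb_gamma` encoding) or a PNG path.
#' @param card_roi card rectangle `c(x, y, w, h)`, 0-based, top-left origin.
#' @param gamma decoding exponent.
#' @param normalize_exposure passed to [white_balance()].
#' @return List with `rgb` (calibrated linear `rgb_image`), `lab`
#'   (`lab_image`), `card`, and `calibration`.
#' @export
calibrate_photo <- function(image, card_roi, gamma = 2.2,
                            normalize_exposure = TRUE) {
  if (is.character(image)) image <- read_photo(image)
  lin <- srgb_decode(image, gamma)
  card <- estimate_card_colour(lin, card_roi)
  wb <- white_balance(lin, card, normalize_exposure = normalize_exposure)
  list(rgb = wb$image, lab = rgb_to_lab(wb$image), card = card,
       calibration = wb$calibration)
}
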