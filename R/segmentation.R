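# Liver masks: read a supplied mask PNG, or fall back to a colour-threshold
# segmenter good enough for synthetic scenes (livers are the only large
# reddish object in frame).

#' Load a liver mask from a PNG file
#'
#' Nonzero pixels are liver. If `image_dim` is supplied the mask size is
#' checked against it.
#'
#' @param path mask PNG path (0 = background, nonzero = liver).
#' @param image_dim optional `c(H, W)` of the photograph the mask belongs to.
#' @return A `liver_mask`: list with `mask` (logical H x W), `area`, `source`.
#' @export
load_mask <- function(path, image_dim = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  mask <- px > 0
  if (!is.null(image_dim) && !all(dim(mask) == image_dim[1:2]))
    stop("mask size does not match image size")
  if (!any(mask)) stop("mask is empty")
  structure(list(mask = mask, area = sum(mask), source = "file"),
            class = "liver_mask")
}

#' Wrap a logical matrix as a liver mask
#'
#' @param mask logical H x W matrix.
#' @param source provenance tag.
#' @return A `liver_mask`.
#' @export
as_liver_mask <- function(mask, source = "file") {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) stop("mask is empty")
  structure(list(mask = mask, area = sum(mask), source = source),
            class = "liver_mask")
}

#' Write a liver mask to PNG
#'
#' @param mask a `liver_mask`.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "liver_mask"))
  png::writePNG(mask$mask * 1, path)
  invisible(path)
}

#' Baseline colour-threshold liver segmentation
#'
#' Selects reddish, mid-luminance pixels (a* above `a_min`, L* inside
#' `L_range`) in a calibrated CIELAB image, closes small gaps
#' morphologically, and keeps the largest connected component. This is a
#' deliberately simple segmenter intended for calibrated scenes where the
#' liver is the dominant reddish object; for clinical photographs a supplied
#' mask is the primary path.
#'
#' @param lab a `lab_image` of a calibrated photograph.
#' @param a_min minimum a* for liver tissue (default 10).
#' @param L_range admissible L* range (default `c(15, 85)`).
#' @param min_area_frac smallest acceptable component area as a fraction of
#'   the image (default 0.005).
#' @param close_radius radius (pixels) of the disc kernel used for
#'   morphological closing.
#' @return A `liver_mask` with `source = "baseline"`.
#' @export
baseline_segment <- function(lab, a_min = 10, L_range = c(15, 85),
                             min_area_frac = 0.005, close_radius = 5) {
  stopifnot(inherits(lab, "lab_image"))
  cand <- lab$a > a_min & lab$L >= L_range[1] & lab$L <= L_range[2]
  if (any(cand)) {
    kern <- EBImage::makeBrush(2L * as.integer(close_radius) + 1L,
                               shape = "disc")
    cand <- EBImage::closing(EBImage::Image(cand * 1), kern) > 0.5
    cand <- matrix(as.logical(cand), nrow = nrow(lab$L))
  }
  lbl <- EBImage::bwlabel(EBImage::Image(cand * 1))
  lbl <- matrix(as.integer(EBImage::imageData(lbl)), nrow = nrow(lab$L))
  if (max(lbl) == 0L)
    stop("baseline segmentation found no liver-like component")
  areas <- tabulate(lbl[lbl > 0L])
  best <- which.max(areas)
  if (areas[best] < min_area_frac * length(cand))
    stop("baseline segmentation found no sufficiently large component")
  as_liver_mask(lbl == best, source = "baseline")
}

#' Intersection over union of two masks
#'
#' @param a,b logical matrices or `liver_mask` objects of equal size.
#' @return IoU in \[0, 1\].
#' @export
mask_iou <- function(a, b) {
  if (inherits(a, "liver_mask")) a <- a$mask
  if (inherits(b, "liver_mask")) b <- b$mask
  stopifnot(all(dim(a) == dim(b)))
  u <- sum(a | b)
  if (u == 0L) return(NA_real_)
  sum(a & b) / u
}
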