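# Random non-overlapping square patches inside the liver mask, with
# specular-highlight rejection by the luminance interquartile range.

#' Plan patch count and size from the liver area
#'
#' The liver's pixel area determines the patch side and count:
#' `side = clip(round(sqrt(area) / 12), 60, 120)` and
#' `n = clip(round(area / (7 * side^2)), 15, 25)`. The constants are set so
#' a one-megapixel liver yields about twenty patches of roughly 80 x 80
#' pixels, the typical operating point; sides are bounded to
#' \[60, 120\] pixels and counts to \[15, 25\].
#'
#' @param area liver area in pixels (> 0).
#' @return A `patch_plan`: list with `n_patches` and `side`.
#' @export
plan_patches <- function(area) {
  stopifnot(length(area) == 1L, area > 0)
  side <- as.integer(clip(round(sqrt(area) / 12), 60, 120))
  n <- as.integer(clip(round(area / (7 * side^2)), 15, 25))
  if (area < 60^2 * 15)
    warning("liver area is small; the patch plan may be infeasible")
  structure(list(n_patches = n, side = side), class = "patch_plan")
}

#' Specular / shadow rejection rule for one patch
#'
#' A patch is accepted iff its mean luminance lies inside the liver's
#' interquartile range `[q1, q3]`. With `highlights_only = TRUE` only the
#' upper bound is enforced (rejecting bright specular patches but keeping
#' dark ones).
#'
#' @param patch_mean_L mean L* of the patch.
#' @param q1,q3 luminance quartiles of the whole masked liver.
#' @param highlights_only apply the rule one-sided.
#' @return `TRUE` if the patch is accepted.
#' @export
reject_specular <- function(patch_mean_L, q1, q3, highlights_only = FALSE) {
  stopifnot(q1 <= q3)
  if (highlights_only) patch_mean_L <= q3
  else patch_mean_L >= q1 & patch_mean_L <= q3
}

#' Sample accepted, non-overlapping patches inside the liver
#'
#' Draws candidate square patches uniformly over the mask's bounding box and
#' accepts a candidate when (i) every pixel of the square lies on the mask,
#' (ii) it does not overlap an already-accepted patch, and (iii) its mean
#' luminance passes [reject_specular()]. Rejected draws are replaced by new
#' random candidates until `plan$n_patches` are accepted or `max_attempts`
#' draws are spent. Deterministic given `seed`.
#'
#' @param mask a `liver_mask`.
#' @param lab the matching `lab_image`.
#' @param plan a `patch_plan` (default: [plan_patches()] of the mask area).
#' @param seed integer seed for the candidate stream.
#' @param min_patches fewer accepted patches than this is an error
#'   (default 8).
#' @param max_attempts cap on candidate draws (default `50 * n_patches`).
#' @param highlights_only passed to [reject_specular()].
#' @return A data.frame of accepted patches with columns `row`, `col`
#'   (1-based top-left corner), `side`, `mean_L`, plus attribute
#'   `"luminance_stats"`.
#' @export
sample_patches <- function(mask, lab, plan = NULL, seed = NULL,
                           min_patches = 8L, max_attempts = NULL,
                           highlights_only = FALSE) {
  stopifnot(inherits(mask, "liver_mask"), inherits(lab, "lab_image"))
  if (is.null(plan)) plan <- plan_patches(mask$area)
  side <- plan$side
  n_want <- plan$n_patches
  if (is.null(max_attempts)) max_attempts <- 50L * n_want
  lum <- luminance_stats(lab, mask$mask)

  Smask <- integral_image(mask$mask * 1)
  SL <- integral_image(lab$L)
  rows <- which(rowSums(mask$mask) > 0)
  cols <- which(colSums(mask$mask) > 0)
  r_lo <- min(rows); r_hi <- max(rows) - side + 1L
  c_lo <- min(cols); c_hi <- max(cols) - side + 1L
  if (r_hi < r_lo || c_hi < c_lo)
    stop("insufficient valid area: mask smaller than one patch")

  acc_r <- integer(0); acc_c <- integer(0); acc_L <- numeric(0)
  with_seed(seed, {
    attempts <- 0L
    while (length(acc_r) < n_want && attempts < max_attempts) {
      attempts <- attempts + 1L
      r <- sample.int(r_hi - r_lo + 1L, 1L) + r_lo - 1L
      cc <- sample.int(c_hi - c_lo + 1L, 1L) + c_lo - 1L
      # full containment: the square must cover side^2 mask pixels
      if (rect_sum(Smask, r, r + side - 1L, cc, cc + side - 1L) < side^2)
        next
      if (length(acc_r) > 0 &&
          any(abs(acc_r - r) < side & abs(acc_c - cc) < side))
        next
      mL <- rect_sum(SL, r, r + side - 1L, cc, cc + side - 1L) / side^2
      if (!reject_specular(mL, lum["q1"], lum["q3"], highlights_only))
        next
      acc_r <- c(acc_r, r); acc_c <- c(acc_c, cc); acc_L <- c(acc_L, mL)
    }
  })
  if (length(acc_r) < min_patches)
    stop(sprintf(
      "insufficient valid area: only %d of %d patches accepted",
      length(acc_r), n_want))
  out <- data.frame(row = acc_r, col = acc_c, side = side, mean_L = acc_L)
  attr(out, "luminance_stats") <- lum
  out
}

#' Extract the CIELAB pixels of one sampled patch
#'
#' @param lab a `lab_image`.
#' @param patch one row of the data.frame returned by [sample_patches()].
#' @return List with `L`, `a`, `b` side x side matrices.
#' @export
patch_pixels <- function(lab, patch) {
  r <- patch$row; cc <- patch$col; s <- patch$side
  list(L = lab$L[r:(r + s - 1L), cc:(cc + s - 1L)],
       a = lab$a[r:(r + s - 1L), cc:(cc + s - 1L)],
       b = lab$b[r:(r + s - 1L), cc:(cc + s - 1L)])
}
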