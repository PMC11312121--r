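# Synthetic liver cases with known ground-truth steatosis.
#
# Each case is a rendered operating-field scene in linear RGB — surgical
# drape background, an elliptical liver whose CIELAB colour and texture
# grain depend on the true steatosis fraction (HS), specular highlight
# discs, and a neutral grey card — distorted by a per-image illuminant
# (per-channel gains and an exposure factor) and finally gamma-encoded, as a
# phone camera would store it. Donor biochemistry is drawn with HS-linked
# effects so clinical covariates carry signal, and per-lobe biopsy readings
# add sampling noise around the true HS.

#' Configuration of the synthetic-case generator
#'
#' Defaults define the reference study conditions: a case mix with 28\%
#' high-steatosis donors (HS above 15\%), no livers above 60\% HS, colour
#' shifting toward yellow (higher b*, lower a*) with HS, texture grain
#' coarsening with HS, random illuminant tint and exposure per image, a
#' Poisson number of specular highlights, and donor biochemistry (ALT, AST,
#' BMI, GGT) increasing with HS while bilirubin, age and sex are
#' independent of it.
#'
#' @param n_cases number of donors/cases to generate.
#' @param image_size square image side in pixels (>= 512).
#' @param p_high probability of the high-HS mixture component.
#' @param hs_low_shape,hs_high_shape Beta shape pairs for the low component
#'   (scaled to \[0, 15\]) and high component (scaled to \[15, 60\]).
#' @param a_intercept,a_slope,b_intercept,b_slope liver chromaticity model:
#'   `a* = a_intercept + a_slope * HS`, `b* = b_intercept + b_slope * HS`.
#' @param chroma_sd per-case SD of the chromaticity noise (CIELAB units).
#' @param chroma_pixel_sd per-pixel SD of the chromaticity noise, giving
#'   a*/b* a fine non-degenerate texture.
#' @param liver_L,liver_L_sd mean liver lightness and its per-case SD.
#' @param grain_len_base,grain_len_slope texture correlation length
#'   `2 + 0.08 * HS` pixels (the mean relation).
#' @param grain_len_jitter_sd per-case lognormal jitter on the grain
#'   length, modelling biological variability of tissue texture.
#' @param grain_amp SD of the grain added to L*.
#' @param gain_range,exposure_range per-channel illuminant gain and global
#'   exposure, each drawn uniformly per image.
#' @param specular_rate Poisson mean of the number of highlight discs.
#' @param specular_L L* value inside a highlight disc.
#' @param specular_radius radius range (pixels) of highlight discs.
#' @param card_reflectance,card_size grey-card linear reflectance and side.
#' @param alt_slope,ast_slope,ggt_slope log-scale HS effects on ALT, AST,
#'   GGT; `bmi_slope` is on the natural scale.
#' @param lab_sd,bmi_sd covariate noise SDs (log scale for the enzymes).
#' @param biopsy_sd per-lobe biopsy sampling noise SD (HS percentage
#'   points).
#' @param surgeon_sd SD of the surgeon's visual HS estimate around truth.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_cases = 192L,
                             image_size = 768L,
                             p_high = 0.28,
                             hs_low_shape = c(1.0, 4.0),
                             hs_high_shape = c(1.6, 3.3),
                             a_intercept = 25, a_slope = -0.15,
                             b_intercept = 10, b_slope = 0.35,
                             chroma_sd = 2,
                             chroma_pixel_sd = 4,
                             liver_L = 48, liver_L_sd = 3,
                             grain_len_base = 2, grain_len_slope = 0.08,
                             grain_len_jitter_sd = 0.6,
                             grain_amp = 4,
                             gain_range = c(0.7, 1.3),
                             exposure_range = c(0.8, 1.2),
                             specular_rate = 2,
                             specular_L = 95,
                             specular_radius = c(8, 18),
                             card_reflectance = 0.18,
                             card_size = 64L,
                             alt_slope = 0.020, ast_slope = 0.012,
                             ggt_slope = 0.008, bmi_slope = 0.09,
                             lab_sd = 0.20, bmi_sd = 2.5,
                             biopsy_sd = 3, surgeon_sd = 10) {
  stopifnot(image_size >= 512L, p_high >= 0, p_high <= 1,
            card_reflectance > 0, card_reflectance < 1)
  structure(as.list(environment()), class = "generator_config")
}

#' Draw one donor record with HS-linked biochemistry
#'
#' True HS is drawn from the two-component mixture; covariates follow
#' log-linear (ALT, AST, GGT) or linear (BMI) effects of HS, with bilirubin,
#' age and sex independent of HS. Uses the ambient RNG stream.
#'
#' @param cfg a `generator_config`.
#' @param hs optional fixed true HS (\%); drawn from the mixture if `NULL`.
#' @return List with `donor` (covariate list) and `hs` (true HS \%).
#' @export
sample_donor <- function(cfg, hs = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(hs)) {
    high <- stats::runif(1) < cfg$p_high
    hs <- if (high)
      15 + 45 * stats::rbeta(1, cfg$hs_high_shape[1], cfg$hs_high_shape[2])
    else
      15 * stats::rbeta(1, cfg$hs_low_shape[1], cfg$hs_low_shape[2])
  }
  donor <- list(
    age = round(clip(stats::rnorm(1, 60, 12), 18, 88)),
    sex = if (stats::runif(1) < 0.62) "M" else "F",
    bmi = round(26 + cfg$bmi_slope * hs + stats::rnorm(1, 0, cfg$bmi_sd), 1),
    ast = round(exp(log(35) + cfg$ast_slope * hs +
                      stats::rnorm(1, 0, cfg$lab_sd)), 1),
    alt = round(exp(log(30) + cfg$alt_slope * hs +
                      stats::rnorm(1, 0, cfg$lab_sd)), 1),
    ggt = round(exp(log(40) + cfg$ggt_slope * hs +
                      stats::rnorm(1, 0, cfg$lab_sd)), 1),
    bilirubin = round(exp(stats::rnorm(1, log(0.5), 0.4)), 2)
  )
  list(donor = donor, hs = hs)
}

# Rotated-ellipse mask on an H x W grid. Column-recycled vector arithmetic
# keeps this O(h*w) with no intermediate index grids.
.ellipse_mask <- function(h, w, cy, cx, ay, ax, theta) {
  dyv <- seq_len(h) - cy
  dxv <- seq_len(w) - cx
  u <- matrix(dxv * cos(theta), h, w, byrow = TRUE) + dyv * sin(theta)
  v <- matrix(-dxv * sin(theta), h, w, byrow = TRUE) + dyv * cos(theta)
  (u / ax)^2 + (v / ay)^2 <= 1
}

# Smoothed unit-variance noise field with Gaussian correlation length `len`:
# white noise convolved with a separable Gaussian kernel (circular edges,
# harmless for noise), then restandardized.
.grain_field <- function(h, w, len) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (len > 0.5) {
    half <- max(1L, ceiling(3 * len))
    k <- stats::dnorm(seq(-half, half), sd = len)
    k <- k / sum(k)
    z <- stats::filter(z, k, circular = TRUE)
    z <- t(stats::filter(t(z), k, circular = TRUE))
  }
  s <- stats::sd(z)
  if (s > 0) z <- z / s
  matrix(z, h, w)
}

#' Render one synthetic liver case
#'
#' Composes the scene in CIELAB, converts to linear RGB, plants the grey
#' card at an exact linear reflectance, applies the per-image illuminant
#' (per-channel gains and exposure), clips, and gamma-encodes. Uses the
#' ambient RNG stream; wrap in a seeded context for reproducibility.
#'
#' @param cfg a `generator_config`.
#' @param donor donor covariate list (from [sample_donor()]).
#' @param hs true HS (\%).
#' @param case_id identifier stored on the case.
#' @param lighting `TRUE` to draw random gains/exposure, or a list
#'   `list(gains = c(r, g, b), exposure = e)` to fix them (use
#'   `list(gains = c(1, 1, 1), exposure = 1)` for a distortion-free render).
#' @param keep_scene also return the pre-lighting linear scene (for
#'   calibration-recovery checks).
#' @return A `synthetic_case`: list with `case_id`, `donor`, `hs_true`,
#'   `image` (gamma-encoded `rgb_image`), `mask` (`liver_mask`), `card_roi`
#'   (`c(x, y, w, h)`, 0-based), `biopsy_hs_left`, `biopsy_hs_right`,
#'   `surgeon_hs`, and `truth` (ellipse, blobs, gains, exposure, optional
#'   `scene`).
#' @export
render_case <- function(cfg, donor, hs, case_id = "case",
                        lighting = TRUE, keep_scene = FALSE) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$image_size
  cy <- n / 2 + stats::runif(1, -15, 15)
  cx <- n / 2 + stats::runif(1, -15, 15)
  ax <- stats::runif(1, 0.33, 0.39) * n
  ay <- stats::runif(1, 0.24, 0.30) * n
  theta <- stats::runif(1, -pi / 9, pi / 9)

  # liver bounding box (rotated-ellipse extents); composition is done on
  # the box only, the drape outside is a constant colour
  ext_x <- sqrt((ax * cos(theta))^2 + (ay * sin(theta))^2)
  ext_y <- sqrt((ax * sin(theta))^2 + (ay * cos(theta))^2)
  r0 <- max(1L, floor(cy - ext_y)); r1 <- min(n, ceiling(cy + ext_y))
  c0 <- max(1L, floor(cx - ext_x)); c1 <- min(n, ceiling(cx + ext_x))
  bh <- r1 - r0 + 1L; bw <- c1 - c0 + 1L
  sub <- .ellipse_mask(bh, bw, cy - r0 + 1, cx - c0 + 1, ay, ax, theta)
  liver <- matrix(FALSE, n, n)
  liver[r0:r1, c0:c1] <- sub

  # CIELAB composition on the box: liver colour model, grain, blobs
  a_case <- cfg$a_intercept + cfg$a_slope * hs + stats::rnorm(1, 0, cfg$chroma_sd)
  b_case <- cfg$b_intercept + cfg$b_slope * hs + stats::rnorm(1, 0, cfg$chroma_sd)
  L_case <- cfg$liver_L + stats::rnorm(1, 0, cfg$liver_L_sd)
  len <- (cfg$grain_len_base + cfg$grain_len_slope * hs) *
    exp(stats::rnorm(1, 0, cfg$grain_len_jitter_sd))
  grain <- .grain_field(bh, bw, len)
  L <- L_case + cfg$grain_amp * grain
  a <- matrix(a_case + stats::rnorm(bh * bw, 0, cfg$chroma_pixel_sd), bh, bw)
  b <- matrix(b_case + stats::rnorm(bh * bw, 0, cfg$chroma_pixel_sd), bh, bw)

  n_blob <- stats::rpois(1, cfg$specular_rate)
  blobs <- NULL
  if (n_blob > 0) {
    idx <- which(sub)
    ctr <- idx[sample.int(length(idx), n_blob, replace = TRUE)]
    br <- ((ctr - 1L) %% bh) + 1L
    bc <- ((ctr - 1L) %/% bh) + 1L
    rad <- stats::runif(n_blob, cfg$specular_radius[1], cfg$specular_radius[2])
    for (i in seq_len(n_blob)) {
      disc <- .ellipse_mask(bh, bw, br[i], bc[i], rad[i], rad[i], 0) & sub
      L[disc] <- cfg$specular_L
      a[disc] <- 0
      b[disc] <- 0
    }
    blobs <- data.frame(row = br + r0 - 1L, col = bc + c0 - 1L, radius = rad)
  }

  lab_box <- structure(list(L = L, a = a, b = b, whitepoint = "D65"),
                       class = "lab_image")
  box_rgb <- lab_to_rgb(lab_box)$pixels
  drape_rgb <- lab_to_rgb(structure(
    list(L = matrix(35, 1, 1), a = matrix(-20, 1, 1), b = matrix(-5, 1, 1),
         whitepoint = "D65"), class = "lab_image"))$pixels
  scene <- array(rep(as.numeric(drape_rgb), each = n * n), c(n, n, 3L))
  for (k in 1:3) {
    pane <- scene[r0:r1, c0:c1, k]
    pane[sub] <- box_rgb[, , k][sub]
    scene[r0:r1, c0:c1, k] <- pane
  }

  # grey card: exact linear reflectance, in a corner clear of the liver
  cs <- cfg$card_size
  marg <- 16L
  corners <- list(c(marg, marg), c(marg, n - marg - cs),
                  c(n - marg - cs, marg), c(n - marg - cs, n - marg - cs))
  card_roi <- NULL
  for (co in corners) {
    rr <- (co[1] + 1L):(co[1] + cs)
    ccc <- (co[2] + 1L):(co[2] + cs)
    pad <- 8L
    rr2 <- max(1L, co[1] - pad + 1L):min(n, co[1] + cs + pad)
    cc2 <- max(1L, co[2] - pad + 1L):min(n, co[2] + cs + pad)
    if (!any(liver[rr2, cc2])) {
      scene[rr, ccc, ] <- cfg$card_reflectance
      card_roi <- c(x = co[2], y = co[1], w = cs, h = cs)  # 0-based
      break
    }
  }
  if (is.null(card_roi)) stop("could not place the grey card clear of the liver")

  if (isTRUE(lighting)) {
    lighting <- list(gains = stats::runif(3, cfg$gain_range[1], cfg$gain_range[2]),
                     exposure = stats::runif(1, cfg$exposure_range[1],
                                             cfg$exposure_range[2]))
  } else if (isFALSE(lighting)) {
    lighting <- list(gains = c(1, 1, 1), exposure = 1)
  }
  lit <- scene
  for (k in 1:3) lit[, , k] <- lit[, , k] * lighting$gains[k] * lighting$exposure
  lit <- clip(lit, 0, 1)
  image <- srgb_encode(rgb_image(lit, "linear"), 2.2)

  truth <- list(hs = hs,
                ellipse = list(cy = cy, cx = cx, ay = ay, ax = ax,
                               theta = theta),
                blobs = blobs,
                gains = lighting$gains, exposure = lighting$exposure,
                a_case = a_case, b_case = b_case, L_case = L_case)
  if (keep_scene) truth$scene <- rgb_image(scene, "linear")

  structure(list(
    case_id = case_id,
    donor = donor,
    hs_true = hs,
    image = image,
    mask = as_liver_mask(liver, source = "truth"),
    card_roi = card_roi,
    biopsy_hs_left = clip(hs + stats::rnorm(1, 0, cfg$biopsy_sd), 0, 100),
    biopsy_hs_right = clip(hs + stats::rnorm(1, 0, cfg$biopsy_sd), 0, 100),
    surgeon_hs = clip(hs + stats::rnorm(1, 0, cfg$surgeon_sd), 0, 100),
    truth = truth
  ), class = "synthetic_case")
}

#' Generate a full synthetic dataset
#'
#' Draws `cfg$n_cases` donors i.i.d. and renders one photograph per case.
#' Deterministic given `seed`. When `dir` is given, the images and masks are
#' written as PNGs and a manifest CSV (with truth columns) is written
#' alongside; otherwise cases are kept in memory.
#'
#' @param cfg a `generator_config`.
#' @param seed integer seed.
#' @param dir optional output directory.
#' @param lighting passed to [render_case()] (default `TRUE`: random
#'   illuminant per image).
#' @param keep_scene passed to [render_case()].
#' @param progress print a dot per rendered case.
#' @return List with `cases` (list of `synthetic_case`) and `manifest`
#'   (data.frame).
#' @export
make_dataset <- function(cfg, seed = 1L, dir = NULL, lighting = TRUE,
                         keep_scene = FALSE, progress = FALSE) {
  stopifnot(inherits(cfg, "generator_config"))
  cases <- vector("list", cfg$n_cases)
  with_seed(seed, {
    for (i in seq_len(cfg$n_cases)) {
      d <- sample_donor(cfg)
      id <- sprintf("case_%03d", i)
      cases[[i]] <- render_case(cfg, d$donor, d$hs, case_id = id,
                                lighting = lighting, keep_scene = keep_scene)
      if (progress) cat(".")
    }
  })
  if (progress && cfg$n_cases > 0) cat("\n")
  manifest <- if (cfg$n_cases > 0)
    do.call(rbind, lapply(cases, manifest_row)) else
      data.frame()
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (cs in cases) {
      write_photo(cs$image, file.path(dir, paste0(cs$case_id, ".png")))
      write_mask(cs$mask, file.path(dir, paste0(cs$case_id, "_mask.png")))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(cases = cases, manifest = manifest)
}

manifest_row <- function(cs) {
  data.frame(
    donor_id = cs$case_id,
    image = paste0(cs$case_id, ".png"),
    mask = paste0(cs$case_id, "_mask.png"),
    card_x = cs$card_roi[["x"]], card_y = cs$card_roi[["y"]],
    card_w = cs$card_roi[["w"]], card_h = cs$card_roi[["h"]],
    age = cs$donor$age, sex = cs$donor$sex, bmi = cs$donor$bmi,
    ast = cs$donor$ast, alt = cs$donor$alt, ggt = cs$donor$ggt,
    bilirubin = cs$donor$bilirubin,
    biopsy_hs_left = cs$biopsy_hs_left,
    biopsy_hs_right = cs$biopsy_hs_right,
    surgeon_hs = cs$surgeon_hs,
    hs_true = cs$hs_true,
    stringsAsFactors = FALSE
  )
}
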