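# Glue from photographs to patch feature matrices.
#
# Image-derived features (colour + texture histograms) are extracted once
# per case; the clinical covariate block is appended at training time so its
# standardization statistics come from training donors only.

#' Extract image-derived patch features for one case
#'
#' Calibrates the photograph (gamma decode, grey-card white balance),
#' converts to CIELAB, samples accepted patches, and computes the colour and
#' LBP histograms of each. With `calibrate = FALSE` the stored pixel values
#' are used as-is (no linearisation, no white balance) — the degraded
#' pipeline used in calibration ablation experiments.
#'
#' @param case a `synthetic_case`, or any list with `image` (`rgb_image`),
#'   `card_roi`, and `mask` (`liver_mask`).
#' @param fcfg a `feature_config` (its clinical flag is ignored here).
#' @param calibrate apply gamma decoding and white balancing.
#' @param seed patch-sampling seed.
#' @return Matrix (patches x features) with attribute `"patches"` (the
#'   sampled patch table).
#' @export
extract_patch_features <- function(case, fcfg = feature_config(),
                                   calibrate = TRUE, seed = NULL) {
  img <- case$image
  if (is.character(img)) img <- read_photo(img)
  if (calibrate) {
    cal <- calibrate_photo(img, case$card_roi)
    lab <- cal$lab
  } else {
    # skip corrections: treat encoded pixels as if they were linear
    lab <- rgb_to_lab(rgb_image(img$pixels, "linear"))
  }
  mask <- case$mask
  if (is.character(mask)) mask <- load_mask(mask, dim(img$pixels))
  patches <- sample_patches(mask, lab, plan_patches(mask$area), seed = seed)
  feats <- t(vapply(seq_len(nrow(patches)), function(i) {
    build_features(patch_pixels(lab, patches[i, ]), fcfg)
  }, numeric(feature_length(feature_config(fcfg$colour_bins, FALSE,
                                           fcfg$lbp_channels)))))
  attr(feats, "patches") <- patches
  feats
}

#' Build a patch-level dataset from a list of cases
#'
#' @param cases list of cases (see [extract_patch_features()]), each also
#'   carrying `case_id`, `donor`, biopsy fields and optionally
#'   `surgeon_hs`.
#' @param fcfg a `feature_config`.
#' @param calibrate apply the calibration pipeline (see
#'   [extract_patch_features()]).
#' @param seed base seed; case `i` samples patches with `seed + i`.
#' @param progress print a dot per case.
#' @return A `patch_dataset`: list with `img_features` (matrix), `case_id`
#'   (per patch), `cases` (per-case data.frame with donor covariates,
#'   biopsies, surgeon estimate), and `fcfg`.
#' @export
build_patch_dataset <- function(cases, fcfg = feature_config(),
                                calibrate = TRUE, seed = 1L,
                                progress = FALSE) {
  feats <- vector("list", length(cases))
  ids <- vector("list", length(cases))
  rows <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    f <- extract_patch_features(cs, fcfg, calibrate = calibrate,
                                seed = seed + i)
    feats[[i]] <- f
    ids[[i]] <- rep(cs$case_id, nrow(f))
    rows[[i]] <- data.frame(
      case_id = cs$case_id,
      donor_id = if (!is.null(cs$donor_id)) cs$donor_id else cs$case_id,
      age = cs$donor$age, sex = cs$donor$sex, bmi = cs$donor$bmi,
      ast = cs$donor$ast, alt = cs$donor$alt, ggt = cs$donor$ggt,
      bilirubin = cs$donor$bilirubin,
      biopsy_hs_left = cs$biopsy_hs_left,
      biopsy_hs_right = cs$biopsy_hs_right,
      surgeon_hs = if (!is.null(cs$surgeon_hs)) cs$surgeon_hs else NA_real_,
      stringsAsFactors = FALSE)
    if (progress) cat(".")
  }
  if (progress && length(cases) > 0) cat("\n")
  structure(list(img_features = do.call(rbind, feats),
                 case_id = unlist(ids),
                 cases = do.call(rbind, rows),
                 fcfg = fcfg),
            class = "patch_dataset")
}

#' Render a synthetic cohort and extract patch features case by case
#'
#' Streaming counterpart of [make_dataset()] + [build_patch_dataset()]:
#' each case is rendered, its features extracted under one or more
#' calibration conditions, and its pixels discarded before the next case,
#' so cohort size is not limited by image memory. Given the same `cfg` and
#' `seed`, the rendered cases are identical to [make_dataset()]'s.
#'
#' @param cfg a `generator_config`.
#' @param seed dataset seed (drives donors and rendering).
#' @param fcfg a `feature_config`.
#' @param calibrate logical vector of calibration conditions to extract
#'   (e.g. `c(TRUE, FALSE)` for the calibrated and uncalibrated pipelines).
#' @param patch_seed base seed for patch sampling (case `i` uses
#'   `patch_seed + i`, as in [build_patch_dataset()]).
#' @param progress print a dot per case.
#' @return A named list of `patch_dataset` objects, one per calibration
#'   condition (`"calibrated"` / `"uncalibrated"`), each also carrying the
#'   cohort `manifest` as an attribute.
#' @export
synthetic_patch_dataset <- function(cfg, seed = 1L,
                                    fcfg = feature_config(),
                                    calibrate = TRUE, patch_seed = 1L,
                                    progress = FALSE) {
  stopifnot(inherits(cfg, "generator_config"))
  cond_names <- ifelse(calibrate, "calibrated", "uncalibrated")
  feats <- lapply(calibrate, function(.) vector("list", cfg$n_cases))
  names(feats) <- cond_names
  rows <- vector("list", cfg$n_cases)
  ids <- vector("list", cfg$n_cases)
  with_seed(seed, {
    for (i in seq_len(cfg$n_cases)) {
      dn <- sample_donor(cfg)
      cs <- render_case(cfg, dn$donor, dn$hs,
                        case_id = sprintf("case_%03d", i))
      for (k in seq_along(calibrate)) {
        f <- extract_patch_features(cs, fcfg, calibrate = calibrate[k],
                                    seed = patch_seed + i)
        attr(f, "patches") <- NULL
        feats[[k]][[i]] <- f
      }
      ids[[i]] <- rep(cs$case_id, nrow(feats[[1]][[i]]))
      rows[[i]] <- manifest_row(cs)
      if (progress) cat(".")
    }
  })
  if (progress && cfg$n_cases > 0) cat("\n")
  manifest <- do.call(rbind, rows)
  cases <- data.frame(
    case_id = manifest$donor_id, donor_id = manifest$donor_id,
    manifest[c("age", "sex", "bmi", "ast", "alt", "ggt", "bilirubin",
               "biopsy_hs_left", "biopsy_hs_right", "surgeon_hs")],
    stringsAsFactors = FALSE)
  out <- lapply(seq_along(calibrate), function(k) {
    ds <- structure(list(img_features = do.call(rbind, feats[[k]]),
                         case_id = unlist(ids),
                         cases = cases,
                         fcfg = fcfg),
                    class = "patch_dataset")
    attr(ds, "manifest") <- manifest
    ds
  })
  names(out) <- cond_names
  out
}

#' Load a dataset written by [make_dataset()] from disk
#'
#' Reads the manifest CSV and reconstitutes the case list with images and
#' masks loaded lazily as paths.
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return List of case lists suitable for [build_patch_dataset()].
#' @export
load_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    r <- man[i, ]
    img <- read_photo(file.path(dir, r$image))
    list(case_id = r$donor_id, donor_id = r$donor_id,
         image = img,
         mask = load_mask(file.path(dir, r$mask), dim(img$pixels)),
         card_roi = c(x = r$card_x, y = r$card_y, w = r$card_w, h = r$card_h),
         donor = list(age = r$age, sex = r$sex, bmi = r$bmi, ast = r$ast,
                      alt = r$alt, ggt = r$ggt, bilirubin = r$bilirubin),
         biopsy_hs_left = r$biopsy_hs_left,
         biopsy_hs_right = r$biopsy_hs_right,
         surgeon_hs = r$surgeon_hs)
  })
}
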