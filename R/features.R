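# Per-patch features: CIELAB colour histograms and local-binary-pattern
# (LBP) texture histograms, optionally concatenated with standardized donor
# covariates.

#' Feature configuration
#'
#' @param colour_bins bins per CIELAB channel histogram (default 32).
#' @param use_clinical append the standardized donor covariate block.
#' @param lbp_channels CIELAB channels on which LBP texture is computed.
#' @return A `feature_config` list. Channel ranges are fixed at
#'   L \[0, 100\], a*/b* \[-128, 127\]; LBP histograms have 256 bins (raw
#'   8-neighbour codes).
#' @export
feature_config <- function(colour_bins = 32L, use_clinical = FALSE,
                           lbp_channels = c("L", "a", "b")) {
  stopifnot(colour_bins >= 2L)
  lbp_channels <- match.arg(lbp_channels, c("L", "a", "b"),
                            several.ok = TRUE)
  structure(list(colour_bins = as.integer(colour_bins),
                 lbp_bins = 256L,
                 channel_ranges = list(L = c(0, 100), a = c(-128, 127),
                                       b = c(-128, 127)),
                 use_clinical = isTRUE(use_clinical),
                 lbp_channels = lbp_channels),
            class = "feature_config")
}

#' Normalized histogram of one CIELAB channel
#'
#' Equal-width bins on a fixed channel range; values outside the range are
#' clipped into the edge bins; counts are normalized to sum 1.
#'
#' @param values numeric vector of channel values (non-empty).
#' @param range `c(lo, hi)` fixed binning range.
#' @param bins number of bins (>= 2).
#' @return Numeric simplex vector of length `bins`.
#' @export
lab_histogram <- function(values, range, bins) {
  if (length(values) == 0L) stop("empty channel input")
  stopifnot(bins >= 2L, range[2] > range[1])
  idx <- floor((values - range[1]) / (range[2] - range[1]) * bins) + 1
  idx <- clip(idx, 1, bins)
  tabulate(idx, nbins = bins) / length(values)
}

#' 8-neighbour local binary pattern codes
#'
#' Classic radius-1 LBP: for each interior pixel, bit `i` (weight `2^i`) is
#' set iff the `i`-th neighbour is `>=` the centre value, neighbours ordered
#' clockwise starting from the top-left diagonal. The one-pixel border is
#' excluded.
#'
#' @param channel numeric side x side matrix (side >= 3).
#' @return Integer (side-2) x (side-2) matrix of codes in \[0, 255\].
#' @export
lbp_codes <- function(channel) {
  stopifnot(is.matrix(channel))
  n <- nrow(channel); m <- ncol(channel)
  if (n < 3L || m < 3L) stop("LBP needs at least a 3 x 3 patch")
  ctr <- channel[2:(n - 1L), 2:(m - 1L)]
  offs <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, 1L),
               c(1L, 1L), c(1L, 0L), c(1L, -1L), c(0L, -1L))
  code <- matrix(0L, n - 2L, m - 2L)
  for (i in seq_along(offs)) {
    dr <- offs[[i]][1]; dc <- offs[[i]][2]
    nb <- channel[(2L + dr):(n - 1L + dr), (2L + dc):(m - 1L + dc)]
    code <- code + bitwShiftL(1L, i - 1L) * (nb >= ctr)
  }
  code
}

#' Normalized 256-bin histogram of LBP codes
#'
#' @param codes integer matrix/vector of codes in \[0, 255\].
#' @return Numeric simplex vector of length 256.
#' @export
lbp_histogram <- function(codes) {
  codes <- as.vector(codes)
  if (length(codes) == 0L) stop("empty code input")
  tabulate(codes + 1L, nbins = 256L) / length(codes)
}

# Donor covariates used by the model, in fixed order.
.clinical_vars <- c("age", "sex", "bmi", "ast", "alt", "ggt", "bilirubin")

#' Fit the clinical standardization scaler on training donors
#'
#' Records, per covariate, the training median (also the imputation value
#' for missing entries) and standard deviation. Sex is encoded 0 = F,
#' 1 = M before scaling. Fitting on training donors only keeps test-set
#' statistics out of the model.
#'
#' @param donors data.frame with columns `age, sex, bmi, ast, alt, ggt,
#'   bilirubin` (one row per training donor).
#' @return A `clinical_scaler`.
#' @export
fit_clinical_scaler <- function(donors) {
  x <- encode_clinical(donors)
  ctr <- apply(x, 2L, stats::median, na.rm = TRUE)
  scl <- apply(x, 2L, stats::sd, na.rm = TRUE)
  scl[!is.finite(scl) | scl == 0] <- 1
  structure(list(center = ctr, scale = scl), class = "clinical_scaler")
}

# Donor data.frame -> numeric matrix in .clinical_vars order; sex to 0/1.
encode_clinical <- function(donors) {
  miss <- setdiff(.clinical_vars, names(donors))
  if (length(miss) > 0)
    stop("donor record lacks columns: ", paste(miss, collapse = ", "))
  sex <- donors$sex
  if (!is.numeric(sex)) sex <- as.numeric(toupper(as.character(sex)) == "M")
  m <- cbind(age = as.numeric(donors$age), sex = sex,
             bmi = as.numeric(donors$bmi), ast = as.numeric(donors$ast),
             alt = as.numeric(donors$alt), ggt = as.numeric(donors$ggt),
             bilirubin = as.numeric(donors$bilirubin))
  m
}

#' Standardize one donor's covariates
#'
#' @param donor single-row data.frame (or list) of donor covariates.
#' @param scaler a `clinical_scaler` fitted on training donors.
#' @return Named numeric vector of length 7; missing values imputed with
#'   the training medians before scaling.
#' @export
scale_clinical <- function(donor, scaler) {
  stopifnot(inherits(scaler, "clinical_scaler"))
  x <- encode_clinical(as.data.frame(donor, stringsAsFactors = FALSE))[1, ]
  nas <- is.na(x)
  x[nas] <- scaler$center[nas]
  (x - scaler$center) / scaler$scale
}

#' Assemble the feature vector of one patch
#'
#' Concatenates the three CIELAB colour histograms, the LBP histograms of
#' the configured channels, and (optionally) the standardized clinical
#' block: `3 * colour_bins + length(lbp_channels) * 256 (+ 7)` features.
#'
#' @param pixels patch pixels from [patch_pixels()] (list `L`, `a`, `b`).
#' @param cfg a `feature_config`.
#' @param donor donor covariates (required when `cfg$use_clinical`).
#' @param scaler `clinical_scaler` (required when `cfg$use_clinical`).
#' @return Named numeric feature vector.
#' @export
build_features <- function(pixels, cfg, donor = NULL, scaler = NULL) {
  stopifnot(inherits(cfg, "feature_config"))
  nb <- cfg$colour_bins
  rng <- cfg$channel_ranges
  col <- c(lab_histogram(pixels$L, rng$L, nb),
           lab_histogram(pixels$a, rng$a, nb),
           lab_histogram(pixels$b, rng$b, nb))
  names(col) <- paste0(rep(c("colL", "cola", "colb"), each = nb),
                       "_", seq_len(nb))
  tex <- unlist(lapply(cfg$lbp_channels, function(ch) {
    h <- lbp_histogram(lbp_codes(pixels[[ch]]))
    names(h) <- paste0("lbp", ch, "_", 0:255)
    h
  }))
  out <- c(col, tex)
  if (cfg$use_clinical) {
    if (is.null(donor) || is.null(scaler))
      stop("clinical features requested but donor or scaler is missing")
    cl <- scale_clinical(donor, scaler)
    names(cl) <- paste0("clin_", .clinical_vars)
    out <- c(out, cl)
  }
  out
}

#' Number of features implied by a configuration
#'
#' @param cfg a `feature_config`.
#' @return Integer feature-vector length.
#' @export
feature_length <- function(cfg) {
  3L * cfg$colour_bins + length(cfg$lbp_channels) * cfg$lbp_bins +
    if (cfg$use_clinical) 7L else 0L
}
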