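# Shared fixtures. Rendered cases are cached per test run so several test
# files can reuse them without re-rendering.

.fixture_env <- new.env(parent = emptyenv())

# A small rendered dataset (512 px images) with deterministic content.
small_dataset <- function(n = 6L, seed = 11L, lighting = TRUE,
                          keep_scene = FALSE) {
  key <- paste0("ds_", n, "_", seed, "_", lighting, "_", keep_scene)
  if (is.null(.fixture_env[[key]])) {
    cfg <- generator_config(n_cases = n, image_size = 512L)
    .fixture_env[[key]] <- make_dataset(cfg, seed = seed,
                                        lighting = lighting,
                                        keep_scene = keep_scene)
  }
  .fixture_env[[key]]
}

# Uniform grey rgb_image.
flat_image <- function(value = 0.5, h = 8L, w = 8L,
                       encoding = "linear") {
  rgb_image(array(value, c(h, w, 3L)), encoding)
}

# A patch_dataset built directly from synthetic feature vectors: `n_cases`
# cases, `n_patch` patches each, with `k_informative` feature columns equal
# to the case label plus noise. No images involved; used for classifier
# mechanics where rendering would be wasted effort.
toy_patch_dataset <- function(n_cases = 40L, n_patch = 8L, d = 20L,
                              k_informative = 3L, noise_sd = 0.1,
                              p_high = 0.3, seed = 5L,
                              label_signal = TRUE) {
  set.seed(seed)
  hs <- ifelse(runif(n_cases) < p_high, runif(n_cases, 20, 50),
               runif(n_cases, 0, 10))
  ids <- sprintf("d%03d", seq_len(n_cases))
  cases <- data.frame(
    case_id = ids, donor_id = ids,
    age = round(runif(n_cases, 30, 80)),
    sex = sample(c("M", "F"), n_cases, replace = TRUE),
    bmi = round(26 + 0.09 * hs + rnorm(n_cases, 0, 2), 1),
    ast = round(exp(log(35) + 0.012 * hs + rnorm(n_cases, 0, 0.2)), 1),
    alt = round(exp(log(30) + 0.020 * hs + rnorm(n_cases, 0, 0.2)), 1),
    ggt = round(exp(log(40) + 0.008 * hs + rnorm(n_cases, 0, 0.2)), 1),
    bilirubin = round(exp(rnorm(n_cases, log(0.5), 0.4)), 2),
    biopsy_hs_left = pmax(0, hs + rnorm(n_cases, 0, 1)),
    biopsy_hs_right = pmax(0, hs + rnorm(n_cases, 0, 1)),
    surgeon_hs = pmax(0, hs + rnorm(n_cases, 0, 8)),
    stringsAsFactors = FALSE)
  lab <- as.integer(hs > 15)
  x <- matrix(rnorm(n_cases * n_patch * d, 0, 1), n_cases * n_patch, d)
  if (label_signal && k_informative > 0) {
    sig <- rep(lab, each = n_patch)
    for (j in seq_len(k_informative))
      x[, j] <- sig + rnorm(length(sig), 0, noise_sd)
  }
  colnames(x) <- paste0("f", seq_len(d))
  structure(list(img_features = x,
                 case_id = rep(ids, each = n_patch),
                 cases = cases,
                 fcfg = feature_config()),
            class = "patch_dataset")
}
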