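# Patch-level classifiers (class-weighted random forest / RBF SVM) with
# donor-level stratified splits and nested cross-validation.

.label_levels <- c("valid", "non_valid")

#' Model configuration
#'
#' @param classifier `"random_forest"` or `"margin_svm"`.
#' @param hs_threshold HS decision threshold in percent (15 or 30 in
#'   practice; any value in (0, 100) is accepted).
#' @param feature_set `"image"` (colour + texture only), `"both"` (image +
#'   clinical), or `"clinical"` (covariates only).
#' @param lobe_rule how the two lobe biopsies combine into a case HS:
#'   `"mean"` (default) or `"max"`.
#' @param grid hyperparameter grid (data.frame); `NULL` uses the default
#'   grid for the classifier (forest: trees 100/300, depth unlimited/10,
#'   mtry sqrt/log2; SVM: cost 0.1/1/10, kernel width 0.5/1/2 times the
#'   median heuristic).
#' @param fraction_threshold liver-level aggregation threshold (see
#'   [aggregate_patches()]).
#' @param test_fraction outer split test share (default 0.30).
#' @param inner_fraction inner split validation share (default 0.10).
#' @param outer_repeats number of outer stratified shuffle splits.
#' @param seed base seed for splits and fits.
#' @return A `model_config` list.
#' @export
model_config <- function(classifier = c("random_forest", "margin_svm"),
                         hs_threshold = 15,
                         feature_set = c("image", "both", "clinical"),
                         lobe_rule = c("mean", "max"),
                         grid = NULL,
                         fraction_threshold = 0.20,
                         test_fraction = 0.30,
                         inner_fraction = 0.10,
                         outer_repeats = 10L,
                         seed = 1L) {
  classifier <- match.arg(classifier)
  feature_set <- match.arg(feature_set)
  lobe_rule <- match.arg(lobe_rule)
  stopifnot(hs_threshold > 0, hs_threshold < 100,
            fraction_threshold > 0, fraction_threshold <= 1)
  if (is.null(grid)) grid <- default_grid(classifier)
  structure(list(classifier = classifier, hs_threshold = hs_threshold,
                 feature_set = feature_set, lobe_rule = lobe_rule,
                 grid = grid, fraction_threshold = fraction_threshold,
                 test_fraction = test_fraction,
                 inner_fraction = inner_fraction,
                 outer_repeats = as.integer(outer_repeats),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Default hyperparameter grid for a classifier
#'
#' @param classifier `"random_forest"` or `"margin_svm"`.
#' @return data.frame of grid points.
#' @export
default_grid <- function(classifier) {
  if (classifier == "random_forest")
    expand.grid(num_trees = c(100L, 300L), max_depth = c(0L, 10L),
                mtry_rule = c("sqrt", "log2"), stringsAsFactors = FALSE)
  else
    expand.grid(cost = c(0.1, 1, 10), gamma_mult = c(0.5, 1, 2),
                stringsAsFactors = FALSE)
}

#' Ground-truth validity label of one case
#'
#' The case HS is the mean (or max) of the available lobe biopsies; the case
#' is `non_valid` when it exceeds the threshold, `valid` otherwise
#' (HS equal to the threshold is valid).
#'
#' @param case_row list/row with `biopsy_hs_left` and/or `biopsy_hs_right`.
#' @param threshold HS threshold in percent.
#' @param lobe_rule `"mean"` or `"max"`.
#' @return Factor level `"valid"` or `"non_valid"`.
#' @export
make_label <- function(case_row, threshold, lobe_rule = c("mean", "max")) {
  lobe_rule <- match.arg(lobe_rule)
  hs <- c(case_row$biopsy_hs_left, case_row$biopsy_hs_right)
  hs <- hs[!is.na(hs)]
  if (length(hs) == 0L) stop("case has no biopsy value")
  hs_case <- if (lobe_rule == "mean") mean(hs) else max(hs)
  factor(if (hs_case > threshold) "non_valid" else "valid",
         levels = .label_levels)
}

case_labels <- function(cases, threshold, lobe_rule = "mean") {
  labs <- vapply(seq_len(nrow(cases)), function(i)
    as.character(make_label(cases[i, ], threshold, lobe_rule)), "")
  stats::setNames(factor(labs, levels = .label_levels), cases$case_id)
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (2 * N_c)`, so the minority class is up-weighted and a
#' balanced set gets unit weights.
#'
#' @param labels factor of class labels (both classes present).
#' @return Named numeric vector of per-class weights.
#' @export
class_weights <- function(labels) {
  labels <- factor(labels, levels = .label_levels)
  n_c <- table(labels)
  if (any(n_c == 0)) stop("both classes must be present to weight them")
  w <- as.numeric(length(labels) / (2 * n_c))
  stats::setNames(w, names(n_c))
}

#' Stratified donor-level train/test split
#'
#' Samples `round(test_fraction * n_c)` donors of each class into the test
#' set (at least one, at most `n_c - 1`), so class proportions are preserved
#' and no donor ever appears on both sides. Deterministic given `seed`.
#'
#' @param donor_labels factor of case labels named by donor id (one entry
#'   per donor).
#' @param test_fraction share of donors per class sent to the test side.
#' @param seed integer seed.
#' @return List with `train` and `test` character vectors of donor ids.
#' @export
split_donors <- function(donor_labels, test_fraction = 0.30, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  donors <- names(donor_labels)
  if (is.null(donors)) stop("donor_labels must be named by donor id")
  test <- character(0)
  with_seed(seed, {
    for (cl in levels(factor(donor_labels))) {
      ids <- donors[donor_labels == cl]
      if (length(ids) < 2L)
        stop("each class needs at least 2 donors to stratify")
      k <- round(test_fraction * length(ids))
      k <- max(1L, min(length(ids) - 1L, k))
      test <- c(test, ids[sample.int(length(ids), k)])
    }
  })
  list(train = setdiff(donors, test), test = sort(test))
}

# Feature matrix for the given patch rows; clinical block scaled with a
# scaler fitted elsewhere (training donors only).
assemble_features <- function(ds, rows, feature_set, scaler = NULL) {
  parts <- list()
  if (feature_set %in% c("image", "both"))
    parts$img <- ds$img_features[rows, , drop = FALSE]
  if (feature_set %in% c("clinical", "both")) {
    stopifnot(!is.null(scaler))
    ci <- match(ds$case_id[rows], ds$cases$case_id)
    cl <- t(vapply(ci, function(i)
      scale_clinical(ds$cases[i, c("age", "sex", "bmi", "ast", "alt",
                                   "ggt", "bilirubin")], scaler),
      numeric(7)))
    colnames(cl) <- paste0("clin_", .clinical_vars)
    parts$clin <- cl
  }
  do.call(cbind, parts)
}

.mtry_from_rule <- function(rule, d) {
  m <- if (rule == "log2") floor(log2(d)) else floor(sqrt(d))
  max(1L, min(d, as.integer(m)))
}

# Median-heuristic RBF kernel width on a subsample of rows.
.median_gamma <- function(x, max_n = 300L) {
  n <- nrow(x)
  if (n > max_n) x <- x[seq(1L, n, length.out = max_n), , drop = FALSE]
  d <- stats::dist(x)
  med <- stats::median(d[d > 0])
  if (!is.finite(med) || med == 0) return(1 / ncol(x))
  1 / (2 * med^2)
}

#' Train a patch-level classifier
#'
#' Fits the configured classifier on the patches of the training donors,
#' with inverse-frequency class weights on the loss. The clinical scaler (if
#' used) is fitted on the training donors inside this call, so no test-set
#' statistics leak into the model. Forest fits record per-feature mean
#' decrease in impurity; SVM scores are mapped to probabilities by a
#' logistic (Platt) link fitted on the training data.
#'
#' @param ds a `patch_dataset`.
#' @param train_donors donor ids to train on.
#' @param cfg a `model_config`.
#' @param params one row of `cfg$grid` (default: the first row).
#' @return A `trained_model`.
#' @export
train_model <- function(ds, train_donors, cfg, params = NULL) {
  stopifnot(inherits(ds, "patch_dataset"), inherits(cfg, "model_config"))
  if (is.null(params)) params <- cfg$grid[1, , drop = FALSE]
  labels <- case_labels(ds$cases, cfg$hs_threshold, cfg$lobe_rule)
  keep_cases <- ds$cases$case_id[ds$cases$donor_id %in% train_donors]
  rows <- which(ds$case_id %in% keep_cases)
  if (length(rows) == 0L) stop("no training patches for the given donors")
  y <- factor(as.character(labels[ds$case_id[rows]]),
              levels = .label_levels)
  if (nlevels(droplevels(y)) < 2L) stop("training set has a single class")
  scaler <- NULL
  if (cfg$feature_set %in% c("clinical", "both")) {
    tr_cases <- ds$cases[ds$cases$case_id %in% keep_cases, ]
    tr_donors <- tr_cases[!duplicated(tr_cases$donor_id), ]
    scaler <- fit_clinical_scaler(tr_donors)
  }
  x <- assemble_features(ds, rows, cfg$feature_set, scaler)
  if (all(apply(x, 2L, stats::sd) == 0))
    stop("all features are degenerate (zero variance)")
  w <- class_weights(y)
  fit <- if (cfg$classifier == "random_forest") {
    md <- params$max_depth
    ranger::ranger(
      x = x, y = y,
      num.trees = params$num_trees,
      mtry = .mtry_from_rule(params$mtry_rule, ncol(x)),
      max.depth = if (is.null(md) || md == 0L) NULL else md,
      probability = TRUE,
      class.weights = as.numeric(w[.label_levels]),
      importance = "impurity",
      seed = cfg$seed, num.threads = 1L)
  } else {
    gam <- .median_gamma(x) * params$gamma_mult
    with_seed(cfg$seed,
      e1071::svm(x = x, y = y, kernel = "radial", cost = params$cost,
                 gamma = gam, class.weights = w, probability = TRUE))
  }
  structure(list(classifier = cfg$classifier, fit = fit, params = params,
                 class_weights = w, scaler = scaler,
                 feature_set = cfg$feature_set,
                 feature_names = colnames(x),
                 hs_threshold = cfg$hs_threshold,
                 lobe_rule = cfg$lobe_rule,
                 fraction_threshold = cfg$fraction_threshold,
                 seed = cfg$seed),
            class = "trained_model")
}

#' Patch-level scores from a trained model
#'
#' @param model a `trained_model`.
#' @param x feature matrix (patches x features) matching the model's
#'   configuration.
#' @return Numeric vector of scores in \[0, 1\]: probability that the patch
#'   is `non_valid`; the implied label is `non_valid` when the score is at
#'   least 0.5.
#' @export
predict_patch <- function(model, x) {
  stopifnot(inherits(model, "trained_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$feature_names))
    stop("feature dimension does not match the model")
  if (model$classifier == "random_forest") {
    p <- stats::predict(model$fit, data = x, num.threads = 1L)$predictions
    as.numeric(p[, "non_valid"])
  } else {
    pr <- stats::predict(model$fit, newdata = x, probability = TRUE)
    as.numeric(attr(pr, "probabilities")[, "non_valid"])
  }
}

#' Liver-level predictions for a set of cases
#'
#' Scores every patch of each case, pools the patch votes, and aggregates
#' them into the liver decision (see [aggregate_patches()]).
#'
#' @param model a `trained_model`.
#' @param ds a `patch_dataset`.
#' @param case_ids cases to predict (default: all in `ds`).
#' @return data.frame with one row per case: `case_id`, `n_patches`,
#'   `n_non_valid`, `fraction`, `decision`.
#' @export
predict_cases <- function(model, ds, case_ids = NULL) {
  if (is.null(case_ids)) case_ids <- ds$cases$case_id
  rows <- which(ds$case_id %in% case_ids)
  x <- assemble_features(ds, rows, model$feature_set, model$scaler)
  scores <- predict_patch(model, x)
  ids <- ds$case_id[rows]
  out <- lapply(case_ids, function(cid) {
    s <- scores[ids == cid]
    agg <- aggregate_patches(s >= 0.5,
                             fraction_threshold = model$fraction_threshold)
    data.frame(case_id = cid, n_patches = agg$n_patches,
               n_non_valid = agg$n_non_valid, fraction = agg$fraction,
               decision = agg$decision, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Evaluate one fitted model on held-out donors: liver-level metrics.
eval_on_donors <- function(model, ds, donors, labels) {
  case_ids <- ds$cases$case_id[ds$cases$donor_id %in% donors]
  pred <- predict_cases(model, ds, case_ids)
  truth <- factor(as.character(labels[pred$case_id]), levels = .label_levels)
  m <- classification_metrics(factor(pred$decision, levels = .label_levels),
                              truth)
  auc <- if (nlevels(droplevels(truth)) == 2L)
    roc_auc(pred$fraction, truth)$auc else NA_real_
  list(pred = pred, truth = truth, metrics = m, auc = auc)
}

#' Donor-level stratified nested cross-validation
#'
#' Outer loop: `outer_repeats` stratified shuffle splits of donors into
#' train and test (70/30 by default). Inner loop: one stratified 90/10 split
#' of the outer-train donors per grid point; the grid point with the best
#' inner liver-level AUC is refitted on the full outer-train set and
#' evaluated on the outer-test livers. The generalisation estimate is the
#' mean of the outer-test metrics. All splits are donor-level, so no donor's
#' patches ever straddle a split.
#'
#' @param ds a `patch_dataset`.
#' @param cfg a `model_config`.
#' @return A `cv_result`: list with `repeats` (per-repeat metrics
#'   data.frame), `mean_metrics`, `chosen` (per-repeat selected grid rows),
#'   `splits` (per-repeat donor manifests), and `predictions` (pooled
#'   outer-test liver predictions with truth and repeat index).
#' @export
nested_cv <- function(ds, cfg) {
  stopifnot(inherits(ds, "patch_dataset"), inherits(cfg, "model_config"))
  labels <- case_labels(ds$cases, cfg$hs_threshold, cfg$lobe_rule)
  donor_tab <- ds$cases[!duplicated(ds$cases$donor_id), ]
  donor_labels <- stats::setNames(
    labels[donor_tab$case_id], donor_tab$donor_id)

  reps <- vector("list", cfg$outer_repeats)
  chosen <- vector("list", cfg$outer_repeats)
  splits <- vector("list", cfg$outer_repeats)
  preds <- vector("list", cfg$outer_repeats)
  for (r in seq_len(cfg$outer_repeats)) {
    seed_r <- cfg$seed + 101L * r
    outer <- split_donors(donor_labels, cfg$test_fraction, seed = seed_r)
    inner <- split_donors(donor_labels[outer$train],
                          cfg$inner_fraction, seed = seed_r + 1L)
    # inner$test is the 10% validation fold; inner$train the 90% fit fold
    best_i <- 1L
    best_auc <- -Inf
    if (nrow(cfg$grid) > 1L) {
      for (i in seq_len(nrow(cfg$grid))) {
        fit_i <- train_model(ds, inner$train, cfg,
                             cfg$grid[i, , drop = FALSE])
        ev <- eval_on_donors(fit_i, ds, inner$test, labels)
        score <- if (is.na(ev$auc)) ev$metrics$accuracy else ev$auc
        if (score > best_auc) { best_auc <- score; best_i <- i }
      }
    }
    model <- train_model(ds, outer$train, cfg,
                         cfg$grid[best_i, , drop = FALSE])
    ev <- eval_on_donors(model, ds, outer$test, labels)
    reps[[r]] <- data.frame(repeat_id = r,
                            accuracy = ev$metrics$accuracy,
                            precision = ev$metrics$precision,
                            recall = ev$metrics$recall,
                            auc = ev$auc)
    chosen[[r]] <- cbind(repeat_id = r, cfg$grid[best_i, , drop = FALSE])
    splits[[r]] <- list(outer_train = outer$train, outer_test = outer$test,
                        inner_train = inner$train, inner_val = inner$test)
    preds[[r]] <- cbind(ev$pred,
                        truth = as.character(ev$truth), repeat_id = r)
  }
  reps <- do.call(rbind, reps)
  structure(list(
    repeats = reps,
    mean_metrics = colMeans(reps[, c("accuracy", "precision", "recall",
                                     "auc")], na.rm = TRUE),
    chosen = do.call(rbind, chosen),
    splits = splits,
    predictions = do.call(rbind, preds),
    config = cfg), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d outer repeats, %s, HS threshold %g%%>\n",
              nrow(x$repeats), x$config$classifier, x$config$hs_threshold))
  m <- x$mean_metrics
  cat(sprintf("  mean accuracy %.3f  precision %.3f  recall %.3f  AUC %.3f\n",
              m["accuracy"], m["precision"], m["recall"], m["auc"]))
  invisible(x)
}
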