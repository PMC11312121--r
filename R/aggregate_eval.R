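# Liver-level aggregation of patch votes and evaluation utilities:
# metrics, ROC/AUC, bootstrap confidence intervals, exact McNemar test,
# feature importance. The positive class is `non_valid` throughout.

#' Aggregate patch votes into a liver-level decision
#'
#' The liver is called `non_valid` when the fraction of non-valid patches
#' reaches `fraction_threshold` (inclusive, so 5 non-valid patches out of 25
#' at the default 0.20 already flag the liver).
#'
#' @param patch_non_valid logical vector (or factor of
#'   `valid`/`non_valid`) of patch votes.
#' @param fraction_threshold decision threshold on the non-valid fraction,
#'   in (0, 1\]; default 0.20.
#' @return List with `n_patches`, `n_non_valid`, `fraction`, `decision`.
#' @export
aggregate_patches <- function(patch_non_valid, fraction_threshold = 0.20) {
  stopifnot(fraction_threshold > 0, fraction_threshold <= 1)
  if (is.factor(patch_non_valid) || is.character(patch_non_valid))
    patch_non_valid <- as.character(patch_non_valid) == "non_valid"
  n <- length(patch_non_valid)
  if (n == 0L) stop("no patches to aggregate")
  k <- sum(patch_non_valid)
  frac <- k / n
  list(n_patches = n, n_non_valid = k, fraction = frac,
       decision = if (frac >= fraction_threshold) "non_valid" else "valid")
}

#' Accuracy, precision and recall of liver decisions
#'
#' Standard definitions with `non_valid` as the positive class. Precision is
#' `NA` when no liver is predicted positive.
#'
#' @param decisions,truths factors/characters of `valid`/`non_valid`, equal
#'   length.
#' @return List with `accuracy`, `precision`, `recall`, and `confusion`
#'   (`tp`, `fp`, `fn`, `tn`).
#' @export
classification_metrics <- function(decisions, truths) {
  decisions <- as.character(decisions)
  truths <- as.character(truths)
  if (length(decisions) == 0L) stop("no predictions to score")
  stopifnot(length(decisions) == length(truths))
  pos <- "non_valid"
  tp <- sum(decisions == pos & truths == pos)
  fp <- sum(decisions == pos & truths != pos)
  fn <- sum(decisions != pos & truths == pos)
  tn <- sum(decisions != pos & truths != pos)
  list(accuracy = (tp + tn) / length(truths),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       confusion = c(tp = tp, fp = fp, fn = fn, tn = tn))
}

#' ROC curve and AUC of liver scores
#'
#' Sweeps the score thresholds, returns the ROC points and the trapezoidal
#' area, which equals the pairwise probability
#' `P(score_pos > score_neg) + 0.5 P(tie)`.
#'
#' @param scores numeric scores (higher = more likely `non_valid`).
#' @param truths labels (`non_valid` is positive).
#' @return List with `roc` (data.frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, truths) {
  truths <- as.character(truths)
  pos <- truths == "non_valid"
  if (!any(pos) || all(pos)) stop("ROC needs both classes")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Percentile bootstrap confidence interval for an evaluation metric
#'
#' Resamples cases with replacement `B` times and takes the 2.5 and 97.5
#' percentiles of the metric. Resamples where the metric is undefined
#' (e.g. precision with no positive predictions) are dropped; more than 50\%
#' undefined is an error.
#'
#' @param metric_fn function of `(pred, truth)` returning a scalar (possibly
#'   `NA`); `pred` may be decisions or scores depending on the metric.
#' @param pred,truth paired vectors, one entry per case.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return Named vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(metric_fn, pred, truth, B = 1000L, seed = 1L,
                         level = 0.95) {
  stopifnot(B >= 1L, length(pred) == length(truth))
  n <- length(pred)
  stat <- with_seed(seed, vapply(seq_len(B), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    v <- suppressWarnings(tryCatch(metric_fn(pred[idx], truth[idx]),
                                   error = function(e) NA_real_))
    if (length(v) != 1L) NA_real_ else as.numeric(v)
  }, 0))
  ok <- stat[!is.na(stat)]
  if (length(ok) < B / 2)
    stop("metric undefined in more than half of the bootstrap resamples")
  a <- (1 - level) / 2
  q <- stats::quantile(ok, c(a, 1 - a), names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Exact McNemar test on paired correctness flags
#'
#' Two-sided exact binomial test on the discordant pairs: `b` cases where
#' only the model is correct, `c` where only the comparator (e.g. the
#' surgeon) is correct; `p = min(1, 2 P(X <= min(b, c)))` with
#' `X ~ Binomial(b + c, 1/2)`. With no discordant pairs the p-value is 1.
#'
#' @param model_correct,comparator_correct logical vectors, paired by case.
#' @return List with `b`, `c`, `p_value`.
#' @export
mcnemar_exact <- function(model_correct, comparator_correct) {
  stopifnot(length(model_correct) == length(comparator_correct))
  b <- sum(model_correct & !comparator_correct)
  cc <- sum(!model_correct & comparator_correct)
  n <- b + cc
  p <- if (n == 0L) 1.0 else min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
  list(b = b, c = cc, p_value = p)
}

#' Feature importance: impurity and permutation rankings
#'
#' The impurity ranking is the forest's accumulated mean decrease in
#' impurity (error for non-forest models). The permutation ranking measures,
#' for each feature, the drop in liver-level AUC on the validation cases
#' when that feature column is shuffled, averaged over `R` shuffles.
#'
#' @param model a `trained_model`.
#' @param ds a `patch_dataset`.
#' @param case_ids validation cases.
#' @param features feature names to permute (default: all model features;
#'   restrict to a subset to save time on wide image-feature models).
#' @param R shuffles per feature (default 10).
#' @param seed integer seed for the shuffles.
#' @param include_impurity compute the impurity ranking (forest only).
#' @return List with `impurity` (data.frame `feature`, `importance`, sorted)
#'   and `permutation` (data.frame `feature`, `auc_drop`, sorted).
#' @export
importance_report <- function(model, ds, case_ids, features = NULL,
                              R = 10L, seed = 1L, include_impurity = TRUE) {
  stopifnot(inherits(model, "trained_model"))
  imp <- NULL
  if (include_impurity) {
    if (model$classifier != "random_forest")
      stop("impurity importance requires a random forest model")
    v <- model$fit$variable.importance
    imp <- data.frame(feature = names(v), importance = as.numeric(v))
    imp <- imp[order(-imp$importance), ]
    rownames(imp) <- NULL
  }
  labels <- case_labels(ds$cases, model$hs_threshold, model$lobe_rule)
  rows <- which(ds$case_id %in% case_ids)
  x <- assemble_features(ds, rows, model$feature_set, model$scaler)
  ids <- ds$case_id[rows]
  truth <- factor(as.character(labels[case_ids]), levels = .label_levels)
  frac_of <- function(xm) {
    s <- predict_patch(model, xm)
    vapply(case_ids, function(cid) mean(s[ids == cid] >= 0.5), 0)
  }
  base_auc <- roc_auc(frac_of(x), truth)$auc
  if (is.null(features)) features <- model$feature_names
  drops <- with_seed(seed, vapply(features, function(f) {
    j <- match(f, model$feature_names)
    mean(vapply(seq_len(R), function(r) {
      xp <- x
      xp[, j] <- xp[sample.int(nrow(xp)), j]
      base_auc - roc_auc(frac_of(xp), truth)$auc
    }, 0))
  }, 0))
  perm <- data.frame(feature = features, auc_drop = as.numeric(drops))
  perm <- perm[order(-perm$auc_drop), ]
  rownames(perm) <- NULL
  list(impurity = imp, permutation = perm)
}

#' Full evaluation report for pooled cross-validation predictions
#'
#' Computes accuracy/precision/recall with bootstrap CIs, the ROC and AUC of
#' the fraction scores with a bootstrap CI, the confusion counts, and (when
#' a surgeon estimate is available) the exact McNemar comparison between the
#' model's and the surgeon's correctness.
#'
#' @param predictions data.frame with `fraction`, `decision`, `truth` (as
#'   produced by [nested_cv()]`$predictions`), and optionally `case_id`.
#' @param ds optional `patch_dataset` providing `surgeon_hs` for the
#'   McNemar comparison.
#' @param hs_threshold HS threshold used to binarise the surgeon estimate.
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @return An `evaluation_report` list.
#' @export
evaluation_report <- function(predictions, ds = NULL, hs_threshold = 15,
                              B = 1000L, seed = 1L) {
  dec <- predictions$decision
  tru <- predictions$truth
  m <- classification_metrics(dec, tru)
  acc_fn <- function(p, t) classification_metrics(p, t)$accuracy
  prec_fn <- function(p, t) classification_metrics(p, t)$precision
  rec_fn <- function(p, t) classification_metrics(p, t)$recall
  auc_fn <- function(p, t) roc_auc(p, t)$auc
  roc <- roc_auc(predictions$fraction, tru)
  rep <- list(
    accuracy = m$accuracy,
    accuracy_ci = bootstrap_ci(acc_fn, dec, tru, B, seed),
    precision = m$precision,
    precision_ci = tryCatch(bootstrap_ci(prec_fn, dec, tru, B, seed + 1L),
                            error = function(e) c(lo = NA, hi = NA)),
    recall = m$recall,
    recall_ci = bootstrap_ci(rec_fn, dec, tru, B, seed + 2L),
    auc = roc$auc,
    auc_ci = bootstrap_ci(auc_fn, predictions$fraction, tru, B, seed + 3L),
    roc = roc$roc,
    confusion = m$confusion,
    mcnemar = NULL)
  if (!is.null(ds) && "case_id" %in% names(predictions) &&
      any(!is.na(ds$cases$surgeon_hs))) {
    i <- match(predictions$case_id, ds$cases$case_id)
    surg <- ifelse(ds$cases$surgeon_hs[i] > hs_threshold,
                   "non_valid", "valid")
    ok <- !is.na(surg)
    rep$mcnemar <- mcnemar_exact((dec == tru)[ok], (surg == tru)[ok])
    rep$surgeon_metrics <- classification_metrics(surg[ok], tru[ok])
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  fmt <- function(v, ci) sprintf("%.3f [%.3f, %.3f]", v, ci[1], ci[2])
  cat("<evaluation_report> (positive class: non_valid)\n")
  cat("  accuracy ", fmt(x$accuracy, x$accuracy_ci), "\n")
  if (!is.na(x$precision))
    cat("  precision", fmt(x$precision, x$precision_ci), "\n")
  cat("  recall   ", fmt(x$recall, x$recall_ci), "\n")
  cat("  AUC      ", fmt(x$auc, x$auc_ci), "\n")
  if (!is.null(x$mcnemar))
    cat(sprintf("  McNemar vs surgeon: b=%d c=%d p=%.4g\n",
                x$mcnemar$b, x$mcnemar$c, x$mcnemar$p_value))
  invisible(x)
}
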