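test_that("liver aggregation uses an inclusive fraction threshold", {
  # boundary: 5 of 25 is exactly 20% and flags the liver
  agg <- aggregate_patches(rep(c(TRUE, FALSE), c(5, 20)))
  expect_equal(agg$fraction, 0.2)
  expect_equal(agg$decision, "non_valid")

  expect_equal(aggregate_patches(rep(FALSE, 20))$decision, "valid")

  agg4 <- aggregate_patches(rep(c(TRUE, FALSE), c(4, 21)))
  expect_equal(agg4$fraction, 0.16)
  expect_equal(agg4$decision, "valid")

  # factor input
  f <- factor(rep(c("non_valid", "valid"), c(6, 4)),
              levels = c("valid", "non_valid"))
  expect_equal(aggregate_patches(f)$n_non_valid, 6)

  expect_error(aggregate_patches(logical(0)), "no patches")
})

test_that("adding a non-valid patch never flips non_valid to valid", {
  set.seed(5)
  for (i in 1:20) {
    votes <- runif(sample(5:30, 1)) < 0.3
    before <- aggregate_patches(votes)$decision
    after <- aggregate_patches(c(votes, TRUE))$decision
    if (before == "non_valid") expect_equal(after, "non_valid")
  }
})

test_that("metrics follow the confusion arithmetic with non_valid positive", {
  pred <- rep(c("non_valid", "non_valid", "valid", "valid"),
              c(9, 1, 2, 8))
  truth <- rep(c("non_valid", "valid", "non_valid", "valid"),
               c(9, 1, 2, 8))
  m <- classification_metrics(pred, truth)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 0.90)
  expect_equal(m$recall, 9 / 11, tolerance = 1e-9)
  expect_equal(unname(m$confusion), c(9, 1, 2, 8))

  all_ok <- classification_metrics(truth, truth)
  expect_equal(c(all_ok$accuracy, all_ok$precision, all_ok$recall),
               c(1, 1, 1))

  none_pos <- classification_metrics(rep("valid", 4),
                                     c("valid", "non_valid", "valid",
                                       "non_valid"))
  expect_true(is.na(none_pos$precision))
  expect_equal(none_pos$recall, 0)
})

test_that("trapezoidal AUC equals the pairwise probability", {
  r <- roc_auc(c(0.8, 0.6, 0.3, 0.6),
               c("non_valid", "non_valid", "valid", "valid"))
  expect_equal(r$auc, 0.875)

  expect_equal(roc_auc(c(1, 0.9, 0.1, 0), rep(c("non_valid", "valid"),
                                              each = 2))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 6), rep(c("non_valid", "valid"), 3))$auc,
               0.5)

  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    truths <- rep("valid", n)
    truths[sample(n, sample(1:(n - 1), 1))] <- "non_valid"
    scores <- round(runif(n), sample(1:3, 1))  # force some ties
    expect_equal(roc_auc(scores, truths)$auc,
                 auc_bruteforce(scores, truths), tolerance = 1e-9)
  }

  expect_error(roc_auc(c(0.1, 0.2), c("valid", "valid")), "both classes")
})

test_that("ROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  scores <- runif(40)
  truths <- ifelse(runif(40) < plogis(6 * (scores - 0.5)),
                   "non_valid", "valid")
  if (length(unique(truths)) == 2) {
    ours <- roc_auc(scores, truths)$auc
    ref <- suppressMessages(
      as.numeric(pROC::auc(pROC::roc(truths, scores,
                                     levels = c("valid", "non_valid"),
                                     direction = "<"))))
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("bootstrap CIs are percentile-correct, degenerate-safe, seeded", {
  acc <- function(p, t) mean(p == t)
  perfect <- bootstrap_ci(acc, rep("valid", 10), rep("valid", 10),
                          B = 200, seed = 1)
  expect_equal(unname(perfect), c(1, 1))

  # n = 3 accuracy sample {1,1,0}: compare the bootstrap distribution with
  # the exhaustive enumeration of the 27 equally likely resamples
  pred <- c("a", "a", "a")
  truth <- c("a", "a", "b")
  B <- 6000
  draws <- with(new.env(), {
    set.seed(2)
    replicate(B, { i <- sample(3, 3, TRUE); mean(pred[i] == truth[i]) })
  })
  # enumeration: k correct ~ Binomial(3, 2/3)
  expected <- dbinom(0:3, 3, 2 / 3)
  observed <- tabulate(round(draws * 3) + 1, 4) / B
  expect_lt(max(abs(observed - expected)), 4 * sqrt(max(expected) / B) + 0.01)
  ci <- bootstrap_ci(acc, pred, truth, B = 2000, seed = 3)
  expect_gte(ci[["lo"]], 0)
  expect_lte(ci[["lo"]], 1 / 3)
  expect_equal(ci[["hi"]], 1)

  ci2 <- bootstrap_ci(acc, pred, truth, B = 500, seed = 9)
  ci3 <- bootstrap_ci(acc, pred, truth, B = 500, seed = 9)
  expect_identical(ci2, ci3)

  # metric undefined in most resamples -> error
  bad <- function(p, t) stop("undefined")
  expect_error(bootstrap_ci(bad, pred, truth, B = 50, seed = 1),
               "undefined in more than half")
})

test_that("exact McNemar matches the binomial tail enumeration", {
  # b = 10, c = 2: p = 2 * P(X <= 2 | n = 12) = 158/4096
  m <- mcnemar_exact(rep(c(TRUE, FALSE), c(10, 2)),
                     rep(c(FALSE, TRUE), c(10, 2)))
  expect_equal(m$b, 10)
  expect_equal(m$c, 2)
  expect_equal(m$p_value, 158 / 4096, tolerance = 1e-12)

  sym <- mcnemar_exact(c(TRUE, FALSE, TRUE, TRUE),
                       c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(sym$p_value, 1)

  none <- mcnemar_exact(c(TRUE, TRUE), c(TRUE, TRUE))
  expect_equal(none$p_value, 1)
})

test_that("sweeping the aggregation threshold reproduces the fraction ROC", {
  set.seed(23)
  n <- 30
  frac <- round(runif(n), 2)
  truth <- ifelse(runif(n) < plogis(8 * (frac - 0.3)), "non_valid", "valid")
  if (length(unique(truth)) < 2) truth[1:2] <- c("valid", "non_valid")
  r <- roc_auc(frac, truth)
  pos <- truth == "non_valid"
  for (i in seq_len(nrow(r$roc))) {
    t <- r$roc$threshold[i]
    dec <- ifelse(frac >= t, "non_valid", "valid")
    expect_equal(mean(dec[pos] == "non_valid"), r$roc$tpr[i])
    expect_equal(mean(dec[!pos] == "non_valid"), r$roc$fpr[i])
  }
})

test_that("planted informative features top both importance rankings", {
  ds <- toy_patch_dataset(n_cases = 60, n_patch = 4, d = 10,
                          k_informative = 1, noise_sd = 0.3, seed = 20)
  cfg <- model_config("random_forest", 15, "image",
                      grid = data.frame(num_trees = 200L, max_depth = 0L,
                                        mtry_rule = "sqrt"),
                      seed = 4)
  labels <- factor(ifelse((ds$cases$biopsy_hs_left +
                             ds$cases$biopsy_hs_right) / 2 > 15,
                          "non_valid", "valid"),
                   levels = c("valid", "non_valid"))
  names(labels) <- ds$cases$donor_id
  sp <- split_donors(labels, 0.3, seed = 2)
  model <- train_model(ds, sp$train, cfg)
  val_cases <- ds$cases$case_id[ds$cases$donor_id %in% sp$test]
  rep <- importance_report(model, ds, val_cases, R = 5, seed = 6)

  # f1 carries the label; it must lead both rankings
  expect_equal(rep$impurity$feature[1], "f1")
  expect_equal(rep$permutation$feature[1], "f1")
  # pure-noise features have near-zero permutation importance
  noise_drop <- rep$permutation$auc_drop[rep$permutation$feature != "f1"]
  expect_lt(max(abs(noise_drop)), 0.15)
  # rankings are permutations of the feature set
  expect_setequal(rep$impurity$feature, colnames(ds$img_features))

  svm_cfg <- model_config("margin_svm", 15, "image",
                          grid = data.frame(cost = 1, gamma_mult = 1),
                          seed = 1)
  svm_model <- train_model(ds, sp$train, svm_cfg)
  expect_error(importance_report(svm_model, ds, val_cases),
               "random forest")
})
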