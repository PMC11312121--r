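test_that("case labels follow the lobe rule and threshold", {
  row <- list(biopsy_hs_left = 14, biopsy_hs_right = 16)
  expect_equal(as.character(make_label(row, 15, "mean")), "valid")
  expect_equal(as.character(make_label(row, 15, "max")), "non_valid")
  zero <- list(biopsy_hs_left = 0, biopsy_hs_right = 0)
  for (thr in c(5, 15, 30))
    expect_equal(as.character(make_label(zero, thr)), "valid")
  one_lobe <- list(biopsy_hs_left = 40, biopsy_hs_right = NA)
  expect_equal(as.character(make_label(one_lobe, 30)), "non_valid")
  expect_error(make_label(list(biopsy_hs_left = NA, biopsy_hs_right = NA),
                          15), "no biopsy")
})

test_that("class weights are inversely proportional to frequency", {
  balanced <- factor(rep(c("valid", "non_valid"), 25),
                     levels = c("valid", "non_valid"))
  expect_equal(unname(class_weights(balanced)), c(1, 1))

  cohort <- factor(rep(c("valid", "non_valid"), c(139, 53)),
                   levels = c("valid", "non_valid"))
  w <- class_weights(cohort)
  expect_equal(unname(w), c(192 / (2 * 139), 192 / (2 * 53)),
               tolerance = 1e-12)
  expect_equal(unname(round(w, 4)), c(0.6906, 1.8113))

  w31 <- class_weights(factor(rep(c("valid", "non_valid"), c(3, 1)),
                              levels = c("valid", "non_valid")))
  expect_equal(unname(w31), c(2 / 3, 2), tolerance = 1e-12)

  expect_error(class_weights(factor(rep("valid", 5),
                                    levels = c("valid", "non_valid"))),
               "both classes")
})

test_that("donor splits are stratified, disjoint and seeded", {
  labs <- factor(rep(c("valid", "non_valid"), c(7, 3)),
                 levels = c("valid", "non_valid"))
  names(labs) <- paste0("d", 1:10)
  sp <- split_donors(labs, 0.3, seed = 4)
  expect_length(sp$test, 3)
  expect_equal(sum(labs[sp$test] == "valid"), 2)
  expect_equal(sum(labs[sp$test] == "non_valid"), 1)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), names(labs))

  sp2 <- split_donors(labs, 0.3, seed = 4)
  expect_identical(sp, sp2)

  too_few <- factor(c("valid", "valid", "non_valid"),
                    levels = c("valid", "non_valid"))
  names(too_few) <- paste0("d", 1:3)
  expect_error(split_donors(too_few), "at least 2 donors")
})

test_that("no donor leaks across any split over many seeds", {
  labs <- factor(rep(c("valid", "non_valid"), c(30, 12)),
                 levels = c("valid", "non_valid"))
  names(labs) <- sprintf("don%02d", 1:42)
  for (s in 1:20) {
    outer <- split_donors(labs, 0.3, seed = s)
    expect_length(intersect(outer$train, outer$test), 0)
    inner <- split_donors(labs[outer$train], 0.1, seed = s + 1000)
    expect_length(intersect(inner$train, inner$test), 0)
    expect_true(all(c(inner$train, inner$test) %in% outer$train))
  }
})

test_that("a weighted forest separates separable patches", {
  ds <- toy_patch_dataset(n_cases = 40, noise_sd = 0.05, seed = 6)
  cfg <- model_config("random_forest", 15, "image",
                      grid = data.frame(num_trees = 100L, max_depth = 0L,
                                        mtry_rule = "sqrt"),
                      seed = 3)
  model <- train_model(ds, ds$cases$donor_id, cfg)
  labels <- as.character(
    factor(ifelse((ds$cases$biopsy_hs_left + ds$cases$biopsy_hs_right) / 2
                  > 15, "non_valid", "valid")))
  names(labels) <- ds$cases$case_id
  x <- ds$img_features
  scores <- predict_patch(model, x)
  pred <- ifelse(scores >= 0.5, "non_valid", "valid")
  truth <- labels[ds$case_id]
  expect_gte(mean(pred == truth), 0.99)

  # recorded weights equal class_weights of the training patch labels
  y <- factor(truth, levels = c("valid", "non_valid"))
  expect_equal(model$class_weights, class_weights(y))

  # scores are proper probabilities and deterministic
  expect_true(all(scores >= 0 & scores <= 1))
  expect_identical(scores, predict_patch(model, x))
  expect_error(predict_patch(model, x[, 1:5]), "dimension")
})

test_that("shuffled labels yield chance-level cross-validated AUC", {
  ds <- toy_patch_dataset(n_cases = 60, n_patch = 6, seed = 8,
                          label_signal = FALSE)
  cfg <- model_config("random_forest", 15, "image",
                      grid = data.frame(num_trees = 100L, max_depth = 0L,
                                        mtry_rule = "sqrt"),
                      outer_repeats = 6L, seed = 10)
  cv <- nested_cv(ds, cfg)
  expect_lt(abs(cv$mean_metrics[["auc"]] - 0.5), 0.12)
})

test_that("the margin SVM trains, scores in [0,1] and separates", {
  ds <- toy_patch_dataset(n_cases = 30, noise_sd = 0.05, seed = 16)
  cfg <- model_config("margin_svm", 15, "image",
                      grid = data.frame(cost = 1, gamma_mult = 1),
                      seed = 2)
  model <- train_model(ds, ds$cases$donor_id, cfg)
  s <- predict_patch(model, ds$img_features)
  expect_true(all(s >= 0 & s <= 1))
  pred <- predict_cases(model, ds)
  truth <- ifelse((ds$cases$biopsy_hs_left + ds$cases$biopsy_hs_right) / 2
                  > 15, "non_valid", "valid")
  expect_gte(mean(pred$decision == truth), 0.9)
})

test_that("a single-point grid reduces nested CV to plain train/test", {
  ds <- toy_patch_dataset(n_cases = 40, seed = 9)
  grid1 <- data.frame(num_trees = 100L, max_depth = 0L, mtry_rule = "sqrt")
  cfg <- model_config("random_forest", 15, "image", grid = grid1,
                      outer_repeats = 1L, seed = 77)
  cv <- nested_cv(ds, cfg)
  expect_equal(nrow(cv$repeats), 1)
  expect_equal(unname(unlist(cv$chosen[1, -1])),
               unname(unlist(grid1[1, ])))

  # replicate manually with the same split and model seeds
  labels <- factor(ifelse((ds$cases$biopsy_hs_left +
                             ds$cases$biopsy_hs_right) / 2 > 15,
                          "non_valid", "valid"),
                   levels = c("valid", "non_valid"))
  names(labels) <- ds$cases$donor_id
  outer <- split_donors(labels, 0.3, seed = 77 + 101)
  model <- train_model(ds, outer$train, cfg)
  pred <- predict_cases(model, ds, outer$test)
  truth <- as.character(labels[pred$case_id])
  m <- classification_metrics(pred$decision, truth)
  expect_equal(cv$repeats$accuracy, m$accuracy)
  expect_equal(cv$repeats$auc, roc_auc(pred$fraction, truth)$auc)

  # determinism of the whole nested procedure
  cv2 <- nested_cv(ds, cfg)
  expect_equal(cv$repeats, cv2$repeats)
  expect_equal(cv$predictions$fraction, cv2$predictions$fraction)

  # donor-level disjointness in every recorded split
  for (sp in cv$splits) {
    expect_length(intersect(sp$outer_train, sp$outer_test), 0)
    expect_length(intersect(sp$inner_train, sp$inner_val), 0)
  }
})

test_that("clinical-only models use the scaler fitted on training donors", {
  ds <- toy_patch_dataset(n_cases = 40, seed = 13)
  cfg <- model_config("random_forest", 15, "clinical",
                      grid = data.frame(num_trees = 100L, max_depth = 0L,
                                        mtry_rule = "sqrt"),
                      seed = 5)
  labels <- factor(ifelse((ds$cases$biopsy_hs_left +
                             ds$cases$biopsy_hs_right) / 2 > 15,
                          "non_valid", "valid"),
                   levels = c("valid", "non_valid"))
  names(labels) <- ds$cases$donor_id
  sp <- split_donors(labels, 0.3, seed = 1)
  model <- train_model(ds, sp$train, cfg)
  expect_s3_class(model$scaler, "clinical_scaler")
  tr <- ds$cases[ds$cases$donor_id %in% sp$train, ]
  expect_equal(unname(model$scaler$center["alt"]), median(tr$alt))
  expect_length(model$feature_names, 7)
})
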