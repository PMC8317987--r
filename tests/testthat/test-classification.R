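test_that("stratified splits honor per-class half-up rounding", {
  ft <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:51),
    group = c(rep("HC", 27), rep("LBP", 24)),
    DC_1 = rnorm(51)
  )
  sp <- stratified_split(ft, 0.70, seed = 1)
  expect_equal(sum(sp$train$group == "HC"), 19)  # round(0.7 * 27)
  expect_equal(sum(sp$train$group == "LBP"), 17) # round(0.7 * 24)
  expect_equal(sum(sp$test$group == "HC"), 8)
  expect_equal(sum(sp$test$group == "LBP"), 7)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  expect_setequal(c(sp$train$subject_id, sp$test$subject_id), ft$subject_id)

  ft2 <- ft[c(1:10, 28:37), ]
  sp2 <- stratified_split(ft2, 0.5, seed = 2)
  expect_equal(as.vector(table(sp2$train$group)), c(5L, 5L))
  expect_equal(as.vector(table(sp2$test$group)), c(5L, 5L))

  # determinism
  sp3 <- stratified_split(ft, 0.70, seed = 1)
  expect_identical(sp$train$subject_id, sp3$train$subject_id)

  # degenerate class
  ft3 <- ft[c(1, 28:30), ]
  expect_error(stratified_split(ft3, 0.7), "empty in one partition")
})

test_that("confusion identities reproduce the defining formulas", {
  cm <- graphmarker:::confusion_metrics(tp = 10, fp = 2, tn = 6, fn = 2)
  expect_equal(cm$accuracy, 0.80)
  expect_equal(cm$sensitivity, 10 / 12, tolerance = 1e-12)
  expect_equal(cm$specificity, 0.75)
  # enumerated random confusion tables
  set.seed(1)
  for (i in 1:20) {
    k <- sample(0:8, 4, replace = TRUE)
    if (sum(k) == 0) next
    cm <- graphmarker:::confusion_metrics(k[1], k[2], k[3], k[4])
    expect_equal(cm$TP + cm$FP + cm$TN + cm$FN, sum(k))
    expect_equal(cm$accuracy, (k[1] + k[3]) / sum(k))
    if (k[1] + k[4] > 0) expect_equal(cm$sensitivity, k[1] / (k[1] + k[4]))
    if (k[3] + k[2] > 0) expect_equal(cm$specificity, k[3] / (k[3] + k[2]))
  }
})

test_that("AUC follows the midrank convention", {
  lab <- c(rep("HC", 4), rep("LBP", 4))
  expect_equal(graphmarker:::auc_from_scores(c(4, 3, 2, 1, -1, -2, -3, -4),
                                             lab, "HC"), 1)
  expect_equal(graphmarker:::auc_from_scores(rep(0, 8), lab, "HC"), 0.5)
  expect_equal(graphmarker:::auc_from_scores(c(1, 1, 0, 0, 1, 0, 0, 0),
                                             lab, "HC"),
               graphmarker:::auc_from_scores(c(1, 1, 0, 0, 1, 0, 0, 0) * 10,
                                             lab, "HC"))
})

test_that("train_svm separates a separable toy set and tunes cost deterministically", {
  ft <- toy_feature_table(n_per_group = 10, n_noise = 1, delta = 30, seed = 1)
  cfg <- eval_config(n_iterations = 1, seed = 1)
  fit <- train_svm(ft, cfg = cfg)
  res <- evaluate(fit, ft)
  expect_equal(res$accuracy, 1)
  expect_true(all(fit$cv$cv_performance == 1))
  expect_equal(fit$chosen_cost, 1) # ties -> smallest cost

  # duplicating the training set leaves the chosen cost unchanged
  ft_dup <- dplyr::bind_rows(ft, dplyr::mutate(ft, subject_id = paste0(subject_id, "b")))
  fit_dup <- train_svm(ft_dup, cfg = cfg)
  expect_equal(fit_dup$chosen_cost, fit$chosen_cost)
})

test_that("zero-variance features are dropped with a warning", {
  ft <- toy_feature_table(n_per_group = 8, n_noise = 2, delta = 2, seed = 3)
  ft$DC_noise1 <- 1
  cfg <- eval_config(cost_grid = 1, seed = 1)
  expect_warning(fit <- train_svm(ft, cfg = cfg), "zero-variance")
  expect_false("DC_noise1" %in% fit$features)
  ft_all <- ft
  for (f in feature_columns(ft_all)) ft_all[[f]] <- 2
  expect_warning(expect_error(train_svm(ft_all, cfg = cfg), "all features"),
                 "zero-variance")
})

test_that("swapping the positive class swaps sensitivity/specificity and flips AUC", {
  ft <- cohort_feature_table(seed = 2, n_hc = 12, n_lbp = 12, n_nodes = 20,
                             n_affected = 4, metrics = "DC")$ft
  sp <- stratified_split(ft, 0.7, seed = 3)
  fit <- train_svm(sp$train, cfg = eval_config(cost_grid = 1))
  res_hc <- evaluate(fit, sp$test, positive_class = "HC")
  res_lbp <- evaluate(fit, sp$test, positive_class = "LBP")
  expect_equal(res_hc$sensitivity, res_lbp$specificity)
  expect_equal(res_hc$specificity, res_lbp$sensitivity)
  expect_equal(res_hc$accuracy, res_lbp$accuracy)
  expect_equal(res_hc$TP, res_lbp$TN)
  expect_equal(res_hc$FN, res_lbp$FP)
  # evaluate() orients decision values to the positive class, so its AUC
  # is designation-invariant; the 1 - AUC flip is a property of the rank
  # statistic with a fixed score orientation
  set.seed(4)
  scores <- rnorm(12)
  labs <- rep(c("HC", "LBP"), 6)
  expect_equal(graphmarker:::auc_from_scores(scores, labs, "HC"),
               1 - graphmarker:::auc_from_scores(scores, labs, "LBP"),
               tolerance = 1e-12)
})

test_that("run_protocol aggregates iterations reproducibly", {
  ft <- cohort_feature_table(seed = 3, n_hc = 12, n_lbp = 12, n_nodes = 20,
                             n_affected = 4, metrics = "DC")$ft
  cfg <- eval_config(n_iterations = 1, cost_grid = c(1, 5), cv_repeats = 2,
                     seed = 7)
  rep1 <- run_protocol(ft, "none", cfg)
  expect_equal(nrow(rep1$per_iteration), 1)
  g <- glance(rep1)
  expect_equal(g$mean_accuracy, rep1$per_iteration$accuracy)
  expect_equal(g$mean_auc, rep1$per_iteration$auc)

  # single iteration equals the manually assembled split/train/evaluate
  sp <- stratified_split(ft, cfg$split_ratio, seed = cfg$seed + 1)
  fit <- train_svm(sp$train, cfg = cfg, seed = cfg$seed + 1)
  manual <- evaluate(fit, sp$test, cfg$positive_class)
  expect_equal(rep1$per_iteration$accuracy, manual$accuracy)
  expect_equal(rep1$per_iteration$auc, manual$auc)
  expect_equal(rep1$per_iteration$chosen_cost, manual$chosen_cost)

  # full determinism of the report
  cfg2 <- eval_config(n_iterations = 4, cost_grid = 1, seed = 11)
  a <- run_protocol(ft, "enet", cfg2)
  b <- run_protocol(ft, "enet", cfg2)
  expect_identical(tidy(a), tidy(b))
  expect_identical(a$feature_frequency, b$feature_frequency)

  # confusion identities hold for every iteration
  p <- a$per_iteration
  expect_true(all(p$TP + p$FP + p$TN + p$FN == nrow(ft) - nrow(sp$train)))
  expect_equal(p$accuracy, (p$TP + p$TN) / (p$TP + p$FP + p$TN + p$FN))

  # selection frequencies sum to total selections and support top-k
  expect_equal(sum(a$feature_frequency$n_selected),
               sum(lengths(p$selected)))
  expect_lte(nrow(top_selected_features(a, 5)), 5)
})

test_that("null-feature protocol accuracy sits near the majority-class rate", {
  accs <- vapply(1:6, function(s) {
    ft <- toy_feature_table(n_per_group = 15, n_noise = 10, delta = 0,
                            seed = 100 + s)
    cfg <- eval_config(n_iterations = 4, cost_grid = 1, seed = s)
    glance(run_protocol(ft, "none", cfg))$mean_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})
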