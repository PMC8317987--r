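#' Evaluation protocol configuration
#'
#' Parameters of the repeated train/test protocol: stratified 70/30
#' splits, a linear SVM with the cost grid tuned by repeated stratified
#' K-fold cross-validation on the training split, and averaging over
#' `n_iterations` random splits.
#'
#' @param split_ratio Training fraction per class (default 0.70).
#' @param n_iterations Number of random split repetitions (default 100).
#' @param cost_grid SVM cost values searched (default `1:10`).
#' @param cv_folds,cv_repeats Folds (default 4) and repeats (default 5)
#'   of the cost-tuning cross-validation.
#' @param positive_class Label treated as positive in the confusion
#'   matrix (default `"HC"`).
#' @param cv_metric Model-selection criterion inside the tuning CV,
#'   `"accuracy"` (default) or `"auc"`.
#' @param seed Base seed; iteration i derives its seed as `seed + i`.
#'
#' @return An `eval_config` list.
#' @export
eval_config <- function(split_ratio = 0.70, n_iterations = 100,
                        cost_grid = 1:10, cv_folds = 4, cv_repeats = 5,
                        positive_class = "HC",
                        cv_metric = c("accuracy", "auc"), seed = 1) {
  if (split_ratio <= 0 || split_ratio >= 1) {
    stop("split_ratio must be in (0, 1)", call. = FALSE)
  }
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  if (length(cost_grid) == 0 || any(cost_grid <= 0)) {
    stop("cost_grid must be non-empty positive costs", call. = FALSE)
  }
  if (cv_folds < 2 || cv_repeats < 1) {
    stop("cv_folds must be >= 2 and cv_repeats >= 1", call. = FALSE)
  }
  structure(list(split_ratio = split_ratio,
                 n_iterations = as.integer(n_iterations),
                 cost_grid = cost_grid, cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 positive_class = positive_class,
                 cv_metric = match.arg(cv_metric),
                 seed = as.integer(seed)),
            class = "eval_config")
}

#' Stratified train/test split
#'
#' Each class contributes `round(ratio * class size)` subjects
#' (half-up rounding) to the training partition; the partition is
#' disjoint, exhaustive and deterministic given the seed.
#'
#' @param table A [feature_table()] (any data frame with a `group`
#'   column works).
#' @param ratio Training fraction.
#' @param seed Integer seed.
#'
#' @return List with elements `train` and `test`.
#' @export
stratified_split <- function(table, ratio = 0.70, seed = 1) {
  stopifnot("group" %in% names(table))
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)", call. = FALSE)
  set.seed(seed)
  train_idx <- integer(0)
  for (lv in unique(table$group)) {
    idx <- which(table$group == lv)
    n_tr <- round_half_up(ratio * length(idx))
    if (n_tr == 0 || n_tr == length(idx)) {
      stop("class '", lv, "' would be empty in one partition", call. = FALSE)
    }
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  train_idx <- sort(train_idx)
  list(train = table[train_idx, , drop = FALSE],
       test = table[-train_idx, , drop = FALSE])
}

confusion_metrics <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  tibble::tibble(
    TP = tp, FP = fp, TN = tn, FN = fn,
    accuracy = (tp + tn) / total,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

#' Train a linear SVM with cost-grid tuning
#'
#' Standardizes features using training-set statistics, drops
#' zero-variance features with a warning, estimates accuracy (or AUC)
#' for every cost by stratified `cv_folds`-fold cross-validation
#' repeated `cv_repeats` times, and fits the final linear SVM at the
#' best cost (ties: smaller cost) on all of the training data. A
#' single-value `cost_grid` skips the tuning CV.
#'
#' @param train Training [feature_table()].
#' @param features Feature columns to use; default all.
#' @param cfg An [eval_config()].
#' @param seed Seed for the tuning folds (default `cfg$seed`).
#'
#' @return An `svm_fit`: fitted model, `chosen_cost`, the scaler, the
#'   feature set, and the per-cost CV trace.
#' @export
train_svm <- function(train, features = NULL, cfg = eval_config(),
                      seed = cfg$seed) {
  m <- as_feature_matrix(train)
  features <- features %||% m$features
  x <- m$x[, features, drop = FALSE]
  scl <- apply(x, 2, sd)
  if (any(scl == 0)) {
    dropped <- features[scl == 0]
    warning("dropping zero-variance feature(s) on train: ",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...", call. = FALSE)
    features <- features[scl != 0]
    if (length(features) == 0) {
      stop("all features have zero variance on the training split",
           call. = FALSE)
    }
    x <- x[, features, drop = FALSE]
    scl <- scl[scl != 0]
  }
  ctr <- colMeans(x)
  xs <- scale(x, ctr, scl)
  y <- m$y
  positive <- cfg$positive_class

  cv <- NULL
  if (length(cfg$cost_grid) > 1) {
    perf <- matrix(NA_real_, length(cfg$cost_grid),
                   cfg$cv_folds * cfg$cv_repeats)
    col <- 0
    for (r in seq_len(cfg$cv_repeats)) {
      folds <- stratified_folds(y, cfg$cv_folds, seed + 1000L * r)
      for (f in seq_len(cfg$cv_folds)) {
        col <- col + 1
        tr <- folds != f
        for (ci in seq_along(cfg$cost_grid)) {
          fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr],
                            kernel = "linear", cost = cfg$cost_grid[ci],
                            scale = FALSE)
          held <- xs[!tr, , drop = FALSE]
          if (cfg$cv_metric == "accuracy") {
            perf[ci, col] <- mean(predict(fit, held) == y[!tr])
          } else {
            perf[ci, col] <- auc_from_scores(svm_scores(fit, held, positive),
                                             y[!tr], positive)
          }
        }
      }
    }
    cv <- tibble::tibble(cost = cfg$cost_grid,
                         cv_performance = rowMeans(perf, na.rm = TRUE))
    best <- dplyr::arrange(cv, dplyr::desc(round(.data$cv_performance, 12)),
                           .data$cost)[1, ]
    chosen_cost <- best$cost
  } else {
    chosen_cost <- cfg$cost_grid[1]
  }

  model <- e1071::svm(xs, y, kernel = "linear", cost = chosen_cost,
                      scale = FALSE)
  structure(list(model = model, chosen_cost = chosen_cost,
                 center = ctr, scale = scl, features = features,
                 levels = levels(y), cv = cv),
            class = "svm_fit")
}

#' Evaluate a fitted SVM on a held-out test table
#'
#' Hard predictions fill the confusion matrix with the stated positive
#' class; AUC is computed from the continuous decision values by the
#' midrank statistic. If the test set contains one class only, the
#' metrics that remain defined are reported and AUC is `NA`.
#'
#' @param fit An `svm_fit` from [train_svm()].
#' @param test Test [feature_table()].
#' @param positive_class Positive label (default `"HC"`).
#'
#' @return One-row tibble: `TP`, `FP`, `TN`, `FN`, `accuracy`,
#'   `sensitivity`, `specificity`, `auc`, `chosen_cost`.
#' @export
evaluate <- function(fit, test, positive_class = "HC") {
  stopifnot(inherits(fit, "svm_fit"), nrow(test) > 0)
  x <- as.matrix(test[, fit$features, drop = FALSE])
  xs <- scale(x, fit$center, fit$scale)
  pred <- predict(fit$model, xs)
  scores <- svm_scores(fit$model, xs, positive_class)
  truth <- test$group
  pos <- truth == positive_class
  pred_pos <- pred == positive_class
  out <- confusion_metrics(tp = sum(pred_pos & pos),
                           fp = sum(pred_pos & !pos),
                           tn = sum(!pred_pos & !pos),
                           fn = sum(!pred_pos & pos))
  out$auc <- auc_from_scores(scores, truth, positive_class)
  out$chosen_cost <- fit$chosen_cost
  out
}

#' Run the repeated split / select / train / test protocol
#'
#' For each iteration (seed = `cfg$seed + i`): draw a stratified
#' train/test split, run feature selection on the training split only,
#' tune and fit the linear SVM on the selected features, and evaluate on
#' the held-out split. Per-iteration results, their arithmetic means and
#' the per-feature selection frequencies are aggregated into an
#' `evaluation_report`.
#'
#' @param table A [feature_table()].
#' @param selector `"enet_subset"` (default), `"enet"`, or `"none"`
#'   (use all features).
#' @param cfg An [eval_config()].
#' @param enet_cfg An [enet_config()] for the selector.
#' @param step Enet-subset size increment (default 25).
#'
#' @return An `evaluation_report` with `per_iteration` (one row per
#'   iteration, including a `selected` list-column), `feature_frequency`
#'   (selection counts over iterations), the selector and the configs.
#'   See [tidy()], [glance()] and [autoplot()] methods.
#' @export
run_protocol <- function(table, selector = c("enet_subset", "enet", "none"),
                         cfg = eval_config(), enet_cfg = enet_config(),
                         step = 25) {
  selector <- match.arg(selector)
  all_features <- feature_columns(table)
  rows <- vector("list", cfg$n_iterations)
  for (i in seq_len(cfg$n_iterations)) {
    s <- cfg$seed + i
    rows[[i]] <- tryCatch({
      split <- stratified_split(table, cfg$split_ratio, seed = s)
      feats <- switch(selector,
        none = all_features,
        enet = enet_select(split$train, enet_cfg, seed = s)$selected,
        enet_subset = enet_subset_select(split$train, enet_cfg, step = step,
                                         seed = s)$selected
      )
      fit <- train_svm(split$train, feats, cfg, seed = s)
      res <- evaluate(fit, split$test, cfg$positive_class)
      dplyr::mutate(res, iteration = i, n_features = length(fit$features),
                    selected = list(fit$features), .before = 1)
    }, error = function(e) {
      stop("protocol iteration ", i, " failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  per_iteration <- dplyr::bind_rows(rows)
  counts <- table(unlist(per_iteration$selected))
  freq <- tibble::tibble(feature = names(counts),
                         n_selected = as.integer(counts),
                         frequency = as.integer(counts) / cfg$n_iterations)
  info <- attr(table, "feature_info")
  if (!is.null(info)) freq <- dplyr::left_join(freq, info, by = "feature")
  freq <- dplyr::arrange(freq, dplyr::desc(.data$n_selected), .data$feature)
  structure(list(per_iteration = per_iteration,
                 feature_frequency = freq,
                 selector = selector, config = cfg, enet_config = enet_cfg),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  g <- glance(x)
  cat("<evaluation_report> selector: ", x$selector, "; ",
      g$n_iterations, " iterations\n", sep = "")
  cat(sprintf("  mean accuracy %.3f | AUC %.3f | sensitivity %.3f | specificity %.3f | features %.1f\n",
              g$mean_accuracy, g$mean_auc, g$mean_sensitivity,
              g$mean_specificity, g$mean_feature_count))
  invisible(x)
}

#' @describeIn run_protocol Per-iteration results as a tibble.
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) {
  dplyr::select(x$per_iteration, -"selected")
}

#' @describeIn run_protocol One-row summary: arithmetic means of the
#'   per-iteration accuracy, AUC, sensitivity, specificity and selected
#'   feature count.
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  p <- x$per_iteration
  tibble::tibble(
    n_iterations = nrow(p),
    mean_accuracy = mean(p$accuracy, na.rm = TRUE),
    mean_auc = mean(p$auc, na.rm = TRUE),
    mean_sensitivity = mean(p$sensitivity, na.rm = TRUE),
    mean_specificity = mean(p$specificity, na.rm = TRUE),
    mean_feature_count = mean(p$n_features)
  )
}

#' Top features by selection frequency
#'
#' @param report An `evaluation_report`.
#' @param n Number of features to return (default 60).
#'
#' @return The first `n` rows of the report's selection-frequency table.
#' @export
top_selected_features <- function(report, n = 60) {
  stopifnot(inherits(report, "evaluation_report"))
  head(report$feature_frequency, n)
}
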