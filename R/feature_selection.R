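#' Assemble a subjects-by-features table from node metrics
#'
#' Concatenates the requested metric blocks into one wide feature table
#' (e.g. `BC + CC + DC` on an N-node parcellation gives `3 N` feature
#' columns). Feature columns are named `<metric>_<node_id>` and the
#' (node, metric) map travels in the `feature_info` attribute.
#'
#' @param metric_tbl Long tibble from [compute_node_metrics()].
#' @param labels Tibble with `subject_id`, `group` (ignored if
#'   `metric_tbl` already carries `group`); `group` must take exactly
#'   two values.
#' @param metrics Metric blocks to concatenate, subset of
#'   `c("BC", "CC", "DC", "LE")`.
#'
#' @return Wide tibble: `subject_id`, `group`, then one numeric column
#'   per (metric, node) feature.
#' @export
feature_table <- function(metric_tbl, labels = NULL,
                          metrics = c("BC", "CC", "DC")) {
  stopifnot(all(c("subject_id", "node_id", "metric", "value") %in%
                  names(metric_tbl)))
  metrics <- match.arg(metrics, c("BC", "CC", "DC", "LE"), several.ok = TRUE)
  tbl <- dplyr::filter(metric_tbl, .data$metric %in% metrics)
  if (!"group" %in% names(tbl)) {
    stopifnot(!is.null(labels), all(c("subject_id", "group") %in% names(labels)))
    tbl <- dplyr::left_join(tbl, dplyr::select(labels, "subject_id", "group"),
                            by = "subject_id")
  }
  tbl$feature <- paste(tbl$metric, tbl$node_id, sep = "_")
  info <- dplyr::distinct(tbl, .data$feature, .data$node_id, .data$metric)
  wide <- tidyr::pivot_wider(
    dplyr::select(tbl, "subject_id", "group", "feature", "value"),
    names_from = "feature", values_from = "value"
  )
  if (anyNA(wide)) stop("feature table contains missing values", call. = FALSE)
  if (length(unique(wide$group)) != 2) {
    stop("group must take exactly two values", call. = FALSE)
  }
  structure(wide, feature_info = info)
}

#' Feature column names of a feature table
#'
#' @param ft A [feature_table()].
#' @return Character vector of feature column names (everything except
#'   the `subject_id`, `group` and `odi` columns).
#' @export
feature_columns <- function(ft) setdiff(names(ft), c("subject_id", "group", "odi"))

as_feature_matrix <- function(ft) {
  feats <- feature_columns(ft)
  x <- as.matrix(ft[, feats, drop = FALSE])
  rownames(x) <- ft$subject_id
  y <- factor(ft$group)
  list(x = x, y = y, features = feats)
}

#' Elastic-net grid configuration
#'
#' The search grid for the penalized logistic regression used as the
#' feature selector. `lambda_grid` is the penalty strength and
#' `alpha_grid` the lasso/ridge mixing weight; the default mixing grid
#' sits close to ridge, which keeps correlated features grouped and
#' zeroes out only clearly non-contributing ones.
#'
#' @param lambda_grid Penalty strengths (default 0.1 to 0.9 by 0.1).
#' @param alpha_grid Mixing weights (default 0.0001 to 0.005 by 0.001).
#' @param cv_folds Folds for the selection cross-validation (default 4).
#'
#' @return An `enet_config` list.
#' @export
enet_config <- function(lambda_grid = seq(0.1, 0.9, by = 0.1),
                        alpha_grid = seq(0.0001, 0.005, by = 0.001),
                        cv_folds = 4) {
  if (length(lambda_grid) == 0 || any(lambda_grid <= 0)) {
    stop("lambda_grid must be non-empty positive penalties", call. = FALSE)
  }
  if (length(alpha_grid) == 0 || any(alpha_grid < 0 | alpha_grid > 1)) {
    stop("alpha_grid must be non-empty mixing weights in [0, 1]", call. = FALSE)
  }
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  structure(list(lambda_grid = sort(lambda_grid),
                 alpha_grid = sort(alpha_grid),
                 cv_folds = as.integer(cv_folds)),
            class = "enet_config")
}

# glmnet warns whenever a class has < 8 observations, which is routine
# for 4-fold CV on small cohorts; that warning is expected and muffled.
quiet_glmnet <- function(...) {
  withCallingHandlers(
    glmnet::glmnet(...),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

# Internal: cross-validated AUC over the (alpha, lambda) grid plus
# full-data nonzero counts, shared by enet_select().
enet_grid_cv <- function(x, y, cfg, seed) {
  lam <- sort(cfg$lambda_grid, decreasing = TRUE)
  folds <- stratified_folds(y, cfg$cv_folds, seed)
  case <- levels(y)[2]  # glmnet models P(y = second level)
  grid <- list()
  for (a in cfg$alpha_grid) {
    auc_mat <- matrix(NA_real_, cfg$cv_folds, length(lam))
    for (f in seq_len(cfg$cv_folds)) {
      tr <- folds != f
      fit <- quiet_glmnet(x[tr, , drop = FALSE], y[tr],
                            family = "binomial", alpha = a, lambda = lam,
                            standardize = TRUE)
      sc <- predict(fit, x[!tr, , drop = FALSE], s = lam, type = "link")
      for (j in seq_along(lam)) {
        auc_mat[f, j] <- auc_from_scores(sc[, j], y[!tr], case)
      }
    }
    full <- quiet_glmnet(x, y, family = "binomial", alpha = a,
                           lambda = lam, standardize = TRUE)
    nz <- apply(as.matrix(full$beta)[, seq_along(lam), drop = FALSE] != 0, 2, sum)
    grid[[length(grid) + 1]] <- tibble::tibble(
      alpha = a, lambda = lam,
      cv_auc = colMeans(auc_mat, na.rm = TRUE),
      n_nonzero = as.integer(nz),
      fit = list(full)
    )
  }
  dplyr::bind_rows(grid)
}

#' Elastic-net feature selection
#'
#' Fits elastic-net-penalized logistic regression over the
#' (lambda, alpha) grid, picks the grid point with maximal
#' cross-validated AUC on the training table (ties: larger lambda, then
#' smaller alpha), and returns the features with nonzero coefficients in
#' the winning fit, sorted by descending absolute coefficient. Grid
#' points whose full-data fit retains no feature are not eligible
#' winners.
#'
#' @param train Training [feature_table()] (at least 2 subjects per
#'   class).
#' @param cfg An [enet_config()].
#' @param seed Integer seed controlling the cross-validation folds.
#'
#' @return A `selection_result`: method, `coefficients` tibble
#'   (feature, coefficient, ordered by |coefficient|), `selected`
#'   character vector, winning `alpha`/`lambda`/`cv_auc`, and the full
#'   `cv` grid trace.
#' @export
enet_select <- function(train, cfg = enet_config(), seed = 1) {
  m <- as_feature_matrix(train)
  if (min(table(m$y)) < 2) {
    stop("need at least 2 training subjects per class", call. = FALSE)
  }
  grid <- enet_grid_cv(m$x, m$y, cfg, seed)
  eligible <- grid[grid$n_nonzero >= 1, ]
  if (nrow(eligible) == 0) {
    stop("elastic net retained zero features at every grid point; ",
         "widen lambda_grid / alpha_grid", call. = FALSE)
  }
  eligible <- dplyr::arrange(eligible, dplyr::desc(round(.data$cv_auc, 12)),
                             dplyr::desc(.data$lambda), .data$alpha)
  win <- eligible[1, ]
  beta <- as.matrix(predict(win$fit[[1]], s = win$lambda,
                            type = "coefficients"))[, 1]
  beta <- beta[setdiff(names(beta), "(Intercept)")]
  nz <- beta[beta != 0]
  coefs <- tibble::tibble(feature = names(nz), coefficient = unname(nz))
  coefs <- dplyr::arrange(coefs, dplyr::desc(abs(.data$coefficient)))
  structure(
    list(method = "enet",
         coefficients = coefs,
         selected = coefs$feature,
         subset_trace = NULL,
         alpha = win$alpha, lambda = win$lambda, cv_auc = win$cv_auc,
         cv = dplyr::select(grid, -"fit"),
         n_features_in = ncol(m$x)),
    class = "selection_result"
  )
}

# Internal: mean cross-validated AUC of a cost-1 linear SVM on a fixed
# feature subset, standardizing within each fold's training part.
svm_subset_cv_auc <- function(x, y, features, folds, positive) {
  k <- max(folds)
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    xt <- x[tr, features, drop = FALSE]
    ctr <- colMeans(xt)
    scl <- apply(xt, 2, sd)
    scl[scl == 0] <- 1
    xt <- scale(xt, ctr, scl)
    xv <- scale(x[!tr, features, drop = FALSE], ctr, scl)
    fit <- e1071::svm(xt, y[tr], kernel = "linear", cost = 1, scale = FALSE)
    aucs[f] <- auc_from_scores(svm_scores(fit, xv, positive), y[!tr], positive)
  }
  mean(aucs, na.rm = TRUE)
}

# Internal: decision values oriented so larger means "positive class".
svm_scores <- function(model, x, positive) {
  dv <- attr(predict(model, x, decision.values = TRUE), "decision.values")
  parts <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  if (parts[1] == positive) as.numeric(dv) else -as.numeric(dv)
}

#' Enet-subset hybrid feature selection
#'
#' The optimal-subset extension of [enet_select()]: rank the
#' elastic-net-selected features by descending absolute coefficient,
#' then evaluate nested cross-validated AUC of a linear SVM on growing
#' top-k subsets (k = step, 2 step, ..., plus the full nonzero set,
#' always evaluated last) and keep the subset with maximal AUC (ties:
#' smaller subset). The elastic-net ranking is computed once and reused
#' for every subset.
#'
#' @inheritParams enet_select
#' @param step Subset-size increment (default 25).
#'
#' @return A `selection_result` with `method = "enet_subset"`, the
#'   chosen subset in `selected`, and the per-size AUC `subset_trace`.
#' @export
enet_subset_select <- function(train, cfg = enet_config(), step = 25,
                               seed = 1) {
  if (step < 1) stop("step must be >= 1", call. = FALSE)
  base <- enet_select(train, cfg, seed)
  nz <- length(base$selected)
  sizes <- unique(c(seq_len(nz %/% step) * step, nz))
  m <- as_feature_matrix(train)
  positive <- levels(m$y)[1]
  folds <- stratified_folds(m$y, cfg$cv_folds, seed + 1L)
  trace <- tibble::tibble(
    size = sizes,
    cv_auc = purrr::map_dbl(sizes, function(k) {
      svm_subset_cv_auc(m$x, m$y, base$selected[seq_len(k)], folds, positive)
    })
  )
  best <- dplyr::arrange(trace, dplyr::desc(round(.data$cv_auc, 12)),
                         .data$size)[1, ]
  out <- base
  out$method <- "enet_subset"
  out$selected <- base$selected[seq_len(best$size)]
  out$subset_trace <- trace
  out$best_size <- best$size
  out
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> method: ", x$method, "; ", length(x$selected),
      " of ", x$n_features_in, " features selected (lambda = ", x$lambda,
      ", alpha = ", x$alpha, ", selection CV-AUC = ",
      round(x$cv_auc, 3), ")\n", sep = "")
  invisible(x)
}

#' @describeIn enet_select Ranked coefficients of a selection result as
#'   a tibble (`feature`, `coefficient`, `rank`, `selected`).
#' @param x A `selection_result`.
#' @param ... Unused.
#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) {
  dplyr::mutate(x$coefficients,
                rank = dplyr::row_number(),
                selected = .data$feature %in% x$selected)
}

#' @describeIn enet_select One-row summary of a selection result.
#' @method glance selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(method = x$method,
                 n_features_in = x$n_features_in,
                 n_nonzero = nrow(x$coefficients),
                 n_selected = length(x$selected),
                 lambda = x$lambda, alpha = x$alpha,
                 selection_cv_auc = x$cv_auc)
}
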