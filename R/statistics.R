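#' Two-sample Wilcoxon rank-sum test with midranks
#'
#' Reports the Mann-Whitney U statistic for `x` and a two-sided
#' p-value. Without ties and with both groups below `exact_limit`, the
#' p-value comes from the exact null distribution of U
#' ([stats::pwilcox]); otherwise a continuity-corrected normal
#' approximation with tie-corrected variance is used. When every value
#' is tied the test is
#' uninformative and p = 1 with a warning.
#'
#' @param x,y Numeric samples for the two groups.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact
#'   distribution; default `NULL` applies the size rule. Exact p-values
#'   are unavailable with ties.
#' @param exact_limit Group size below which the exact distribution is
#'   used (default 10).
#'
#' @return List: `statistic` (U), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact = NULL, exact_limit = 10) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  all_vals <- c(x, y)
  r <- rank(all_vals, ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(all_vals)
  has_ties <- any(ties > 1)
  if (length(ties) == 1L) {
    warning("all values tied; rank-sum test is uninformative", call. = FALSE)
    return(list(statistic = u, p_value = 1, method = "degenerate"))
  }
  use_exact <- exact %||% (!has_ties && max(n1, n2) < exact_limit)
  if (use_exact && has_ties) {
    warning("ties present; falling back to the normal approximation",
            call. = FALSE)
    use_exact <- FALSE
  }
  if (use_exact) {
    lower <- pwilcox(u, n1, n2)
    upper <- 1 - pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (abs(u - mu) - 0.5) / sqrt(v) # continuity-corrected
    p <- min(1, 2 * pnorm(-max(z, 0)))
    method <- "normal"
  }
  list(statistic = u, p_value = p, method = method)
}

#' Node-wise rank-sum tests with FDR control
#'
#' Runs a two-sided rank-sum group comparison for every (node, metric)
#' pair of a metric table and adjusts the p-values by the
#' Benjamini-Hochberg step-up procedure, by default jointly across all
#' pairs.
#'
#' @param metric_tbl Long tibble from [compute_node_metrics()].
#' @param labels Tibble with `subject_id`, `group` (two groups, each
#'   with at least 2 subjects).
#' @param q Significance threshold on the adjusted p-value
#'   (default 0.05).
#' @param family `"joint"` (default) adjusts across nodes and metrics
#'   together; `"per_metric"` adjusts within each metric.
#'
#' @return Tibble: `node_id`, `metric`, `statistic`, `p_value`,
#'   `q_value`, `significant`.
#' @export
wilcoxon_by_node <- function(metric_tbl, labels, q = 0.05,
                             family = c("joint", "per_metric")) {
  family <- match.arg(family)
  stopifnot(all(c("subject_id", "node_id", "metric", "value") %in%
                  names(metric_tbl)),
            all(c("subject_id", "group") %in% names(labels)))
  groups <- sort(unique(labels$group))
  if (length(groups) != 2 || min(table(labels$group)) < 2) {
    stop("labels must define two groups with >= 2 subjects each",
         call. = FALSE)
  }
  tbl <- dplyr::left_join(metric_tbl,
                          dplyr::select(labels, "subject_id", "group"),
                          by = "subject_id")
  out <- dplyr::summarise(
    dplyr::group_by(tbl, .data$node_id, .data$metric),
    test = list(rank_sum_test(.data$value[.data$group == groups[1]],
                              .data$value[.data$group == groups[2]])),
    .groups = "drop"
  )
  out$statistic <- purrr::map_dbl(out$test, "statistic")
  out$p_value <- purrr::map_dbl(out$test, "p_value")
  out$test <- NULL
  if (family == "joint") {
    out$q_value <- p.adjust(out$p_value, method = "BH")
  } else {
    out <- dplyr::mutate(dplyr::group_by(out, .data$metric),
                         q_value = p.adjust(.data$p_value, method = "BH"))
    out <- dplyr::ungroup(out)
  }
  out$significant <- out$q_value < q
  out
}

#' Permutation-test significance of classifier performance
#'
#' Builds the null distribution of a protocol statistic (mean accuracy
#' or AUC over iterations) by shuffling the group labels once per
#' permutation and re-running the full protocol — including feature
#' selection, which must sit inside the null to avoid optimistic bias.
#' The p-value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (1 + n_perm)`, so it is never exactly
#' zero.
#'
#' @param table A [feature_table()].
#' @param cfg An [eval_config()] for the observed run.
#' @param n_perm Number of permutations (default 1000; at least 20).
#' @param statistic Per-iteration field averaged into the test
#'   statistic.
#' @param selector,enet_cfg,step Passed to [run_protocol()].
#' @param n_iter_perm Iterations per permutation run; defaults to the
#'   observed `cfg$n_iterations`. A reduced count is permitted and
#'   logged, trading null resolution for runtime (conservative under
#'   the null).
#' @param observed Optional precomputed `evaluation_report` for the
#'   unpermuted labels.
#'
#' @return A `permutation_null`: `observed`, `null_values`, `n_perm`,
#'   `p_value`, `statistic`.
#' @export
permutation_test <- function(table, cfg = eval_config(), n_perm = 1000,
                             statistic = c("accuracy", "auc",
                                           "sensitivity", "specificity"),
                             selector = "enet_subset",
                             enet_cfg = enet_config(), step = 25,
                             n_iter_perm = NULL, observed = NULL) {
  statistic <- match.arg(statistic)
  if (n_perm < 20) {
    stop("n_perm must be >= 20 (p-value resolution too coarse)",
         call. = FALSE)
  }
  if (is.null(observed)) {
    observed <- run_protocol(table, selector, cfg, enet_cfg, step)
  }
  obs <- mean(observed$per_iteration[[statistic]], na.rm = TRUE)
  n_iter_perm <- as.integer(n_iter_perm %||% cfg$n_iterations)
  if (n_iter_perm < cfg$n_iterations) {
    message("permutation null uses ", n_iter_perm,
            " protocol iteration(s) per permutation (observed used ",
            cfg$n_iterations, ")")
  }
  set.seed(cfg$seed)
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  null_values <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(perm_seeds[b])
    tbl_b <- table
    tbl_b$group <- sample(tbl_b$group)
    cfg_b <- cfg
    cfg_b$n_iterations <- n_iter_perm
    cfg_b$seed <- perm_seeds[b] %% 100000L
    rep_b <- run_protocol(tbl_b, selector, cfg_b, enet_cfg, step)
    null_values[b] <- mean(rep_b$per_iteration[[statistic]], na.rm = TRUE)
  }
  structure(list(observed = obs, null_values = null_values,
                 n_perm = n_perm,
                 p_value = (1 + sum(null_values >= obs)) / (1 + n_perm),
                 statistic = statistic),
            class = "permutation_null")
}

# Internal: add-one permutation p-value, shared with permutation_test().
perm_pvalue <- function(observed, null_values) {
  (1 + sum(null_values >= observed)) / (1 + length(null_values))
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("<permutation_null> statistic: ", x$statistic,
      sprintf("; observed = %.4f, p = %.4g (%d permutations)\n",
              x$observed, x$p_value, x$n_perm), sep = "")
  invisible(x)
}

#' @describeIn permutation_test Null distribution as a tibble.
#' @param x A `permutation_null`.
#' @param ... Unused.
#' @method tidy permutation_null
#' @export
tidy.permutation_null <- function(x, ...) {
  tibble::tibble(permutation = seq_len(x$n_perm), value = x$null_values)
}

#' @describeIn permutation_test One-row summary.
#' @method glance permutation_null
#' @export
glance.permutation_null <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, observed = x$observed,
                 n_perm = x$n_perm, p_value = x$p_value,
                 null_mean = mean(x$null_values),
                 null_q95 = unname(quantile(x$null_values, 0.95)))
}

#' Correlate node metrics with disability scores
#'
#' Pearson correlation (with two-sided p) between each (node, metric)
#' column and the subjects' disability scores, optionally restricted to
#' a feature subset such as the top-60 most frequently selected
#' features.
#'
#' @param metric_tbl Long tibble from [compute_node_metrics()].
#' @param scores Tibble with `subject_id` and `odi`; subjects with
#'   missing scores are dropped.
#' @param features Optional restriction: a character vector of
#'   `<metric>_<node_id>` feature ids or a tibble with `node_id` and
#'   `metric` columns.
#'
#' @return Tibble: `node_id`, `metric`, `estimate`, `p_value`, `n`;
#'   zero-variance inputs yield `NA` estimates and are flagged in
#'   `degenerate`.
#' @export
correlate_with_disability <- function(metric_tbl, scores, features = NULL) {
  stopifnot(all(c("subject_id", "odi") %in% names(scores)))
  tbl <- dplyr::inner_join(metric_tbl,
                           dplyr::select(scores, "subject_id", "odi"),
                           by = "subject_id")
  tbl <- dplyr::filter(tbl, !is.na(.data$odi))
  if (!is.null(features)) {
    if (is.character(features)) {
      tbl <- dplyr::filter(tbl, paste(.data$metric, .data$node_id,
                                      sep = "_") %in% features)
    } else {
      tbl <- dplyr::semi_join(tbl, features, by = c("node_id", "metric"))
    }
  }
  dplyr::summarise(
    dplyr::group_by(tbl, .data$node_id, .data$metric),
    n = dplyr::n(),
    degenerate = sd(.data$value) == 0 || sd(.data$odi) == 0 || .data$n[1] < 3,
    estimate = if (.data$degenerate[1]) NA_real_ else
      unname(cor.test(.data$value, .data$odi)$estimate),
    p_value = if (.data$degenerate[1]) NA_real_ else
      cor.test(.data$value, .data$odi)$p.value,
    .groups = "drop"
  )
}
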