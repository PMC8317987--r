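#' Read a subject table
#'
#' Expects delimited text with a header of `subject_id`, `group` and
#' optionally `odi` (a 0-100 disability score). Validation errors name
#' the offending line.
#'
#' @param path File path.
#' @param delim Field delimiter (default comma).
#'
#' @return Tibble with `subject_id` (character), `group` and, when
#'   present, `odi`.
#' @export
read_subject_table <- function(path, delim = ",") {
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("subject_id", "group") %in% names(tbl))) {
    stop("subject table needs columns subject_id and group", call. = FALSE)
  }
  dup <- tbl$subject_id[duplicated(tbl$subject_id)]
  if (length(dup)) {
    stop("duplicated subject_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  groups <- unique(tbl$group)
  if (length(groups) > 2) {
    bad <- which(!tbl$group %in% groups[1:2])[1]
    stop("more than two group labels; first unexpected label '",
         tbl$group[bad], "' at line ", bad + 1, call. = FALSE)
  }
  if ("odi" %in% names(tbl)) {
    odi <- suppressWarnings(as.numeric(tbl$odi))
    bad <- which((!is.na(tbl$odi) & is.na(odi)) |
                   (!is.na(odi) & (odi < 0 | odi > 100)))
    if (length(bad)) {
      stop("malformed or out-of-range odi score '", tbl$odi[bad[1]],
           "' at line ", bad[1] + 1, " (must be a number in [0, 100])",
           call. = FALSE)
    }
    tbl$odi <- odi
  }
  tbl
}

#' Read and write parcel time series
#'
#' Series files are delimited text with a `node_id` column followed by
#' one column per timepoint.
#'
#' @param series Nodes-by-timepoints numeric matrix.
#' @param path File path.
#' @param delim Field delimiter (default comma).
#'
#' @return `read_series()` returns the matrix with node ids as
#'   rownames; `write_series()` returns `path` invisibly.
#' @export
write_series <- function(series, path, delim = ",") {
  df <- data.frame(node_id = rownames(series) %||% seq_len(nrow(series)),
                   series, check.names = FALSE)
  names(df)[-1] <- paste0("t", seq_len(ncol(series)))
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path, delim = ",") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  colnames(m) <- NULL
  m
}

#' Read and write connectivity matrices
#'
#' Matrices are written as delimited text with a header row of node ids
#' and a leading `node_id` column; the excluded diagonal round-trips as
#' empty fields.
#'
#' @param fc An [compute_fc()] matrix.
#' @param path File path.
#' @param delim Field delimiter (default comma).
#'
#' @return `read_fc_matrix()` returns an `fc_matrix`;
#'   `write_fc_matrix()` returns `path` invisibly.
#' @export
write_fc_matrix <- function(fc, path, delim = ",") {
  ids <- attr(fc, "node_ids") %||% rownames(fc)
  df <- data.frame(node_id = ids, unclass(fc), check.names = FALSE)
  names(df)[-1] <- ids
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' @rdname write_fc_matrix
#' @export
read_fc_matrix <- function(path, delim = ",") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  ids <- as.character(df[[1]])
  dimnames(m) <- list(ids, ids)
  diag(m) <- NA_real_
  structure(m, node_ids = ids, subject_id = NA_character_,
            class = c("fc_matrix", "matrix", "array"))
}

#' Write a synthetic cohort to a directory
#'
#' Writes one series file per subject (`series_<id>.csv`), the subject
#' table (`subjects.csv`, with `odi` when present), and
#' `ground_truth.json` echoing the generating spec and the synthetic
#' affected-node set (a generator construct, not an empirical quantity).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#'
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- dplyr::select(cohort$subjects, -"series")
  readr::write_csv(subjects, file.path(dir, "subjects.csv"))
  purrr::walk2(cohort$subjects$series, cohort$subjects$subject_id,
               ~ write_series(.x, file.path(dir, paste0("series_", .y, ".csv"))))
  jsonlite::write_json(
    list(affected_nodes = cohort$affected_nodes,
         note = "synthetic ground truth from the cohort generator",
         spec = unclass(cohort$spec)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `subjects.csv` and per-subject
#'   series files.
#'
#' @return List with `subjects` (tibble with `series` list-column) and,
#'   when `ground_truth.json` is present, `affected_nodes` and the spec
#'   echo.
#' @export
read_cohort <- function(dir) {
  subjects <- read_subject_table(file.path(dir, "subjects.csv"))
  subjects$series <- purrr::map(subjects$subject_id, function(id) {
    read_series(file.path(dir, paste0("series_", id, ".csv")))
  })
  out <- list(subjects = subjects)
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    out$affected_nodes <- gt$affected_nodes
    out$spec_echo <- gt$spec
  }
  out
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]. Provide
#' either an in-memory cohort (`cohort`, or any tibble with
#' `subject_id`, `group` and a `series` list-column) or a directory
#' written by [write_cohort()] via `cohort_dir`.
#'
#' @param cohort In-memory cohort (takes precedence).
#' @param cohort_dir Directory with `subjects.csv` and series files.
#' @param metrics Metric combination, non-empty subset of
#'   `c("BC", "CC", "DC", "LE")`.
#' @param selector Feature-selection method flag.
#' @param densities Density grid.
#' @param enet An [enet_config()].
#' @param eval An [eval_config()].
#' @param n_perm Permutations for the significance test (>= 20);
#'   `0` skips the permutation stage.
#' @param n_iter_perm Protocol iterations per permutation.
#' @param statistic Permuted statistic.
#' @param out_dir Output directory for the artifact files.
#' @param seed Pipeline seed (overrides `eval$seed`).
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, cohort_dir = NULL,
                            metrics = c("BC", "CC", "DC"),
                            selector = c("enet_subset", "enet", "none"),
                            densities = default_density_grid(),
                            enet = enet_config(), eval = eval_config(),
                            n_perm = 99, n_iter_perm = 1,
                            statistic = "accuracy",
                            out_dir = tempfile("graphmarker_run_"),
                            seed = 1) {
  if (is.null(cohort) && is.null(cohort_dir)) {
    stop("provide a cohort or a cohort_dir", call. = FALSE)
  }
  metrics <- match.arg(metrics, c("BC", "CC", "DC", "LE"), several.ok = TRUE)
  structure(list(cohort = cohort, cohort_dir = cohort_dir,
                 metrics = metrics, selector = match.arg(selector),
                 densities = densities, enet = enet, eval = eval,
                 n_perm = n_perm, n_iter_perm = n_iter_perm,
                 statistic = statistic, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Connectivity, density-averaged graph metrics, feature selection,
#' the repeated SVM protocol, node-wise rank-sum statistics,
#' permutation significance and (when disability scores are present)
#' metric-disability correlations, with every result written to the
#' output directory as delimited text or JSON alongside a config echo
#' and a log of the seeds used.
#'
#' @param config A [pipeline_config()].
#'
#' @return Invisibly, a list with the in-memory results (`metric_tbl`,
#'   `selection`, `report`, `node_tests`, `permutation`, `correlations`)
#'   and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_add <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cfg <- config$eval
  cfg$seed <- config$seed
  log_add("pipeline seed: ", config$seed)
  log_add("metrics: ", paste(config$metrics, collapse = "+"),
          "; selector: ", config$selector)
  log_add("densities: ", paste(config$densities, collapse = ", "))
  log_add("iteration seeds: ", cfg$seed + 1, "..",
          cfg$seed + cfg$n_iterations)

  subjects <- stage("input", {
    if (!is.null(config$cohort)) {
      if (inherits(config$cohort, "synthetic_cohort")) {
        config$cohort$subjects
      } else {
        config$cohort
      }
    } else {
      read_cohort(config$cohort_dir)$subjects
    }
  })

  fc_tbl <- stage("connectivity", cohort_fc(subjects))
  metric_tbl <- stage("graph_metrics", {
    m <- compute_node_metrics(fc_tbl, config$densities,
                              unique(c(config$metrics)))
    readr::write_csv(m, file.path(config$out_dir, "metrics.csv"))
    m
  })

  labels <- dplyr::select(subjects, "subject_id", "group")
  ft <- stage("feature_table",
              feature_table(metric_tbl, labels, config$metrics))

  selection <- stage("feature_selection", {
    split <- stratified_split(ft, cfg$split_ratio, seed = config$seed)
    sel <- if (config$selector == "enet") {
      enet_select(split$train, config$enet, seed = config$seed)
    } else if (config$selector == "enet_subset") {
      enet_subset_select(split$train, config$enet, seed = config$seed)
    } else NULL
    if (!is.null(sel)) {
      jsonlite::write_json(
        list(method = sel$method, lambda = sel$lambda, alpha = sel$alpha,
             selection_cv_auc = sel$cv_auc, n_selected = length(sel$selected),
             selected = sel$selected,
             subset_trace = sel$subset_trace),
        file.path(config$out_dir, "selection.json"),
        auto_unbox = TRUE, digits = NA
      )
      readr::write_csv(tidy(sel),
                       file.path(config$out_dir, "selection_ranked.csv"))
    }
    sel
  })

  report <- stage("classification", {
    rep <- run_protocol(ft, config$selector, cfg, config$enet)
    readr::write_csv(tidy(rep),
                     file.path(config$out_dir, "per_iteration.csv"))
    readr::write_csv(rep$feature_frequency,
                     file.path(config$out_dir, "feature_frequency.csv"))
    jsonlite::write_json(as.list(glance(rep)),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    rep
  })

  node_tests <- stage("statistics", {
    nt <- wilcoxon_by_node(metric_tbl, labels)
    readr::write_csv(nt, file.path(config$out_dir, "node_tests.csv"))
    nt
  })

  permutation <- NULL
  if (config$n_perm >= 20) {
    permutation <- stage("permutation", {
      pt <- permutation_test(ft, cfg, n_perm = config$n_perm,
                             statistic = config$statistic,
                             selector = config$selector,
                             enet_cfg = config$enet,
                             n_iter_perm = config$n_iter_perm,
                             observed = report)
      jsonlite::write_json(as.list(glance(pt)),
                           file.path(config$out_dir, "permutation.json"),
                           auto_unbox = TRUE, digits = NA)
      pt
    })
    log_add("permutation: ", config$n_perm, " permutations, ",
            config$n_iter_perm, " iteration(s) each")
  }

  correlations <- NULL
  if ("odi" %in% names(subjects)) {
    correlations <- stage("correlation", {
      top <- top_selected_features(report, 60)
      co <- correlate_with_disability(metric_tbl,
                                      dplyr::select(subjects, "subject_id",
                                                    "odi"),
                                      features = top$feature)
      readr::write_csv(co, file.path(config$out_dir, "odi_correlations.csv"))
      co
    })
  }

  echo <- unclass(config)
  echo$cohort <- NULL
  echo$enet <- unclass(echo$enet)
  echo$eval <- unclass(echo$eval)
  jsonlite::write_json(echo, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))

  invisible(list(metric_tbl = metric_tbl, selection = selection,
                 report = report, node_tests = node_tests,
                 permutation = permutation, correlations = correlations,
                 out_dir = config$out_dir))
}
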