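#' Compute a functional connectivity matrix from parcel time series
#'
#' Off-diagonal entries are Fisher-z-transformed Pearson correlations,
#' `atanh(r)`, between node time series; `r` is clipped to
#' `(-1 + 1e-12, 1 - 1e-12)` before the transform so perfectly
#' correlated series map to a large finite value. The diagonal is not a
#' usable edge weight and is stored as `NA` (self-connections are never
#' thresholded or used by the graph metrics).
#'
#' @param series Numeric nodes-by-timepoints matrix (at least 3
#'   timepoints; every node series must have nonzero variance).
#' @param node_ids Optional node identifiers; defaults to the series
#'   rownames or `1:N`.
#' @param subject_id Optional owner id carried as an attribute.
#'
#' @return An `fc_matrix`: a symmetric numeric matrix with `NA`
#'   diagonal and attributes `node_ids` and `subject_id`.
#' @examples
#' set.seed(1)
#' fc <- compute_fc(matrix(rnorm(5 * 40), 5, 40))
#' fc[1:3, 1:3]
#' @export
compute_fc <- function(series, node_ids = NULL, subject_id = NA_character_) {
  if (!is.matrix(series) || !is.numeric(series)) {
    stop("series must be a numeric nodes-by-timepoints matrix", call. = FALSE)
  }
  if (ncol(series) < 3) {
    stop("series must have at least 3 timepoints", call. = FALSE)
  }
  if (anyNA(series) || any(!is.finite(series))) {
    stop("series contains NA or non-finite values", call. = FALSE)
  }
  node_ids <- node_ids %||% rownames(series) %||% as.character(seq_len(nrow(series)))
  v <- apply(series, 1, stats::var)
  if (any(v == 0)) {
    stop("constant time series for node(s): ",
         paste(node_ids[v == 0], collapse = ", "), call. = FALSE)
  }
  r <- cor(t(series))
  eps <- 1e-12
  r <- pmin(pmax(r, -1 + eps), 1 - eps)
  z <- atanh(r)
  z <- (z + t(z)) / 2  # enforce exact symmetry
  diag(z) <- NA_real_
  dimnames(z) <- list(node_ids, node_ids)
  structure(z, node_ids = node_ids, subject_id = subject_id,
            class = c("fc_matrix", "matrix", "array"))
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat("<fc_matrix> ", nrow(x), " x ", ncol(x),
      " Fisher-z connectivity (diagonal excluded), subject: ",
      attr(x, "subject_id"), "\n", sep = "")
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x)))])
  invisible(x)
}

#' Average member (e.g. voxel or vertex) series into parcel series
#'
#' @param voxel_series Numeric members-by-timepoints matrix.
#' @param membership Node assignment, one value per member row.
#'
#' @return Nodes-by-timepoints matrix of arithmetic mean series, rows
#'   ordered by sorted unique membership value.
#' @export
mean_parcel_series <- function(voxel_series, membership) {
  if (!is.matrix(voxel_series) || nrow(voxel_series) != length(membership)) {
    stop("membership must assign a node to every row of voxel_series",
         call. = FALSE)
  }
  counts <- table(membership)
  if (any(counts == 0)) stop("every node needs at least one member", call. = FALSE)
  out <- rowsum(voxel_series, group = membership, reorder = TRUE)
  out / as.vector(counts[rownames(out)])
}

#' Compute connectivity matrices for every subject of a cohort
#'
#' @param cohort A `synthetic_cohort`, or a tibble with columns
#'   `subject_id` and a `series` list-column.
#'
#' @return A tibble with `subject_id`, `group` (if present) and an
#'   `fc` list-column of [compute_fc()] matrices.
#' @export
cohort_fc <- function(cohort) {
  subjects <- if (inherits(cohort, "synthetic_cohort")) cohort$subjects else cohort
  stopifnot(is.data.frame(subjects), "series" %in% names(subjects))
  out <- dplyr::select(subjects, -"series")
  out$fc <- purrr::map2(subjects$series, subjects$subject_id,
                        ~ compute_fc(.x, subject_id = .y))
  tibble::as_tibble(out)
}
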