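#' Specify a synthetic two-group resting-state cohort
#'
#' Describes a cohort of healthy-control (HC) and patient (LBP) subjects
#' whose parcel time series are drawn from group-specific latent
#' covariance matrices. The patient covariance differs from the control
#' covariance only at a set of "affected" nodes, whose off-diagonal
#' covariances are attenuated by the factor `1 / (1 + effect_size)`, so
#' `effect_size = 0` yields an exact null cohort (identical group
#' covariances) and increasing values progressively disconnect the
#' affected parcels.
#'
#' @param n_hc Number of control subjects (default 27).
#' @param n_lbp Number of patient subjects (default 24).
#' @param n_nodes Number of parcels (default 360).
#' @param n_timepoints Samples per series (default 2250, i.e. six 5-min
#'   runs at a repetition time of 0.8 s).
#' @param n_affected Number of nodes carrying the group effect
#'   (default 10% of `n_nodes`).
#' @param effect_size Non-negative strength of the group effect on the
#'   covariance scale; 0 gives a null cohort.
#' @param noise_sd Standard deviation of independent observation noise
#'   added to each sample.
#' @param seed Integer RNG seed; generation is bit-reproducible given
#'   the spec.
#'
#' @return A `cohort_spec` object (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_hc = 27, n_lbp = 24, n_nodes = 360,
                        n_timepoints = 2250,
                        n_affected = round(0.1 * n_nodes),
                        effect_size = 1, noise_sd = 1, seed = 1) {
  counts <- c(n_hc = n_hc, n_lbp = n_lbp, n_nodes = n_nodes,
              n_timepoints = n_timepoints)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("n_hc, n_lbp, n_nodes and n_timepoints must be integers >= 1",
         call. = FALSE)
  }
  if (n_affected < 0 || n_affected != round(n_affected)) {
    stop("n_affected must be a non-negative integer", call. = FALSE)
  }
  if (n_affected > n_nodes) {
    stop("n_affected must not exceed n_nodes", call. = FALSE)
  }
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(n_hc = as.integer(n_hc), n_lbp = as.integer(n_lbp),
         n_nodes = as.integer(n_nodes),
         n_timepoints = as.integer(n_timepoints),
         n_affected = as.integer(n_affected),
         effect_size = effect_size, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_hc, " HC + ", x$n_lbp, " LBP, ",
      x$n_nodes, " nodes x ", x$n_timepoints, " timepoints; ",
      x$n_affected, " affected nodes, effect_size = ", x$effect_size,
      ", noise_sd = ", x$noise_sd, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

# Base latent covariance: random community structure (compound-symmetric
# blocks over a weak global background) plus a low-rank random
# component, rescaled to a correlation matrix. Positive definite by
# construction before rescaling.
build_base_covariance <- function(n_nodes) {
  n_comm <- max(2L, ceiling(n_nodes / 15))
  comm <- sample(rep_len(seq_len(n_comm), n_nodes))
  sigma <- matrix(0.05, n_nodes, n_nodes)
  same <- outer(comm, comm, `==`)
  sigma[same] <- 0.30
  diag(sigma) <- 1
  q <- max(2L, ceiling(n_nodes / 20))
  loadings <- matrix(rnorm(n_nodes * q, sd = 0.15), n_nodes, q)
  sigma <- sigma + tcrossprod(loadings)
  d <- sqrt(diag(sigma))
  sigma / outer(d, d)
}

# Clip eigenvalues at a small floor to repair indefiniteness introduced
# by the group perturbation; deterministic.
nearest_pd <- function(sigma, floor = 1e-8) {
  sigma <- (sigma + t(sigma)) / 2
  eig <- eigen(sigma, symmetric = TRUE)
  if (min(eig$values) >= floor) return(sigma)
  vals <- pmax(eig$values, floor)
  out <- eig$vectors %*% (vals * t(eig$vectors))
  (out + t(out)) / 2
}

#' Generate a synthetic two-group cohort of parcel time series
#'
#' Draws each subject's node-by-time series as zero-mean correlated
#' Gaussian samples from their group's latent covariance, plus
#' independent observation noise. The patient covariance attenuates the
#' off-diagonal covariances of the affected nodes by
#' `1 / (1 + effect_size)` and is re-projected to the nearest
#' positive-definite matrix by eigenvalue clipping. Ground truth
#' (affected node set, both latent covariances, the spec) travels with
#' the result.
#'
#' @param spec A [cohort_spec()].
#'
#' @return A `synthetic_cohort`: a list with `subjects` (a tibble with
#'   columns `subject_id`, `group`, and a `series` list-column of
#'   nodes-by-timepoints matrices), `affected_nodes` (integer node ids),
#'   `group_covariances` (named list `HC`, `LBP`), and `spec`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(
#'   n_hc = 4, n_lbp = 4, n_nodes = 12, n_timepoints = 50,
#'   n_affected = 3, effect_size = 1.5, seed = 7))
#' cohort$subjects
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  sigma_hc <- build_base_covariance(spec$n_nodes)
  affected <- sort(sample.int(spec$n_nodes, spec$n_affected))

  atten <- 1 / (1 + spec$effect_size)
  sigma_lbp <- sigma_hc
  if (spec$n_affected > 0 && spec$effect_size > 0) {
    scale <- rep(1, spec$n_nodes)
    scale[affected] <- atten
    d <- diag(sigma_lbp)
    sigma_lbp <- sigma_lbp * outer(scale, scale)
    diag(sigma_lbp) <- d
    sigma_lbp <- nearest_pd(sigma_lbp)
  }

  chol_hc <- chol(sigma_hc)
  chol_lbp <- tryCatch(chol(sigma_lbp), error = function(e) {
    stop("patient covariance is not positive definite after repair: ",
         conditionMessage(e), call. = FALSE)
  })

  draw_series <- function(chol_u) {
    z <- matrix(rnorm(spec$n_nodes * spec$n_timepoints),
                spec$n_nodes, spec$n_timepoints)
    x <- crossprod(chol_u, z)
    if (spec$noise_sd > 0) {
      x <- x + matrix(rnorm(length(x), sd = spec$noise_sd), nrow(x))
    }
    rownames(x) <- seq_len(spec$n_nodes)
    x
  }

  n_total <- spec$n_hc + spec$n_lbp
  ids <- sprintf("S%03d", seq_len(n_total))
  groups <- c(rep("HC", spec$n_hc), rep("LBP", spec$n_lbp))
  series <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    series[[i]] <- draw_series(if (groups[i] == "HC") chol_hc else chol_lbp)
  }

  structure(
    list(
      subjects = tibble::tibble(subject_id = ids, group = groups,
                                series = series),
      affected_nodes = affected,
      group_covariances = list(HC = sigma_hc, LBP = sigma_lbp),
      spec = spec
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$subjects), " subjects (",
      sum(x$subjects$group == "HC"), " HC / ",
      sum(x$subjects$group == "LBP"), " LBP), ",
      x$spec$n_nodes, " nodes, ", x$spec$n_timepoints, " timepoints, ",
      length(x$affected_nodes), " affected nodes\n", sep = "")
  invisible(x)
}

# Location parameter of a [0, 100]-truncated normal whose mean equals
# the target (truncation at 0 would otherwise inflate low group means).
truncnorm_location <- function(target, s) {
  if (s == 0) return(target)
  trunc_mean <- function(mu) {
    a <- (0 - mu) / s
    b <- (100 - mu) / s
    mu + s * (stats::dnorm(a) - stats::dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  stats::uniroot(function(mu) trunc_mean(mu) - target,
                 lower = target - 6 * s, upper = target + 6 * s,
                 tol = 1e-10)$root
}

#' Add disability (ODI-like) scores to a cohort
#'
#' Draws per-subject functional-disability scores from group-specific
#' normal distributions truncated to the instrument's 0-100 range via
#' the inverse-CDF method; the location parameter is moment-matched so
#' the truncated distribution's mean equals the requested group mean.
#' Defaults reproduce the reported group moments of the Oswestry
#' Disability Index (controls 5.63 +/- 5.60, patients 33.3 +/- 15.3).
#'
#' @param cohort A `synthetic_cohort`.
#' @param hc_mean,hc_sd Control-group mean and SD on the 0-100 scale.
#' @param lbp_mean,lbp_sd Patient-group mean and SD.
#' @param seed Integer RNG seed for the score draw.
#'
#' @return The cohort with an `odi` column added to `subjects`.
#' @export
generate_disability_scores <- function(cohort, hc_mean = 5.63,
                                       hc_sd = 5.60, lbp_mean = 33.3,
                                       lbp_sd = 15.3, seed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (hc_sd < 0 || lbp_sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (any(c(hc_mean, lbp_mean) < 0) || any(c(hc_mean, lbp_mean) > 100)) {
    stop("group means must lie in [0, 100]", call. = FALSE)
  }
  set.seed(seed)
  grp <- cohort$subjects$group
  mu_hc <- truncnorm_location(hc_mean, hc_sd)
  mu_lbp <- truncnorm_location(lbp_mean, lbp_sd)
  mu <- ifelse(grp == "HC", mu_hc, mu_lbp)
  s <- ifelse(grp == "HC", hc_sd, lbp_sd)
  odi <- numeric(length(grp))
  pos <- s > 0
  if (any(pos)) {
    lo <- pnorm((0 - mu[pos]) / s[pos])
    hi <- pnorm((100 - mu[pos]) / s[pos])
    odi[pos] <- mu[pos] + s[pos] * qnorm(runif(sum(pos), lo, hi))
  }
  odi[!pos] <- mu[!pos]
  cohort$subjects$odi <- odi
  cohort
}
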