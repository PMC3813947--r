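#' Per-cluster PCA with Hotelling T-squared distances
#'
#' Even after k-means every spike is forced into some cluster, so a cluster
#' may still harbor heterogeneous waveforms. Each cluster is therefore
#' modelled by a centered PCA of its members; the Hotelling T-squared distance
#' of member `x` is `sum_j score_j(x)^2 / lambda_j` over the retained
#' components (the multivariate analogue of a squared t-statistic). Members
#' beyond the cutoff at the configured coverage `scope` are "T2-unselected"
#' outliers, to be re-examined by the subtraction algorithm.
#'
#' The cutoff is the `scope` quantile of `p(n-1)/(n-p) * F(p, n-p)` (the null
#' of T-squared with estimated mean and covariance); for `n <= p` the
#' chi-squared(p) quantile is the large-n fallback. Components with eigenvalue
#' below `min_eigen_frac` of the leading eigenvalue are dropped as numerical
#' rank deficiency.
#'
#' @param cluster_data Numeric matrix, rows = spikes of one cluster (z-space).
#' @param scope Coverage probability of the homogeneity region
#'   (default 0.9999).
#' @param min_eigen_frac Relative eigenvalue floor for retaining components
#'   (default 1e-10).
#' @param iterate If `TRUE`, refit after removing flagged members until the
#'   flagged set is stable (or `max_iter` refits). The default is a single
#'   pass: iterating shrinks the cutoff progressively because each refit
#'   estimates a tighter covariance.
#' @param max_iter Refit cap when `iterate = TRUE` (default 20).
#' @return An `oligo_t2`: `center`, `loadings` (orthonormal columns),
#'   `eigenvalues` (non-increasing), `n_components`, `t2` (per spike; for
#'   iterated fits, the T2 of every original member under the final model),
#'   `t2_cutoff`, `scope`, `n`.
#' @export
fit_t2 <- function(cluster_data, scope = 0.9999, min_eigen_frac = 1e-10,
                   iterate = FALSE, max_iter = 20) {
  m <- as.matrix(cluster_data)
  if (iterate) {
    keep <- rep(TRUE, nrow(m))
    for (it in seq_len(max_iter)) {
      fit <- fit_t2(m[keep, , drop = FALSE], scope = scope,
                    min_eigen_frac = min_eigen_frac)
      # score all original members under the current model
      centered <- sweep(m, 2, fit$center)
      scores <- centered %*% fit$loadings
      t2_all <- rowSums(sweep(scores^2, 2, fit$eigenvalues, "/"))
      new_keep <- t2_all <= fit$t2_cutoff
      if (identical(new_keep, keep)) break
      keep <- new_keep
    }
    fit$t2 <- t2_all
    fit$n <- nrow(m)
    return(fit)
  }
  n <- nrow(m)
  if (n <= ncol(m)) {
    stop("cluster size must exceed the dimension for a stable PCA",
         call. = FALSE)
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (ev[1] <= 0) stop("cluster has zero variance", call. = FALSE)
  keep <- ev > min_eigen_frac * ev[1]
  if (any(!keep)) {
    warning(sum(!keep), " near-zero-variance component(s) dropped",
            call. = FALSE)
  }
  p <- sum(keep)
  scores <- pc$x[, keep, drop = FALSE]
  t2 <- rowSums(sweep(scores^2, 2, ev[keep], "/"))
  cutoff <- if (n - p > 0) {
    p * (n - 1) / (n - p) * qf(scope, p, n - p)
  } else {
    qchisq(scope, p)
  }
  structure(
    list(center = pc$center, loadings = pc$rotation[, keep, drop = FALSE],
         eigenvalues = ev[keep], n_components = p, t2 = t2,
         t2_cutoff = cutoff, scope = scope, n = n),
    class = "oligo_t2"
  )
}

#' @export
print.oligo_t2 <- function(x, ...) {
  cat(sprintf("<oligo_t2> n = %d, %d component(s); cutoff(T2, scope %.4f%%) = %.3f; %d outlier(s)\n",
              x$n, x$n_components, 100 * x$scope, x$t2_cutoff,
              sum(x$t2 > x$t2_cutoff)))
  invisible(x)
}

#' Select homogeneous cluster members by T-squared distance
#'
#' @param model An [fit_t2()] result.
#' @return A list: `selected` / `unselected` row indices (unselected have
#'   `t2 > t2_cutoff`), counts, and the unselected fraction.
#' @export
select_by_t2 <- function(model) {
  stopifnot(inherits(model, "oligo_t2"))
  out <- model$t2 > model$t2_cutoff
  list(
    selected = which(!out),
    unselected = which(out),
    n_selected = sum(!out),
    n_unselected = sum(out),
    fraction_unselected = mean(out)
  )
}
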