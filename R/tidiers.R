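#' Tidy a spike k-means model
#'
#' @param x An `oligo_kmeans`.
#' @param ... Unused.
#' @return One row per cluster: `cluster`, `size`, and the centroid
#'   coordinates.
#' @method tidy oligo_kmeans
#' @export
tidy.oligo_kmeans <- function(x, ...) {
  k <- x$k
  sizes <- tabulate(x$labels, k)
  cent <- tibble::as_tibble(x$centroids, .name_repair = "minimal")
  names(cent) <- colnames(x$centroids) %||% paste0("dim", seq_len(ncol(cent)))
  dplyr::bind_cols(tibble::tibble(cluster = seq_len(k), size = sizes), cent)
}

#' Glance at a spike k-means model
#' @inheritParams tidy.oligo_kmeans
#' @return One row: `k`, `metric`, `n`, `inertia`, `iterations`.
#' @method glance oligo_kmeans
#' @export
glance.oligo_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, metric = x$metric, n = length(x$labels),
                 inertia = x$inertia, iterations = x$iterations)
}

#' Tidy a silhouette report
#' @param x An `oligo_silhouette`.
#' @param ... Unused.
#' @return The per-spike silhouette tibble.
#' @method tidy oligo_silhouette
#' @export
tidy.oligo_silhouette <- function(x, ...) x$values

#' @rdname tidy.oligo_silhouette
#' @method glance oligo_silhouette
#' @export
glance.oligo_silhouette <- function(x, ...) {
  tibble::tibble(overall_mean = x$overall_mean, metric = x$metric,
                 n_clusters = nrow(x$cluster_means))
}

#' Tidy a T-squared homogeneity model
#' @param x An `oligo_t2`.
#' @param ... Unused.
#' @return One row per cluster member: `spike`, `t2`, `selected`.
#' @method tidy oligo_t2
#' @export
tidy.oligo_t2 <- function(x, ...) {
  tibble::tibble(spike = seq_along(x$t2), t2 = x$t2,
                 selected = x$t2 <= x$t2_cutoff)
}

#' @rdname tidy.oligo_t2
#' @method glance oligo_t2
#' @export
glance.oligo_t2 <- function(x, ...) {
  tibble::tibble(n = x$n, n_components = x$n_components,
                 t2_cutoff = x$t2_cutoff, scope = x$scope,
                 fraction_unselected = mean(x$t2 > x$t2_cutoff))
}

#' Tidy a Gaussian ISI-curve fit
#' @param x An `oligo_gauss_fit`.
#' @param ... Unused.
#' @return One row per mode: `mode`, `a` (peak pd), `b` (mode, ln s),
#'   `c` (width, ln s), `mode_isi_s` (`exp(b)`).
#' @method tidy oligo_gauss_fit
#' @export
tidy.oligo_gauss_fit <- function(x, ...) {
  if (!x$converged) return(tibble::tibble())
  dplyr::mutate(
    dplyr::bind_cols(tibble::tibble(mode = seq_len(x$k_modes)), x$params),
    mode_isi_s = exp(.data$b)
  )
}

#' @rdname tidy.oligo_gauss_fit
#' @method glance oligo_gauss_fit
#' @export
glance.oligo_gauss_fit <- function(x, ...) {
  tibble::tibble(k_modes = x$k_modes, ssr = x$ssr, n_b = x$n_b, K = x$K,
                 aicc = x$aicc, adjusted_r = x$adjusted_r,
                 converged = x$converged)
}

#' Tidy a feature-vs-ISI fit
#' @param x An `oligo_feature_isi`.
#' @param ... Unused.
#' @return The binned observed/predicted tibble.
#' @method tidy oligo_feature_isi
#' @export
tidy.oligo_feature_isi <- function(x, ...) {
  if (is.null(x$bins)) tibble::tibble() else x$bins
}

#' @rdname tidy.oligo_feature_isi
#' @method glance oligo_feature_isi
#' @export
glance.oligo_feature_isi <- function(x, ...) {
  tibble::tibble(feature = x$feature_name, model = x$model,
                 aicc_exp = x$aicc_exp, aicc_lin = x$aicc_lin,
                 spearman_r = x$spearman_r, t_stat = x$t_stat,
                 p_value = x$p_value, failed = x$failed, n_b = x$n_b)
}

#' Tidy a unit activity
#' @param x An `oligo_unit`.
#' @param ... Unused.
#' @return The per-spike tibble with provenance.
#' @method tidy oligo_unit
#' @export
tidy.oligo_unit <- function(x, ...) x$spikes

#' @rdname tidy.oligo_unit
#' @method glance oligo_unit
#' @export
glance.oligo_unit <- function(x, ...) {
  tibble::tibble(cluster_id = x$cluster_id, n_spikes = nrow(x$spikes),
                 n_t2 = x$n_t2, n_sa = x$n_sa,
                 fraction_retrieved = x$fraction_retrieved,
                 fraction_retained = x$fraction_retained)
}

#' Glance at a validation report
#' @param x An `oligo_validation`.
#' @param ... Unused.
#' @return One row: verdict, refractory class/fraction, best mode count,
#'   decline flag, feature support.
#' @method glance oligo_validation
#' @export
glance.oligo_validation <- function(x, ...) {
  tibble::tibble(
    verdict = x$verdict,
    refractory_class = x$refractory$class,
    refractory_fraction = x$refractory$fraction,
    best_k = if (is.null(x$best_k)) NA_integer_ else x$best_k,
    leftward_decline = x$leftward_decline,
    feature_support = isTRUE(x$feature_support)
  )
}

#' Tidy an accuracy report
#' @param x An `oligo_accuracy`.
#' @param ... Unused.
#' @return The per-group accuracy tibble.
#' @method tidy oligo_accuracy
#' @export
tidy.oligo_accuracy <- function(x, ...) x$by_group
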