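#' Plot superimposed spike waveforms
#'
#' @param object An `oligo_waveforms`.
#' @param labels Optional cluster labels (one per snippet) to color by.
#' @param max_traces Subsample cap for readability (default 200).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot oligo_waveforms
#' @export
autoplot.oligo_waveforms <- function(object, labels = NULL, max_traces = 200,
                                     ...) {
  n <- nrow(object$waveforms)
  pick <- if (n > max_traces) {
    sort(sample.int(n, max_traces))
  } else seq_len(n)
  tm <- (seq_len(ncol(object$waveforms)) - object$align_index) /
    object$rate * 1000
  df <- purrr::map_dfr(pick, function(i) {
    tibble::tibble(trace = i, time_ms = tm, uV = object$waveforms[i, ],
                   cluster = if (is.null(labels)) NA else labels[i])
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$uV,
                                        group = .data$trace)) +
    ggplot2::labs(x = "time from peak (ms)", y = expression(mu * V))
  if (is.null(labels)) {
    p + ggplot2::geom_line(alpha = 0.25)
  } else {
    p + ggplot2::geom_line(ggplot2::aes(color = factor(.data$cluster)),
                           alpha = 0.4) +
      ggplot2::labs(color = "cluster")
  }
}

#' Silhouette plot for a clustering
#'
#' @param object An `oligo_silhouette`.
#' @param ... Unused.
#' @return A ggplot: per-spike silhouettes sorted within clusters, with the
#'   overall mean as a dashed line.
#' @method autoplot oligo_silhouette
#' @export
autoplot.oligo_silhouette <- function(object, ...) {
  df <- dplyr::mutate(
    dplyr::arrange(object$values, .data$cluster, dplyr::desc(.data$silhouette)),
    rank = dplyr::row_number()
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$silhouette,
                                   fill = factor(.data$cluster))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = object$overall_mean, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "silhouette value", fill = "cluster")
}

#' Log-ISI histogram with optional Gaussian-curve overlay
#'
#' @param object An `oligo_isi_hist`.
#' @param fit Optional `oligo_gauss_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot; the dashed vertical line marks the 3-ms refractory
#'   bound at `ln(0.003)`.
#' @method autoplot oligo_isi_hist
#' @export
autoplot.oligo_isi_hist <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object$bins, ggplot2::aes(.data$mid, .data$pd)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = log(0.003), linetype = "dashed") +
    ggplot2::labs(x = "ln ISI (ln s)", y = "probability density")
  if (!is.null(fit) && fit$converged) {
    grid <- seq(object$edges[1], object$edges[length(object$edges)],
                length.out = 400)
    curve <- tibble::tibble(
      mid = grid,
      pd = gaussian_mixture_curve(grid, fit$params$a, fit$params$b,
                                  fit$params$c))
    p <- p + ggplot2::geom_line(data = curve, color = "steelblue")
  }
  p
}

#' Feature-vs-preceding-ISI plot with the selected model curve
#'
#' @param object An `oligo_feature_isi`.
#' @param ... Unused.
#' @return A ggplot of binned feature means against ln preceding ISI.
#' @method autoplot oligo_feature_isi
#' @export
autoplot.oligo_feature_isi <- function(object, ...) {
  if (is.null(object$bins)) stop("no fitted bins to plot", call. = FALSE)
  ggplot2::ggplot(object$bins, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred), color = "steelblue") +
    ggplot2::labs(x = "ln preceding ISI (ln s)", y = object$feature_name,
                  subtitle = sprintf("%s model, r = %.3f", object$model,
                                     object$spearman_r))
}

#' Per-group sorting accuracy against template amplitude
#'
#' @param object An `oligo_accuracy`.
#' @param specs Optional [template_specs()] to place groups at their peak
#'   SNR on the x axis; otherwise groups are ordered by id.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot oligo_accuracy
#' @export
autoplot.oligo_accuracy <- function(object, specs = NULL, ...) {
  df <- object$by_group
  if (!is.null(specs)) {
    df <- dplyr::left_join(df, specs[, c("group_id", "peak_snr")],
                           by = "group_id")
    ggplot2::ggplot(df, ggplot2::aes(.data$peak_snr, .data$accuracy)) +
      ggplot2::geom_point() + ggplot2::geom_line() +
      ggplot2::labs(x = "template peak SNR", y = "sorting accuracy") +
      ggplot2::ylim(0, 1)
  } else {
    ggplot2::ggplot(df, ggplot2::aes(factor(.data$group_id), .data$accuracy)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "group", y = "sorting accuracy") +
      ggplot2::ylim(0, 1)
  }
}
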