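#' Extract the six waveform features
#'
#' Feature extraction is restricted to the 5-ms segment spanning 2 ms before
#' to 3 ms after the spike peak (the later afterpotential is more prone to
#' contamination by other fibers and ambient interference). The six features
#' per spike are:
#'
#' * `peak_amplitude` (uV) — the sample value at the aligned peak.
#' * `peak_roundness` (uV/ms^2) — the central second difference at the peak,
#'   scaled by the squared sample interval in ms.
#' * `prespike_rms` (uV) — RMS of the 1-ms segment starting 2 ms before the
#'   peak.
#' * `repolarization_rate` (uV/ms) — the steepest fall (`max -dV/dt`) between
#'   the peak and the post-peak minimum.
#' * `afterhyperpolarization` (uV) — the post-peak minimum within the segment.
#' * `ref_correlation` — Pearson correlation with the reference waveform over
#'   the same segment; 0 (with `corr_defined = FALSE`) for flat segments.
#'
#' @param ws An [extract_waveforms()] result.
#' @param ref An [build_reference()] result with identical alignment.
#' @return An `oligo_features` object whose `$features` tibble has one row per
#'   spike (`spike`, `timestamp`, the six features, `corr_defined`). Z-scored
#'   views are added by [zscore_features()].
#' @export
extract_features <- function(ws, ref) {
  stopifnot(inherits(ws, "oligo_waveforms"), inherits(ref, "oligo_reference"))
  if (ref$align_index != ws$align_index) {
    stop("reference and waveforms are aligned differently", call. = FALSE)
  }
  a <- ws$align_index
  rate <- ws$rate
  dt_ms <- 1000 / rate
  s_pre <- ms_to_samples(2, rate)
  s_post <- ms_to_samples(3, rate)
  seg_idx <- (a - s_pre):(a + s_post - 1L)
  pre_idx <- (a - s_pre):(a - s_pre + ms_to_samples(1, rate) - 1L)
  post_idx <- (a + 1L):(a + s_post - 1L)
  ref_seg <- ref$mean_waveform[seg_idx]

  wf <- ws$waveforms
  n <- nrow(wf)
  feat <- purrr::map_dfr(seq_len(n), function(i) {
    w <- wf[i, ]
    ahp_rel <- which.min(w[post_idx])
    ahp_idx <- post_idx[ahp_rel]
    repol <- if (ahp_idx > a) {
      max(-diff(w[a:ahp_idx]) / dt_ms)
    } else 0
    seg <- w[seg_idx]
    flat <- sd(seg) == 0 || sd(ref_seg) == 0
    tibble::tibble(
      peak_amplitude = w[a],
      peak_roundness = (w[a - 1L] - 2 * w[a] + w[a + 1L]) / dt_ms^2,
      prespike_rms = sqrt(mean(w[pre_idx]^2)),
      repolarization_rate = repol,
      afterhyperpolarization = w[ahp_idx],
      ref_correlation = if (flat) 0 else cor(seg, ref_seg),
      corr_defined = !flat
    )
  })
  features <- dplyr::bind_cols(
    tibble::tibble(spike = seq_len(n), timestamp = ws$timestamps), feat
  )
  structure(
    list(features = features, active = feature_names(), z = NULL),
    class = "oligo_features"
  )
}

feature_names <- function() {
  c("peak_amplitude", "peak_roundness", "prespike_rms",
    "repolarization_rate", "afterhyperpolarization", "ref_correlation")
}

#' @export
print.oligo_features <- function(x, ...) {
  cat(sprintf("<oligo_features> %d spikes; active: %s%s\n",
              nrow(x$features), paste(x$active, collapse = ", "),
              if (is.null(x$z)) " (not yet z-scored)" else " (z-scored)"))
  invisible(x)
}

# Column z-scoring with the sample SD (n-1). Zero-SD columns are dropped with
# a warning; returns the matrix plus the surviving column names.
zscore_matrix <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  keep <- s > 0
  if (any(!keep)) {
    warning("zero-variance column(s) excluded from z-scoring: ",
            paste(colnames(m)[!keep], collapse = ", "), call. = FALSE)
  }
  z <- sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]), 2, s[keep], "/")
  z
}

#' Z-score waveform features
#'
#' Standardizes each active feature to mean 0 and sample SD 1 (n-1
#' denominator) over all spikes in the analysed epoch. Constant features are
#' excluded with a warning. The correlation feature is sometimes uninformative
#' when all fibers share similar biphasic shapes and may be dropped via
#' `active`.
#'
#' @param ft An [extract_features()] result.
#' @param active Character vector of feature names to standardize (default:
#'   all six).
#' @return `ft` with `$z` set to the n x p z-score matrix and `$active`
#'   updated to the surviving features.
#' @export
zscore_features <- function(ft, active = feature_names()) {
  stopifnot(inherits(ft, "oligo_features"))
  active <- match.arg(active, feature_names(), several.ok = TRUE)
  if (nrow(ft$features) < 2) stop("need >= 2 spikes to z-score", call. = FALSE)
  m <- as.matrix(ft$features[, active, drop = FALSE])
  z <- zscore_matrix(m)
  ft$z <- z
  ft$active <- colnames(z)
  ft
}

#' Full-waveform representation in 32 samples
#'
#' Alternative to feature extraction: the 32 consecutive amplitude values
#' spanning 1.2 ms before to 2 ms after the peak (half-open window including
#' the peak) are taken directly as coordinates, giving each spike a point in
#' R^32. Columns are z-scored for clustering by [zscore_matrix()] internally
#' when `zscore = TRUE`.
#'
#' @param ws An [extract_waveforms()] result at 10 kHz (other rates use the
#'   equivalent ms window).
#' @param zscore If `TRUE` (default) z-score each column.
#' @return An n x 32 matrix (raw uV, or column z-scores).
#' @export
full_waveform_vectors <- function(ws, zscore = TRUE) {
  stopifnot(inherits(ws, "oligo_waveforms"))
  a <- ws$align_index
  w_pre <- ms_to_samples(1.2, ws$rate)
  w_post <- ms_to_samples(2, ws$rate)
  idx <- (a - w_pre):(a + w_post - 1L)
  v <- ws$waveforms[, idx, drop = FALSE]
  colnames(v) <- paste0("s", seq_len(ncol(v)))
  if (zscore) zscore_matrix(v) else v
}
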