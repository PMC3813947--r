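#' Residual of an outlier waveform against the cluster reference
#'
#' First step of the data-based subtraction algorithm (SA): a T2-unselected
#' waveform is assumed to be the cluster's ideal waveform distorted by an
#' added signal, so the reference is subtracted pointwise from the 25-ms
#' outlier snippet. The residual maximum is searched within 2-15 ms of the
#' window (interference landing in that range can distort the 5-ms feature
#' segment) and a 5-ms residual excerpt spanning 2 ms before to 3 ms after
#' that maximum is extracted for matching back against the recording.
#'
#' @param outlier Numeric 25-ms waveform (uV), aligned like `reference`.
#' @param reference An [build_reference()] result of identical length and
#'   alignment.
#' @return An `oligo_residual`: `full_residual`, `max_index` (1-based sample
#'   within the window), `max_time_ms`, `segment` (50 samples at 10 kHz),
#'   `residual_peak` (uV), `rate`, `align_index`.
#' @export
compute_residual <- function(outlier, reference) {
  stopifnot(inherits(reference, "oligo_reference"))
  ref <- reference$mean_waveform
  if (length(outlier) != length(ref)) {
    stop("outlier and reference lengths differ (misaligned inputs)",
         call. = FALSE)
  }
  rate <- reference$rate
  res <- as.numeric(outlier) - ref
  lo <- ms_to_samples(2, rate) + 1L   # first sample at/after 2 ms
  hi <- ms_to_samples(15, rate)       # last sample before 15 ms
  search <- res[lo:hi]
  m <- lo + which.max(search) - 1L
  s_pre <- ms_to_samples(2, rate)
  s_post <- ms_to_samples(3, rate)
  seg_lo <- max(1L, m - s_pre)
  seg <- res[seg_lo:(m + s_post - 1L)]
  structure(
    list(full_residual = res, max_index = m,
         max_time_ms = (m - 1L) / rate * 1000,
         segment = seg, segment_peak_offset = m - seg_lo,
         residual_peak = res[m], rate = rate,
         align_index = reference$align_index),
    class = "oligo_residual"
  )
}

# Sliding normalized cross-correlation of a short template against a long
# trace, via one FFT-based correlation plus cumulative window sums.
sliding_ncc <- function(y, seg) {
  n <- length(y)
  L <- length(seg)
  n_win <- n - L + 1L
  n2 <- nextn(n + L - 1L)
  fy <- fft(c(y, rep(0, n2 - n)))
  fs <- fft(c(rev(seg), rep(0, n2 - L)))
  z <- Re(fft(fy * fs, inverse = TRUE)) / n2
  sxy <- z[L:(L + n_win - 1L)]
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  sy <- cs[(L + 1L):(n + 1L)] - cs[1:n_win]
  sy2 <- cs2[(L + 1L):(n + 1L)] - cs2[1:n_win]
  var_y <- pmax((sy2 - sy^2 / L) / (L - 1), 0)
  mx <- mean(seg)
  sdx <- sd(seg)
  num <- (sxy - sy * mx) / (L - 1)
  den <- sdx * sqrt(var_y)
  r <- ifelse(den > 0, num / den, 0)
  pmin(pmax(r, -1), 1)
}

#' Scan the original recording for a residual waveform
#'
#' Second step of SA: the 5-ms residual segment is slid across an epoch of the
#' original recording (default the first 10 min) using FFT-based normalized
#' cross-correlation. A candidate window is a match when its correlation with
#' the residual exceeds `r_min` **and** its peak magnitude differs from the
#' residual peak by less than `mag_tol` (relative). Windows overlapping the
#' outlier's own position (within 25 ms) are excluded, so an outlier can never
#' match itself. One local correlation maximum is reported per
#' supra-threshold run.
#'
#' @param residual An [compute_residual()] result with `residual_peak > 0`.
#' @param rec The original [recording()].
#' @param exclude_index Sample index of the outlier's own peak in `rec`
#'   (optional; `NULL` disables self-exclusion).
#' @param epoch Scan epoch in seconds (default 600; capped at the recording
#'   duration).
#' @param r_min Correlation threshold (default 0.95).
#' @param mag_tol Relative magnitude tolerance (default 0.30).
#' @return An `oligo_sa_match`: `$matches` tibble (`match_time`, `correlation`,
#'   `magnitude_ratio`), `n_matches`, `scan_epoch`.
#' @export
scan_recording <- function(residual, rec, exclude_index = NULL, epoch = 600,
                           r_min = 0.95, mag_tol = 0.30) {
  stopifnot(inherits(residual, "oligo_residual"),
            inherits(rec, "oligo_recording"))
  empty <- structure(
    list(matches = tibble::tibble(match_time = numeric(),
                                  correlation = numeric(),
                                  magnitude_ratio = numeric()),
         n_matches = 0L, scan_epoch = epoch, r_min = r_min,
         mag_tol = mag_tol),
    class = "oligo_sa_match"
  )
  seg <- residual$segment
  if (sd(seg) == 0 || residual$residual_peak <= 0) return(empty)
  n_scan <- min(length(rec$samples), round(epoch * rec$rate))
  y <- rec$samples[seq_len(n_scan)]
  L <- length(seg)
  if (n_scan <= L) return(empty)
  r <- sliding_ncc(y, seg)

  if (!is.null(exclude_index)) {
    guard <- ms_to_samples(25, rec$rate)
    lo <- max(1L, exclude_index - guard - L + 1L)
    hi <- min(length(r), exclude_index + guard)
    if (lo <= hi) r[lo:hi] <- -Inf
  }
  ok <- r > r_min
  if (!any(ok)) return(empty)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- mapply(function(s, e) s + which.max(r[s:e]) - 1L,
                 starts[runs$values], ends[runs$values])
  peak_off <- residual$segment_peak_offset
  cand_peak <- vapply(cand, function(i) max(y[i:(i + L - 1L)]), numeric(1))
  ratio <- cand_peak / residual$residual_peak
  pass <- abs(1 - ratio) < mag_tol
  matches <- tibble::tibble(
    match_time = rec$t0 + (cand[pass] + peak_off - 1L) / rec$rate,
    correlation = r[cand][pass],
    magnitude_ratio = ratio[pass]
  )
  structure(
    list(matches = matches, n_matches = nrow(matches), scan_epoch = epoch,
         r_min = r_min, mag_tol = mag_tol),
    class = "oligo_sa_match"
  )
}

#' @export
print.oligo_sa_match <- function(x, ...) {
  cat(sprintf("<oligo_sa_match> %d match(es) over %.0f s (r > %.2f, |1-ratio| < %.2f)\n",
              x$n_matches, x$scan_epoch, x$r_min, x$mag_tol))
  invisible(x)
}

#' Classify a T2-unselected waveform
#'
#' Decides the fate of one outlier from its residual. Verdicts:
#'
#' * `retrieved-subthreshold` — the residual peak is below `4 * sigma_n`
#'   (80% of the 5-sigma detection threshold): the distortion is explainable
#'   as sub-threshold noise.
#' * `retrieved-matched` — the residual is demonstrably present elsewhere in
#'   the original recording (at least one scan match).
#' * `rejected-outlier` — neither criterion holds.
#' * `flagged-pitfall` — the residual itself correlates > 0.95 with the
#'   cluster's own reference. This happens when an outlier is roughly twice
#'   the reference amplitude: subtraction then leaves a copy of the reference,
#'   which of course occurs throughout the recording, so blind matching would
#'   silently absorb a genuinely different spike. Such cases are flagged for
#'   manual review and never auto-retrieved, whatever the other criteria say.
#'
#' By default the two retrieval criteria are a disjunction (sub-threshold OR
#' matched): retrieved residuals are frequently full-amplitude spikes of
#' another active fiber, which can never be sub-threshold. `criteria = "and"`
#' restores the conjunctive reading (both required).
#'
#' @param residual An [compute_residual()] result.
#' @param matches An [scan_recording()] result.
#' @param noise An [estimate_noise_sigma()] result (`sigma_n > 0`).
#' @param own_reference The cluster's [build_reference()].
#' @param criteria `"or"` (default) or `"and"`.
#' @param sigma_ceiling Sub-threshold ceiling in units of `sigma_n`
#'   (default 4).
#' @return An `oligo_sa_decision`: `verdict`, `retrieved` (logical), and
#'   `criteria_log` (named logicals: `subthreshold`, `matched`, `pitfall`).
#' @export
classify_outlier <- function(residual, matches, noise, own_reference,
                             criteria = c("or", "and"), sigma_ceiling = 4) {
  stopifnot(inherits(residual, "oligo_residual"),
            inherits(noise, "oligo_noise"))
  criteria <- match.arg(criteria)
  if (noise$sigma_n <= 0) stop("sigma_n must be positive", call. = FALSE)

  sub <- residual$residual_peak < sigma_ceiling * noise$sigma_n
  matched <- !is.null(matches) && matches$n_matches >= 1L
  pitfall <- pitfall_correlation(residual, own_reference) > 0.95

  verdict <- if (pitfall) {
    "flagged-pitfall"
  } else if (criteria == "or") {
    if (sub) "retrieved-subthreshold"
    else if (matched) "retrieved-matched"
    else "rejected-outlier"
  } else {
    if (sub && matched) "retrieved-matched" else "rejected-outlier"
  }
  structure(
    list(verdict = verdict,
         retrieved = verdict %in% c("retrieved-subthreshold",
                                    "retrieved-matched"),
         criteria_log = c(subthreshold = sub, matched = matched,
                          pitfall = pitfall)),
    class = "oligo_sa_decision"
  )
}

# Correlation of the residual's 5-ms segment with the reference's own 5-ms
# feature segment (2 ms before to 3 ms after the reference peak).
pitfall_correlation <- function(residual, reference) {
  a <- reference$align_index
  rate <- reference$rate
  s_pre <- ms_to_samples(2, rate)
  s_post <- ms_to_samples(3, rate)
  ref_seg <- reference$mean_waveform[(a - s_pre):(a + s_post - 1L)]
  seg <- residual$segment
  L <- min(length(seg), length(ref_seg))
  seg <- seg[seq_len(L)]; ref_seg <- ref_seg[seq_len(L)]
  if (sd(seg) == 0 || sd(ref_seg) == 0) return(0)
  cor(seg, ref_seg)
}

#' Run the subtraction algorithm over a cluster's outliers
#'
#' Convenience driver: for every T2-unselected waveform, compute the residual
#' against the cluster reference, scan the recording, and classify.
#'
#' @param ws The cluster's [extract_waveforms()] (full recording's waveform
#'   set).
#' @param unselected Row indices (into `ws`) of the T2-unselected waveforms.
#' @param reference The cluster reference (mean of T2-selected members).
#' @param rec Original [recording()].
#' @param noise Noise estimate.
#' @param epoch,r_min,mag_tol,criteria,sigma_ceiling Passed through to
#'   [scan_recording()] / [classify_outlier()].
#' @return A tibble with one row per outlier: `spike`, `verdict`, `retrieved`,
#'   `residual_peak`, `n_matches`, `pitfall`.
#' @export
run_sa <- function(ws, unselected, reference, rec, noise, epoch = 600,
                   r_min = 0.95, mag_tol = 0.30, criteria = "or",
                   sigma_ceiling = 4) {
  purrr::map_dfr(unselected, function(i) {
    res <- compute_residual(ws$waveforms[i, ], reference)
    sub <- res$residual_peak < sigma_ceiling * noise$sigma_n
    needs_scan <- !(criteria == "or" && sub)
    m <- if (needs_scan && res$residual_peak > 0) {
      scan_recording(res, rec, exclude_index = ws$peak_index[i],
                     epoch = epoch, r_min = r_min, mag_tol = mag_tol)
    } else NULL
    dec <- classify_outlier(res, m, noise, reference, criteria = criteria,
                            sigma_ceiling = sigma_ceiling)
    tibble::tibble(
      spike = i, verdict = dec$verdict, retrieved = dec$retrieved,
      residual_peak = res$residual_peak,
      n_matches = if (is.null(m)) NA_integer_ else m$n_matches,
      pitfall = unname(dec$criteria_log["pitfall"])
    )
  })
}

#' Assemble a unit activity from T2-selected and SA-retrieved spikes
#'
#' The homogeneous core of a cluster plus its SA-retrieved outliers are
#' merged, time-sorted, and tagged with per-spike provenance; together they
#' are the putative single-fiber unit.
#'
#' @param selected,retrieved Disjoint row-index sets (into `ws`) from one
#'   cluster.
#' @param ws The [extract_waveforms()] set.
#' @param cluster_id Label for the source cluster.
#' @param cluster_size Total spikes in the cluster (for the retained
#'   fraction); defaults to `length(selected) + length(retrieved)`.
#' @return An `oligo_unit`: `$spikes` tibble (`spike`, `timestamp`,
#'   `provenance` in {T2, SA}), `cluster_id`, `fraction_retrieved` (retrieved
#'   / unselected is up to the caller; stored as retrieved / unit size),
#'   `fraction_retained` (unit size / cluster size).
#' @export
assemble_unit <- function(selected, retrieved, ws, cluster_id = 1L,
                          cluster_size = NULL) {
  stopifnot(inherits(ws, "oligo_waveforms"))
  if (length(intersect(selected, retrieved)) > 0) {
    stop("`selected` and `retrieved` overlap", call. = FALSE)
  }
  ids <- c(selected, retrieved)
  prov <- c(rep("T2", length(selected)), rep("SA", length(retrieved)))
  ord <- order(ws$timestamps[ids])
  spikes <- tibble::tibble(
    spike = as.integer(ids[ord]),
    timestamp = ws$timestamps[ids][ord],
    provenance = prov[ord]
  )
  if (is.null(cluster_size)) cluster_size <- length(ids)
  structure(
    list(spikes = spikes, cluster_id = cluster_id,
         n_t2 = length(selected), n_sa = length(retrieved),
         fraction_retrieved = if (length(ids)) length(retrieved) / length(ids) else 0,
         fraction_retained = if (cluster_size) length(ids) / cluster_size else 0),
    class = "oligo_unit"
  )
}

#' @export
print.oligo_unit <- function(x, ...) {
  cat(sprintf("<oligo_unit> cluster %s: %d spikes (%d T2 + %d SA), %.1f%% of cluster retained\n",
              x$cluster_id, nrow(x$spikes), x$n_t2, x$n_sa,
              100 * x$fraction_retained))
  invisible(x)
}
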