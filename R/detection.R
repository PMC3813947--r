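#' Robust noise estimate and detection threshold
#'
#' Oligofiber spiking occupies only a small fraction of the trace (a fiber
#' firing at 5 Hz with 5-ms spikes has a duty cycle of 0.025), so the median
#' absolute sample is dominated by the instrumental noise. The noise standard
#' deviation is estimated as `sigma_n = median(|x|) / 0.6745` (the absolute
#' median of a zero-mean Gaussian is 0.6745 of its SD), and the spike-detection
#' threshold is fixed at `5 * sigma_n`.
#'
#' @param rec An [recording()] of the band-passed signal.
#' @return An `oligo_noise` object: `sigma_n` (uV), `threshold` (uV, exactly
#'   `5 * sigma_n`), and `method_window` (the duration analysed, s).
#' @export
estimate_noise_sigma <- function(rec) {
  stopifnot(inherits(rec, "oligo_recording"))
  if (length(rec$samples) < 1000) {
    stop("need at least 1000 samples for a stable noise estimate", call. = FALSE)
  }
  sigma_n <- median(abs(rec$samples)) / 0.6745
  structure(
    list(sigma_n = sigma_n, threshold = 5 * sigma_n,
         method_window = duration(rec)),
    class = "oligo_noise"
  )
}

#' @export
print.oligo_noise <- function(x, ...) {
  cat(sprintf("<oligo_noise> sigma_n = %.3f uV, threshold (5 sigma_n) = %.3f uV over %.1f s\n",
              x$sigma_n, x$threshold, x$method_window))
  invisible(x)
}

#' Fraction of recording time occupied by spiking
#'
#' @param rate Firing rate in Hz (>= 0).
#' @param spike_duration Single-spike duration in seconds (>= 0).
#' @return `rate * spike_duration`, capped at 1. For example 5 Hz firing with
#'   5-ms spikes gives 0.025.
#' @export
spiking_duty_cycle <- function(rate, spike_duration) {
  stopifnot(rate >= 0, spike_duration >= 0)
  min(rate * spike_duration, 1)
}

#' Detect spikes by threshold crossing
#'
#' Finds local maxima exceeding the `5 * sigma_n` threshold. Within each
#' contiguous supra-threshold run the peak is the argmax (earliest sample on
#' ties); within any `min_separation` window only the largest peak is kept.
#' The peak sample time is the spike timestamp.
#'
#' @param rec An [recording()].
#' @param noise An [estimate_noise_sigma()] result with `sigma_n > 0`.
#' @param min_separation Dead time between accepted peaks in seconds
#'   (default 1 ms, well under the 3-ms refractory bound).
#' @param polarity `"positive"` detects positive peaks (the usual biphasic
#'   overshoot morphology); `"absolute"` detects on `|x|`.
#' @return A tibble of spike events: `timestamp` (s), `peak_index` (1-based
#'   sample), `amplitude` (uV at the peak of the detected polarity), and `snr`
#'   (`amplitude / sigma_n`).
#' @export
detect_spikes <- function(rec, noise, min_separation = 0.001,
                          polarity = c("positive", "absolute")) {
  stopifnot(inherits(rec, "oligo_recording"), inherits(noise, "oligo_noise"))
  polarity <- match.arg(polarity)
  if (noise$sigma_n <= 0) {
    stop("zero noise threshold: refusing to detect on sigma_n <= 0",
         call. = FALSE)
  }
  x <- if (polarity == "absolute") abs(rec$samples) else rec$samples
  above <- x > noise$threshold
  empty <- tibble::tibble(timestamp = numeric(), peak_index = integer(),
                          amplitude = numeric(), snr = numeric())
  if (!any(above)) return(empty)

  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  peaks <- mapply(function(s, e) s + which.max(x[s:e]) - 1L,
                  starts[keep], ends[keep])
  amps <- x[peaks]

  # Greedy by amplitude: within any min_separation window keep the largest.
  min_gap <- min_separation * rec$rate
  ord <- order(amps, peaks, decreasing = c(TRUE, FALSE), method = "radix")
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(peaks[kept] - peaks[i]) >= min_gap)) {
      kept <- c(kept, i)
    }
  }
  kept <- kept[order(peaks[kept])]
  tibble::tibble(
    timestamp = rec$t0 + (peaks[kept] - 1L) / rec$rate,
    peak_index = as.integer(peaks[kept]),
    amplitude = amps[kept],
    snr = amps[kept] / noise$sigma_n
  )
}

#' Extract peak-aligned waveform snippets
#'
#' Each detected spike is cut as a 25-ms snippet spanning 12 ms before to
#' 13 ms after the peak (a half-open window; 250 samples at 10 kHz with the
#' peak at the 121st sample). Events too close to the recording edges are
#' dropped with a warning.
#'
#' @param rec An [recording()].
#' @param events Spike-event tibble from [detect_spikes()] (needs
#'   `peak_index` and `timestamp`).
#' @return An `oligo_waveforms` object: `waveforms` (n x 250 matrix, uV),
#'   `align_index` (1-based peak column), `rate`, `timestamps`, `peak_index`,
#'   and `kept` (row indices of `events` that survived the edge check).
#' @export
extract_waveforms <- function(rec, events) {
  stopifnot(inherits(rec, "oligo_recording"))
  n_pre <- ms_to_samples(12, rec$rate)
  n_post <- ms_to_samples(13, rec$rate)
  len <- n_pre + n_post
  p <- events$peak_index
  ok <- (p - n_pre) >= 1L & (p + n_post - 1L) <= length(rec$samples)
  if (any(!ok)) {
    warning(sum(!ok), " event(s) within 12/13 ms of the recording edges dropped",
            call. = FALSE)
  }
  p <- p[ok]
  wf <- matrix(0, nrow = length(p), ncol = len)
  for (i in seq_along(p)) {
    wf[i, ] <- rec$samples[(p[i] - n_pre):(p[i] + n_post - 1L)]
  }
  structure(
    list(waveforms = wf, align_index = n_pre + 1L, rate = rec$rate,
         timestamps = events$timestamp[ok], peak_index = p,
         kept = which(ok)),
    class = "oligo_waveforms"
  )
}

#' @export
print.oligo_waveforms <- function(x, ...) {
  cat(sprintf("<oligo_waveforms> %d snippets x %d samples @ %g Hz (peak at column %d)\n",
              nrow(x$waveforms), ncol(x$waveforms), x$rate, x$align_index))
  invisible(x)
}

#' Build a reference waveform by averaging
#'
#' The reference spike waveform is the pointwise mean of a set of similarly
#' shaped snippets (classically ~20 hand-picked spikes; downstream, the mean of
#' a cluster's homogeneity-selected members).
#'
#' @param ws An [extract_waveforms()] result.
#' @param pick Row indices of the snippets to average (>= 1 row).
#' @param source_cluster Provenance label (default `"manual"`).
#' @return An `oligo_reference`: `mean_waveform`, `n_averaged`,
#'   `source_cluster`, `align_index`, `rate`.
#' @export
build_reference <- function(ws, pick, source_cluster = "manual") {
  stopifnot(inherits(ws, "oligo_waveforms"))
  pick <- as.integer(pick)
  if (length(pick) < 1) stop("empty selection for reference", call. = FALSE)
  m <- ws$waveforms[pick, , drop = FALSE]
  structure(
    list(mean_waveform = colMeans(m), n_averaged = nrow(m),
         source_cluster = source_cluster, align_index = ws$align_index,
         rate = ws$rate),
    class = "oligo_reference"
  )
}
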