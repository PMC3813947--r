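# Shared fixture builders. Everything is generated in code at test time.

# A waveform set built directly from a matrix (bypassing detection).
ws_from_matrix <- function(m, rate = 10000, align = 121L,
                           timestamps = NULL) {
  if (is.null(timestamps)) timestamps <- seq_len(nrow(m)) * 0.1
  structure(
    list(waveforms = m, align_index = align, rate = rate,
         timestamps = timestamps,
         peak_index = as.integer(round(timestamps * rate)) + 1L,
         kept = seq_len(nrow(m))),
    class = "oligo_waveforms"
  )
}

ref_from_wave <- function(w, rate = 10000, align = 121L, n = 20L) {
  structure(
    list(mean_waveform = as.numeric(w), n_averaged = n,
         source_cluster = "manual", align_index = align, rate = rate),
    class = "oligo_reference"
  )
}

noise_obj <- function(sigma) {
  structure(list(sigma_n = sigma, threshold = 5 * sigma, method_window = NA),
            class = "oligo_noise")
}

# A fake log-ISI histogram holding exact (mid, pd) pairs, for curve-fit
# oracles with known generating parameters.
hist_from_curve <- function(mid, pd, h) {
  structure(
    list(bins = tibble::tibble(mid = mid, pd = pd, count = NA_integer_),
         h = h, edges = c(mid - h / 2, mid[length(mid)] + h / 2),
         n = NA_integer_, ln_isis = numeric(), isis = numeric()),
    class = "oligo_isi_hist"
  )
}

# Default single template (unit peak) for constructions.
unit_template <- function(row = 4, rate = 10000) {
  oligosort::make_template(oligosort::template_specs()[row, ], rate)
}

# Exhaustive sliding-correlation oracle (direct cor() per window).
ncc_oracle <- function(y, seg) {
  L <- length(seg)
  vapply(seq_len(length(y) - L + 1L), function(i) {
    w <- y[i:(i + L - 1L)]
    if (sd(w) == 0) 0 else cor(seg, w)
  }, numeric(1))
}

# Brute-force k=2 partition oracle: best assignment by total within-cluster
# distance under the centroid rule for the metric (n <= 12).
best_partition_2 <- function(z, metric) {
  n <- nrow(z)
  best <- NULL
  cdist <- function(m) {
    cen <- if (metric == "cityblock") apply(m, 2, median) else colMeans(m)
    d <- sweep(m, 2, cen)
    if (metric == "cityblock") sum(abs(d)) else sum(d^2)
  }
  for (mask in 1:(2^(n - 1) - 1)) {
    lab <- as.integer(intToBits(mask))[1:n]
    if (sum(lab) == 0 || sum(lab) == n) next
    tot <- cdist(z[lab == 1, , drop = FALSE]) +
      cdist(z[lab == 0, , drop = FALSE])
    if (is.null(best) || tot < best$tot) best <- list(tot = tot, lab = lab)
  }
  best
}

same_partition <- function(a, b) {
  # identical up to label renaming
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}
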