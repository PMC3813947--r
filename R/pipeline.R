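#' Pipeline configuration
#'
#' All tunables in one list, serializable to YAML for provenance. Defaults
#' follow the methodology's stated values: 5-sigma detection, 25-ms snippets
#' (12 before / 13 after the peak), 5-ms feature segment (2/3 ms), 32-sample
#' full-waveform window (1.2/2 ms), cityblock k-means on features with 10
#' restarts, 99.99% T-squared scope, SA with r > 0.95, magnitude within 30%,
#' 4-sigma sub-threshold ceiling and a 600-s scan epoch, 3-ms refractory with
#' the 0.1% clean bound, up to 3 ISI Gaussian modes.
#'
#' @param ... Named overrides of any default.
#' @return An `oligo_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    threshold_sigma = 5,
    min_separation = 0.001,
    polarity = "positive",
    active_features = feature_names(),
    representation = "features",     # or "full-waveform"
    metric = "cityblock",
    n_restarts = 10,
    kmeans_seed = 1,
    t2_scope = 0.9999,
    sa_enabled = TRUE,
    sa_r_min = 0.95,
    sa_mag_tol = 0.30,
    sa_sigma_ceiling = 4,
    sa_epoch = 600,
    sa_criteria = "or",
    refractory = 0.003,
    clean_fraction = 0.001,
    max_modes = 3,
    reference_n = 20
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "oligo_config")
}

#' @export
print.oligo_config <- function(x, ...) {
  cat("<oligo_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @param cfg An [pipeline_config()].
#' @return `read_config()` returns an `oligo_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# Provisional reference for the correlation feature: the `reference_n`
# snippets most correlated with the grand-mean waveform, averaged.
provisional_reference <- function(ws, n_ref = 20) {
  grand <- colMeans(ws$waveforms)
  n <- nrow(ws$waveforms)
  if (n <= 2) return(build_reference(ws, seq_len(n)))
  cors <- apply(ws$waveforms, 1, function(w) {
    if (sd(w) == 0) -1 else cor(w, grand)
  })
  pick <- order(cors, decreasing = TRUE)[seq_len(min(n_ref, n))]
  build_reference(ws, pick, source_cluster = "provisional")
}

#' Run the complete sorting pipeline
#'
#' detect -> extract snippets -> provisional reference -> six features (or
#' full-waveform vectors) -> z-scores -> k-means -> per-cluster PCA/T-squared
#' homogeneity selection -> subtraction-algorithm retrieval of the outliers ->
#' unit assembly. `k` is supplied by the user (judge it from the feature
#' plots or a silhouette sweep); everything else comes from `config`.
#'
#' @param rec An [recording()].
#' @param k Number of k-means clusters.
#' @param config An [pipeline_config()].
#' @param mask Optional indices (into the detected-event order) of spikes to
#'   exclude before clustering — manual pre-removal of obvious clusters on
#'   very large recordings; never automated.
#' @return An `oligo_sort` list: `noise`, `events`, `waveforms`, `features`,
#'   `kmeans`, `silhouette`, `clusters` (per-cluster t2 fit, selection, SA
#'   table, reference), `units` (list of [assemble_unit()]), `config`.
#' @export
run_pipeline <- function(rec, k, config = pipeline_config(), mask = NULL) {
  stopifnot(inherits(rec, "oligo_recording"))
  noise <- estimate_noise_sigma(rec)
  events <- detect_spikes(rec, noise, min_separation = config$min_separation,
                          polarity = config$polarity)
  if (!is.null(mask)) events <- events[-mask, , drop = FALSE]
  if (nrow(events) < k + 1) {
    stop("too few detected spikes (", nrow(events), ") for k = ", k,
         call. = FALSE)
  }
  ws <- extract_waveforms(rec, events)
  ref0 <- provisional_reference(ws, config$reference_n)
  ft <- extract_features(ws, ref0)
  z <- if (config$representation == "full-waveform") {
    full_waveform_vectors(ws)
  } else {
    ft <- zscore_features(ft, config$active_features)
    ft$z
  }
  km <- kmeans_spikes(z, k, metric = config$metric, seed = config$kmeans_seed,
                      n_restarts = config$n_restarts)
  sil <- if (k >= 2) spike_silhouette(z, km$labels, config$metric) else NULL

  clusters <- lapply(seq_len(k), function(j) {
    members <- which(km$labels == j)
    if (length(members) <= ncol(z) + 1) {
      return(list(members = members, t2 = NULL, selection = NULL,
                  reference = NULL, sa = NULL,
                  note = "too small for homogeneity analysis"))
    }
    t2 <- fit_t2(z[members, , drop = FALSE], scope = config$t2_scope)
    selctn <- select_by_t2(t2)
    sel_ids <- members[selctn$selected]
    unsel_ids <- members[selctn$unselected]
    ref <- build_reference(ws, sel_ids, source_cluster = j)
    sa <- NULL
    if (config$sa_enabled && length(unsel_ids) > 0) {
      sa <- run_sa(ws, unsel_ids, ref, rec, noise,
                   epoch = config$sa_epoch, r_min = config$sa_r_min,
                   mag_tol = config$sa_mag_tol,
                   criteria = config$sa_criteria,
                   sigma_ceiling = config$sa_sigma_ceiling)
    }
    list(members = members, t2 = t2, selection = selctn,
         selected = sel_ids, unselected = unsel_ids, reference = ref,
         sa = sa)
  })

  units <- lapply(seq_len(k), function(j) {
    cl <- clusters[[j]]
    if (is.null(cl$selection)) {
      return(assemble_unit(cl$members, integer(0), ws, cluster_id = j,
                           cluster_size = length(cl$members)))
    }
    retrieved <- if (!is.null(cl$sa)) cl$sa$spike[cl$sa$retrieved] else integer(0)
    assemble_unit(cl$selected, retrieved, ws, cluster_id = j,
                  cluster_size = length(cl$members))
  })

  structure(
    list(noise = noise, events = events, waveforms = ws, features = ft,
         kmeans = km, silhouette = sil, clusters = clusters, units = units,
         config = config),
    class = "oligo_sort"
  )
}

#' @export
print.oligo_sort <- function(x, ...) {
  cat(sprintf("<oligo_sort> %d spikes -> %d clusters (%s/%s)\n",
              nrow(x$events), x$kmeans$k, x$config$representation,
              x$config$metric))
  for (u in x$units) {
    cat(sprintf("  cluster %s: %d spikes (%d T2 + %d SA)\n",
                u$cluster_id, nrow(u$spikes), u$n_t2, u$n_sa))
  }
  invisible(x)
}
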