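#' Spike half-duration of a mean waveform
#'
#' Width at half maximum of the dominant deflection: the global extremum's
#' lobe is followed left and right to the points where it falls to half its
#' peak absolute amplitude, with linear interpolation between samples.
#'
#' @param mean_waveform Numeric voltage trace.
#' @param sample_rate Hz.
#' @return Half-duration in ms.
#' @export
compute_half_duration <- function(mean_waveform, sample_rate) {
  w <- as.numeric(mean_waveform)
  if (length(w) < 3L || all(!is.finite(w)) || max(abs(w), na.rm = TRUE) == 0)
    stop("waveform is flat or all-zero; half-duration undefined", call. = FALSE)
  m <- which.max(abs(w))
  y <- w * sign(w[m])          # dominant lobe made positive
  half <- y[m] / 2
  i <- m
  while (i > 1L && y[i - 1L] >= half) i <- i - 1L
  left <- if (i == 1L) 1 else
    (i - 1L) + (half - y[i - 1L]) / (y[i] - y[i - 1L])
  j <- m
  while (j < length(y) && y[j + 1L] >= half) j <- j + 1L
  right <- if (j == length(y)) length(y) else
    j + (y[j] - half) / (y[j] - y[j + 1L])
  (right - left) * 1000 / sample_rate
}

#' Amplitude ratio of a mean waveform
#'
#' `(n - p) / (n + p)`, where p and n are the peak absolute amplitudes of the
#' first positive and first negative waveform segments in temporal order.
#' Samples below a relative tolerance of the trace maximum are treated as
#' baseline and do not open a segment.
#'
#' @param mean_waveform Numeric voltage trace.
#' @param tol Relative amplitude below which samples count as baseline.
#' @return Dimensionless ratio in \[-1, 1\].
#' @export
compute_amplitude_ratio <- function(mean_waveform, tol = 1e-6) {
  w <- as.numeric(mean_waveform)
  amax <- max(abs(w))
  if (!is.finite(amax) || amax == 0)
    stop("waveform is flat or all-zero; amplitude ratio undefined", call. = FALSE)
  s <- sign(w)
  s[abs(w) < tol * amax] <- 0
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  first_pos <- which(r$values == 1)[1]
  first_neg <- which(r$values == -1)[1]
  if (is.na(first_pos) || is.na(first_neg))
    stop("waveform lacks a positive or negative segment; ratio undefined",
         call. = FALSE)
  p <- max(w[starts[first_pos]:ends[first_pos]])
  n <- max(-w[starts[first_neg]:ends[first_neg]])
  if (p + n == 0) stop("degenerate segments; ratio undefined", call. = FALSE)
  (n - p) / (n + p)
}

#' Extract waveform features for every unit
#'
#' Units whose features are undefined (flat traces, single-signed traces) are
#' returned with `valid = FALSE` and excluded from clustering downstream,
#' never silently dropped.
#'
#' @param session A `vta_session`, or a waveforms table (`unit_id`,
#'   `sample_index`, `voltage`).
#' @param sample_rate Hz (taken from session metadata when available).
#' @return `data.frame`: `unit_id`, `half_duration` (ms), `amplitude_ratio`,
#'   `valid`.
#' @export
waveform_features <- function(session, sample_rate = NULL) {
  if (inherits(session, "vta_session")) {
    wf <- session$waveforms
    if (is.null(sample_rate)) sample_rate <- session$meta$sample_rate
  } else wf <- session
  stopifnot(!is.null(sample_rate))
  ids <- unique(wf$unit_id)
  res <- data.frame(unit_id = ids, half_duration = NA_real_,
                    amplitude_ratio = NA_real_, valid = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    w <- wf$voltage[wf$unit_id == ids[k]][order(wf$sample_index[wf$unit_id == ids[k]])]
    ft <- tryCatch(list(hd = compute_half_duration(w, sample_rate),
                        ar = compute_amplitude_ratio(w)),
                   error = function(e) NULL)
    if (!is.null(ft)) {
      res$half_duration[k] <- ft$hd
      res$amplitude_ratio[k] <- ft$ar
      res$valid[k] <- TRUE
    }
  }
  res
}

#' Classifier configuration
#' @param n_clusters Number of waveform clusters (>= 2).
#' @param sd_threshold Assignment threshold in s.d. units.
#' @param standardize Standardize features before the initial clustering.
#' @param metric `"axiswise"`: a unit is inside a cluster when within
#'   `sd_threshold` on both feature axes; `"mahalanobis"`: diagonal-covariance
#'   distance `sqrt(sum(z^2)) <= sd_threshold`.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(n_clusters = 2L, sd_threshold = 3.0,
                              standardize = TRUE,
                              metric = c("axiswise", "mahalanobis")) {
  metric <- match.arg(metric)
  stopifnot(n_clusters >= 2L, sd_threshold > 0)
  structure(list(n_clusters = as.integer(n_clusters),
                 sd_threshold = sd_threshold, standardize = standardize,
                 metric = metric),
            class = "classifier_config")
}

#' Initial clustering of waveform features
#'
#' K-means partitioning (10 restarts) of the (optionally standardized)
#' half-duration / amplitude-ratio plane. The cluster with the larger mean
#' half-duration is designated dopamine-like, following the waveform
#' convention that dopamine spikes are wide.
#'
#' @param features Output of [waveform_features()] (invalid rows excluded
#'   automatically).
#' @param config A [classifier_config()].
#' @param seed Seed for the k-means restarts.
#' @return List: `assignment` (named integer vector), `dopamine_cluster`
#'   (cluster index), `centers` (feature-space centers).
#' @export
initial_clustering <- function(features, config = classifier_config(),
                               seed = 1L) {
  feats <- features[features$valid, , drop = FALSE]
  if (nrow(feats) < 2L * config$n_clusters)
    stop("too few units with valid features for clustering", call. = FALSE)
  x <- cbind(half_duration = feats$half_duration,
             amplitude_ratio = feats$amplitude_ratio)
  if (any(apply(x, 2, stats::sd) == 0) && nrow(unique(x)) < config$n_clusters)
    stop("degenerate feature geometry: fewer distinct points than clusters",
         call. = FALSE)
  xs <- if (config$standardize) scale(x) else x
  set.seed(as.integer(seed))
  km <- stats::kmeans(xs, centers = config$n_clusters, nstart = 10L)
  assignment <- stats::setNames(km$cluster, feats$unit_id)
  mean_hd <- tapply(feats$half_duration, km$cluster, mean)
  dopa <- as.integer(names(mean_hd)[which.max(mean_hd)])
  centers <- do.call(rbind, lapply(seq_len(config$n_clusters), function(k)
    colMeans(x[km$cluster == k, , drop = FALSE])))
  list(assignment = assignment, dopamine_cluster = dopa, centers = centers)
}

#' Leave-one-out cluster assignment
#'
#' For each unit, every cluster's center and per-axis s.d. are recomputed with
#' that unit excluded; the unit is "within" a cluster when its standardized
#' distance does not exceed the threshold (metric per the config). Units
#' within exactly one cluster take its label; units within zero or more than
#' one cluster are left unclassified. One pass, no iteration.
#'
#' @param features Output of [waveform_features()].
#' @param clustering Output of [initial_clustering()].
#' @param config A [classifier_config()].
#' @return List of class `classification_result`: `labels` (`data.frame` with
#'   `unit_id`, `label`, one distance column per cluster in s.d. units),
#'   `dopamine_cluster`, `clusters` (per-cluster center/s.d./size).
#' @export
classify_leave_one_out <- function(features, clustering,
                                   config = classifier_config()) {
  feats <- features[features$valid, , drop = FALSE]
  assignment <- clustering$assignment[feats$unit_id]
  ks <- sort(unique(assignment))
  x <- cbind(feats$half_duration, feats$amplitude_ratio)
  rownames(x) <- feats$unit_id
  nuni <- nrow(feats)
  dist_mat <- matrix(NA_real_, nuni, length(ks),
                     dimnames = list(feats$unit_id, paste0("d_cluster", ks)))
  within <- matrix(FALSE, nuni, length(ks))
  for (u in seq_len(nuni)) {
    for (ci in seq_along(ks)) {
      members <- which(assignment == ks[ci])
      members <- setdiff(members, u)
      if (length(members) < 2L)
        stop("cluster ", ks[ci], " has fewer than 2 members after excluding ",
             feats$unit_id[u], call. = FALSE)
      ctr <- colMeans(x[members, , drop = FALSE])
      sds <- apply(x[members, , drop = FALSE], 2, stats::sd)
      sds[sds == 0] <- .Machine$double.eps
      z <- abs(x[u, ] - ctr) / sds
      d <- if (config$metric == "axiswise") max(z) else sqrt(sum(z^2))
      dist_mat[u, ci] <- d
      within[u, ci] <- d <= config$sd_threshold
    }
  }
  n_in <- rowSums(within)
  dopa_col <- which(ks == clustering$dopamine_cluster)
  label <- rep("unclassified", nuni)
  one <- n_in == 1L
  label[one & within[, dopa_col]] <- "dopamine"
  label[one & !within[, dopa_col]] <- "other"
  labels <- data.frame(unit_id = feats$unit_id, label = label,
                       stringsAsFactors = FALSE)
  labels <- cbind(labels, as.data.frame(dist_mat, row.names = NULL))
  cl_sum <- lapply(seq_along(ks), function(ci) {
    members <- which(assignment == ks[ci])
    list(cluster = ks[ci],
         center = colMeans(x[members, , drop = FALSE]),
         sd = apply(x[members, , drop = FALSE], 2, stats::sd),
         n = length(members))
  })
  structure(list(labels = labels,
                 dopamine_cluster = clustering$dopamine_cluster,
                 clusters = cl_sum, config = config),
            class = "classification_result")
}

#' Classify a session's units
#'
#' Feature extraction, initial clustering and leave-one-out assignment in one
#' step. Units with undefined features are reported with label
#' `"unclassified"` and `valid = FALSE`.
#'
#' @param session A `vta_session`.
#' @param config A [classifier_config()].
#' @param seed Clustering seed.
#' @return `data.frame` `unit_labels`: `unit_id`, `label`, distances, `valid`.
#' @export
classify_units <- function(session, config = classifier_config(), seed = 1L) {
  feats <- waveform_features(session)
  clus <- initial_clustering(feats, config, seed)
  res <- classify_leave_one_out(feats, clus, config)
  out <- merge(feats[, c("unit_id", "half_duration", "amplitude_ratio", "valid")],
               res$labels, by = "unit_id", all.x = TRUE, sort = FALSE)
  out$label[!out$valid] <- "unclassified"
  out[match(feats$unit_id, out$unit_id), ]
}
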