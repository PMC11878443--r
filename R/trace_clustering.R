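#' Normalize each intensity trace to its maximum
#'
#' Divides every trace by its own maximum value, so traces become comparable
#' by shape (when in the series they were excited) rather than brightness.
#' All-zero traces cannot be normalized and are dropped with a warning.
#'
#' @param traces an `IntensityTraces`.
#' @return an `IntensityTraces` with `normalization_state = "per-trace-max"`.
#' @export
normalize_per_trace <- function(traces) {
  v <- traces$values
  mx <- apply(v, 1, max)
  drop <- mx <= 0
  if (any(drop)) {
    warning(sprintf("dropping %d all-zero trace(s): spot id %s", sum(drop),
                    paste(traces$spot_id[drop], collapse = ", ")))
    v <- v[!drop, , drop = FALSE]
    traces$spot_id <- traces$spot_id[!drop]
    traces$clipped <- traces$clipped[!drop]
    if (!is.null(traces$n_pixels)) traces$n_pixels <- traces$n_pixels[!drop]
    mx <- mx[!drop]
  }
  traces$values <- v / mx
  traces$normalization_state <- "per-trace-max"
  traces
}

#' Cluster reflection traces by excitation epoch
#'
#' k-means clustering of per-trace-normalized intensity traces (the full
#' trace is the feature vector), used to sort reflections by the period of
#' the dose series in which they were maximally excited. Labels are
#' relabeled canonically: cluster 1 has the earliest mean argmax fluence,
#' ascending. Ten restarts are used and the solution with the lowest
#' within-cluster sum of squares kept. If the data hold fewer distinct
#' traces than `k`, the number of clusters is reduced to the number of
#' distinct traces (with a warning), so identical traces always land in one
#' cluster.
#'
#' @param traces a normalized `IntensityTraces` (see [normalize_per_trace()];
#'   raw traces are normalized on the fly with a warning).
#' @param k number of clusters (default 5).
#' @param seed integer RNG seed.
#' @param nstart number of k-means restarts.
#' @return object of class `ClusterResult`: list with `labels` (1..k, one
#'   per trace), `k`, `order` (clusters by ascending mean argmax fluence),
#'   `mean_argmax_fluence`, `inertia`, `seed`, `spot_id`.
#' @export
cluster_traces <- function(traces, k = 5, seed = 0, nstart = 10) {
  if (traces$normalization_state != "per-trace-max") {
    warning("traces not normalized; applying normalize_per_trace()")
    traces <- normalize_per_trace(traces)
  }
  v <- traces$values
  if (nrow(v) < k) {
    stop(sprintf("only %d traces for k = %d clusters; use a smaller k",
                 nrow(v), k))
  }
  k_eff <- min(k, nrow(unique(v)))
  if (k_eff < k) {
    warning(sprintf("only %d distinct traces; clustering with k = %d",
                    k_eff, k_eff))
  }
  set.seed(seed)
  km <- if (k_eff == 1) {
    ctr <- colMeans(v)
    list(cluster = rep(1L, nrow(v)),
         tot.withinss = sum(sweep(v, 2, ctr)^2))
  } else if (k_eff == nrow(v)) {
    # as many clusters as (distinct) traces: each is its own cluster
    list(cluster = seq_len(nrow(v)), tot.withinss = 0)
  } else {
    stats::kmeans(v, centers = k_eff, nstart = nstart, iter.max = 100)
  }
  # canonical order: by mean argmax fluence of member traces, ascending
  arg_fl <- traces$fluence_axis[apply(v, 1, which.max)]
  mean_arg <- tapply(arg_fl, km$cluster, mean)
  ord <- order(mean_arg)
  relabel <- integer(k_eff)
  relabel[ord] <- seq_len(k_eff)
  structure(list(labels = relabel[km$cluster], k = k_eff,
                 order = seq_len(k_eff),
                 mean_argmax_fluence = as.numeric(mean_arg[ord]),
                 inertia = km$tot.withinss, seed = seed,
                 spot_id = traces$spot_id),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %d traces in %d clusters (inertia %.4g)\n",
              length(x$labels), x$k, x$inertia))
  cat("  mean argmax fluence by cluster:",
      paste(sprintf("%.3g", x$mean_argmax_fluence), collapse = ", "), "\n")
  invisible(x)
}
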