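#' Parameters for phenotype outlier detection
#'
#' @param eps DBSCAN neighbourhood radius in (scaled) phenotype-space
#'   distance.
#' @param min_pts DBSCAN core-point threshold (neighbours including self).
#' @param scaling `"standardise"` (each axis to unit variance; the two axes —
#'   maturation time in minutes and fluorescence in a.u. — are on
#'   incomparable scales) or `"none"`.
#' @param min_lineages_per_trap A trap is counted only with strictly more
#'   than 2 lineages (default 3 = "more than 2").
#' @param min_major_cluster_traps An FP is reported only when its major
#'   cluster holds strictly more than 5 traps (default 6 = "more than 5").
#' @return A list of class `outlier_params`.
#' @export
outlier_params <- function(eps = 0.5, min_pts = 5L,
                           scaling = c("standardise", "none"),
                           min_lineages_per_trap = 3L,
                           min_major_cluster_traps = 6L) {
  scaling <- match.arg(scaling)
  stopifnot(eps > 0, min_pts >= 2)
  structure(list(
    eps = eps, min_pts = as.integer(min_pts), scaling = scaling,
    min_lineages_per_trap = as.integer(min_lineages_per_trap),
    min_major_cluster_traps = as.integer(min_major_cluster_traps)
  ), class = "outlier_params")
}

#' DBSCAN clustering
#'
#' Classic density-based clustering: points with at least `min_pts`
#' neighbours within `eps` (self included) are core points; clusters are the
#' connected components of core points under eps-reachability, plus border
#' points assigned to the first core cluster that reaches them; the rest is
#' noise (label 0). Distances are Euclidean; the implementation is the
#' O(n^2) textbook algorithm, adequate for phenotype tables.
#'
#' @param x Numeric matrix, one point per row.
#' @param eps Neighbourhood radius.
#' @param min_pts Core-point neighbour threshold (self included).
#' @return Integer cluster labels, 0 = noise.
#' @export
dbscan_cluster <- function(x, eps, min_pts) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  neigh <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  is_core <- vapply(neigh, length, integer(1)) >= min_pts

  labels <- integer(n)  # 0 = unvisited/noise
  cluster <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !is_core[i]) next
    cluster <- cluster + 1L
    labels[i] <- cluster
    queue <- setdiff(neigh[[i]], i)
    while (length(queue) > 0L) {
      j <- queue[1L]
      queue <- queue[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cluster
        if (is_core[j]) queue <- c(queue, neigh[[j]][labels[neigh[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Detect phenotype outlier traps for one fluorescent protein
#'
#' Pools the per-lineage phenotype points (maturation time, pre-swap
#' fluorescence) of one FP across replicates, clusters them with DBSCAN, and
#' labels traps against the largest ("major") cluster. A trap is counted only
#' if it has strictly more than 2 lineages and all of them agree on being
#' inside or outside the major cluster; the FP is reported only when the
#' major cluster holds strictly more than 5 traps.
#'
#' @param points data.frame with columns `trap_id`, `lineage_id`, `tau_m`,
#'   `pre_chl_fluorescence` (one row per lineage; replicates already pooled).
#' @param params An [outlier_params()].
#' @return A list of class `outlier_result`:
#'   \describe{
#'     \item{trap_labels}{data.frame `(trap_id, n_lineages, label)` with
#'       label in `major`/`deviating`/`excluded`.}
#'     \item{deviating_fraction}{deviating / (deviating + major), `NA` when
#'       the FP is not reportable.}
#'     \item{reportable}{whether the major cluster held enough traps.}
#'     \item{all_noise}{flag: clustering found no cluster at all.}
#'     \item{point_labels}{per-point cluster ids (0 = noise).}
#'   }
#' @export
detect_outliers <- function(points, params = outlier_params()) {
  stopifnot(all(c("trap_id", "lineage_id", "tau_m", "pre_chl_fluorescence")
                %in% names(points)))
  if (nrow(points) < params$min_pts) {
    stop("need at least min_pts = ", params$min_pts, " points")
  }
  if (!all(is.finite(points$tau_m)) ||
      !all(is.finite(points$pre_chl_fluorescence))) {
    stop("phenotype coordinates must be finite")
  }
  xy <- cbind(points$tau_m, points$pre_chl_fluorescence)
  if (params$scaling == "standardise") {
    sds <- apply(xy, 2L, stats::sd)
    sds[sds == 0] <- 1
    xy <- sweep(xy, 2L, sds, "/")
  }
  labels <- dbscan_cluster(xy, params$eps, params$min_pts)
  all_noise <- all(labels == 0L)
  major <- if (all_noise) NA_integer_ else
    as.integer(names(which.max(table(labels[labels > 0L]))))

  in_major <- labels == major & !is.na(major)
  traps <- unique(points$trap_id)
  lab <- character(length(traps))
  n_lin <- integer(length(traps))
  for (k in seq_along(traps)) {
    sel <- points$trap_id == traps[k]
    n_lin[k] <- sum(sel)
    inside <- in_major[sel]
    lab[k] <- if (n_lin[k] < params$min_lineages_per_trap) "excluded"
      else if (all(inside)) "major"
      else if (all(!inside)) "deviating"
      else "excluded"  # not unanimous
  }
  trap_labels <- data.frame(trap_id = traps, n_lineages = n_lin, label = lab,
                            stringsAsFactors = FALSE)
  n_major <- sum(lab == "major")
  n_dev <- sum(lab == "deviating")
  reportable <- n_major >= params$min_major_cluster_traps
  structure(list(
    trap_labels = trap_labels,
    deviating_fraction = if (reportable && (n_major + n_dev) > 0)
      n_dev / (n_major + n_dev) else NA_real_,
    reportable = reportable,
    all_noise = all_noise,
    point_labels = labels
  ), class = "outlier_result")
}
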