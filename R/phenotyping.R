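#' Background-subtracted total cell fluorescence
#'
#' Sum of pixel intensities inside the cell mask with the mean camera
#' background subtracted from every pixel: `sum(pixels) - bg_mean * area`.
#'
#' @param pixels Numeric vector of pixel intensities inside the cell outline
#'   (or, equivalently, pass `raw_total` and `area`).
#' @param bg_mean Mean background intensity per pixel (>= 0).
#' @param raw_total,area Alternative tabular input: the raw summed intensity
#'   and the pixel area.
#' @return Background-subtracted total fluorescence, a.u.
#' @export
total_cell_fluorescence <- function(pixels = NULL, bg_mean = 0,
                                    raw_total = NULL, area = NULL) {
  stopifnot(bg_mean >= 0)
  if (!is.null(pixels)) {
    if (length(pixels) == 0L) stop("empty cell mask")
    return(sum(pixels - bg_mean))
  }
  stopifnot(!is.null(raw_total), !is.null(area))
  raw_total - bg_mean * area
}

#' Build lineage traces from cell observations
#'
#' Sums area and background-subtracted fluorescence over all living
#' descendants of each lineage founder at every frame, carrying the mean
#' surroundings density (area-weighted) for the bleed filter. Times are kept
#' relative to the chloramphenicol swap (t = 0 at swap).
#'
#' @param observations Cell observation data.frame with columns `time`,
#'   `trap_id`, `lineage_id`, `cell_id`, `parent_id`, `area`,
#'   `raw_total_intensity`, `surroundings_mean_density`.
#' @param bg_per_px Camera background per pixel subtracted from raw
#'   intensities.
#' @return data.frame `(lineage_id, trap_id, time, total_fluorescence,
#'   total_area, density, surroundings_density)`, one row per lineage frame.
#' @export
build_lineage_traces <- function(observations, bg_per_px = 0) {
  obs <- observations
  .check_parent_links(obs)
  obs$fl <- total_cell_fluorescence(raw_total = obs$raw_total_intensity,
                                    area = obs$area, bg_mean = bg_per_px)
  key <- interaction(obs$lineage_id, obs$time, drop = TRUE)
  agg <- data.frame(
    lineage_id = tapply(obs$lineage_id, key, `[`, 1L),
    trap_id = tapply(obs$trap_id, key, `[`, 1L),
    time = as.numeric(tapply(obs$time, key, `[`, 1L)),
    total_fluorescence = as.numeric(tapply(obs$fl, key, sum)),
    total_area = as.numeric(tapply(obs$area, key, sum)),
    surroundings_density = as.numeric(
      tapply(obs$surroundings_mean_density * obs$area, key, sum) /
        tapply(obs$area, key, sum)
    ),
    stringsAsFactors = FALSE
  )
  agg$density <- agg$total_fluorescence / agg$total_area
  agg <- agg[order(agg$lineage_id, agg$time), ]
  rownames(agg) <- NULL
  agg
}

.check_parent_links <- function(obs) {
  by_lin <- split(obs, obs$lineage_id)
  for (lin in by_lin) {
    known <- unique(lin$cell_id)
    parents <- unique(lin$parent_id[!is.na(lin$parent_id)])
    broken <- setdiff(parents, known)
    if (length(broken) > 0L) {
      stop("broken parent links in lineage ", lin$lineage_id[1L], ": ",
           paste(utils::head(broken, 5L), collapse = ", "))
    }
    founders <- unique(lin$cell_id[is.na(lin$parent_id)])
    if (length(founders) != 1L) {
      stop("lineage ", lin$lineage_id[1L], " must have exactly one founder, ",
           "found ", length(founders))
    }
  }
  invisible(TRUE)
}

#' Aggregate one lineage's observations into a trace
#'
#' Convenience wrapper over [build_lineage_traces()] for a single lineage,
#' additionally reporting the mean fluorescence of the last three pre-swap
#' frames.
#'
#' @inheritParams build_lineage_traces
#' @return A list with `trace` (the per-frame data.frame) and
#'   `pre_chl_mean_fluorescence` (`NA` with fewer than 3 pre-swap frames).
#' @export
aggregate_lineage <- function(observations, bg_per_px = 0) {
  stopifnot(length(unique(observations$lineage_id)) == 1L)
  trace <- build_lineage_traces(observations, bg_per_px = bg_per_px)
  pre <- trace$total_fluorescence[trace$time <= 0]
  pre_mean <- if (length(pre) >= 3L) mean(utils::tail(pre, 3L)) else NA_real_
  list(trace = trace, pre_chl_mean_fluorescence = pre_mean)
}

#' Bleed-through inclusion filter
#'
#' A lineage is included iff, on average over its frames, the fluorescence
#' density inside the cells is at least `min_ratio`-fold the density of the
#' trap's immediate surroundings (boundary inclusive). Frames with zero
#' surroundings density and positive cell density count as infinitely clean
#' and force inclusion.
#'
#' @param trace One lineage's trace (rows of [build_lineage_traces()]).
#' @param min_ratio Required mean density ratio (default 3).
#' @return Logical: keep this lineage?
#' @export
bleed_filter <- function(trace, min_ratio = 3) {
  ratio <- ifelse(trace$surroundings_density > 0,
                  trace$density / trace$surroundings_density,
                  ifelse(trace$density > 0, Inf, NA_real_))
  m <- mean(ratio, na.rm = TRUE)
  if (is.nan(m)) return(TRUE)  # no usable frames: nothing to exclude on
  m >= min_ratio
}

#' Filter lineages on temporal coverage
#'
#' Retains lineages that already existed at the swap (an observation at or
#' before `t_chl`) and that were tracked to the end of the experiment (an
#' observation at the final frame, within `dt_tol` of `t_end`).
#'
#' @param traces Trace data.frame from [build_lineage_traces()].
#' @param t_chl Swap time (0 in swap-relative time).
#' @param t_end End-of-experiment time.
#' @param dt_tol Tolerance for "reaches the end", minutes.
#' @return The retained subset of `traces`.
#' @export
filter_lineages <- function(traces, t_chl = 0, t_end, dt_tol = 1e-6) {
  stopifnot(t_chl < t_end)
  keep_ids <- vapply(split(traces, traces$lineage_id), function(tr) {
    any(tr$time <= t_chl) && any(abs(tr$time - t_end) <= dt_tol)
  }, logical(1))
  traces[traces$lineage_id %in% names(keep_ids)[keep_ids], ]
}
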