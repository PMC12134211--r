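#' Choose between the single- and double-exponential models
#'
#' For all lineages of one fluorescent protein in one experiment, compute the
#' end-point to peak fluorescence ratio (peak = maximum sample; end point =
#' mean of the last `n_end` samples, for noise robustness) and average over
#' lineages. If the mean ratio is strictly below `threshold` the signal has
#' bleached by more than 15% and the double-exponential model is selected.
#'
#' @param traces List of per-lineage trace data.frames (post-swap rows are
#'   used; each needs `time` and `total_fluorescence`).
#' @param threshold Bleaching decision threshold on mean end/peak
#'   (default 0.85; the boundary itself selects the single model).
#' @param n_end Samples averaged into the end point (default 2).
#' @return `"single"` or `"double"`.
#' @export
choose_model <- function(traces, threshold = 0.85, n_end = 2L) {
  stopifnot(length(traces) >= 1L)
  ratios <- vapply(traces, function(tr) {
    f <- tr$total_fluorescence[tr$time >= 0]
    f <- f[order(tr$time[tr$time >= 0])]
    peak <- max(f)
    endp <- mean(utils::tail(f, n_end))
    endp / peak
  }, numeric(1))
  if (mean(ratios) < threshold) "double" else "single"
}

#' Fit a maturation model to one post-swap trace
#'
#' Nonlinear least squares (Levenberg-Marquardt) on the single- or
#' double-exponential model. Initialisation: `c0` = fluorescence at t = 0
#' clamped positive; `alpha0 = max(F_end/F_0 - 1, 0.1)`; `tau_m0` = time at
#' which half the eventual rise is reached; `tau_b0 = 2 * t_acq`. Bounds:
#' `c > 0`, `alpha >= 0`, `tau_m > 0` and, via the increment
#' parameterisation `tau_b = tau_m + dtau`, `tau_b > tau_m`. A fit whose
#' `tau_m` exceeds the acquisition window is flagged censored (reported as
#' "> t_acq"). If the primary start fails or stalls, a small set of fallback
#' starts is tried and the lowest-residual convergent fit kept;
#' non-convergence of every start yields a flagged failure, not an error.
#'
#' @param times Times after the swap, minutes (post-swap samples, `>= 0`).
#' @param values Total fluorescence at `times`, a.u.
#' @param model `"single"` or `"double"`.
#' @param t_acq Acquisition window, minutes (default 300).
#' @return A list of class `maturation_fit`: `model`, `c`, `alpha`, `tau_m`,
#'   `tau_b` (`NA` for single), `resid_norm`, `censored`, `n_points`,
#'   `converged`.
#' @export
fit_maturation <- function(times, values, model = c("single", "double"),
                           t_acq = 300) {
  model <- match.arg(model)
  keep <- times >= 0 & is.finite(values)
  t <- times[keep]
  y <- values[keep]
  if (length(t) < 5L) stop("need at least 5 post-swap points")
  o <- order(t)
  t <- t[o]; y <- y[o]

  c0 <- max(y[which.min(t)], max(y) * 1e-3, 1e-9)
  f_end <- mean(utils::tail(y, 2L))
  alpha0 <- max(f_end / c0 - 1, 0.1)
  half_level <- c0 + 0.5 * (max(y) - c0)
  above <- which(y >= half_level)
  tau_m0 <- if (length(above) > 0 && t[above[1L]] > 0) t[above[1L]] else
    max(diff(range(t)) / 4, 1)

  failed <- function() {
    structure(list(model = model, c = NA_real_, alpha = NA_real_,
                   tau_m = NA_real_, tau_b = NA_real_, resid_norm = NA_real_,
                   censored = NA, n_points = length(t), converged = FALSE),
              class = "maturation_fit")
  }

  # the documented initialisation first; a few fallback starts guard against
  # singular Jacobians on strongly bleached or slow curves
  dtau0 <- max(2 * t_acq - tau_m0, 1)
  starts <- if (model == "single") {
    list(list(cc = c0, a = alpha0, tm = tau_m0),
         list(cc = c0, a = 1, tm = max(t) / 4),
         list(cc = c0, a = 3, tm = max(t)))
  } else {
    list(list(cc = c0, a = alpha0, tm = tau_m0, dt_ = dtau0),
         list(cc = c0, a = 2, tm = tau_m0, dt_ = 5 * tau_m0),
         list(cc = c0, a = 3, tm = max(t) / 6, dt_ = max(t)),
         list(cc = c0, a = 0.5, tm = max(t) / 2, dt_ = 2 * max(t)))
  }
  one_fit <- function(start) {
    if (model == "single") {
      tryCatch(minpack.lm::nlsLM(
        y ~ cc * (a + 1 - a * exp(-t / tm)),
        start = start,
        lower = c(cc = 1e-12, a = 0, tm = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ), error = function(e) NULL)
    } else {
      tryCatch(minpack.lm::nlsLM(
        # tau_b = tm + dt_ keeps the bleaching time above the maturation time
        y ~ cc * (((tm + dt_) / dt_) * (a + 1) * exp(-t / (tm + dt_)) -
                    a * ((tm + dt_) / dt_) * exp(-t / tm)),
        start = start,
        lower = c(cc = 1e-12, a = 0, tm = 1e-9, dt_ = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ), error = function(e) NULL)
    }
  }
  fit <- NULL
  for (start in starts) {
    cand <- one_fit(start)
    if (is.null(cand)) next
    if (is.null(fit) ||
        sum(stats::resid(cand)^2) < sum(stats::resid(fit)^2) * (1 - 1e-9)) {
      fit <- cand
    }
    # a near-perfect fit needs no further starts
    if (sum(stats::resid(fit)^2) < 1e-16 * sum(y^2)) break
  }
  if (is.null(fit)) return(failed())

  cf <- stats::coef(fit)
  tau_m <- unname(cf["tm"])
  structure(list(
    model = model,
    c = unname(cf["cc"]), alpha = unname(cf["a"]), tau_m = tau_m,
    tau_b = if (model == "double") tau_m + unname(cf["dt_"]) else NA_real_,
    resid_norm = sqrt(sum(stats::resid(fit)^2)),
    censored = tau_m > t_acq,
    n_points = length(t), converged = TRUE
  ), class = "maturation_fit")
}

#' Average lineage traces onto a common time grid
#'
#' @param traces List of trace data.frames (`time`, `total_fluorescence`).
#'   All must share the sampling grid.
#' @return data.frame `(time, total_fluorescence)` with the across-lineage
#'   mean at each time.
#' @export
average_traces <- function(traces) {
  stopifnot(length(traces) >= 1L)
  all_t <- sort(unique(unlist(lapply(traces, function(tr) tr$time))))
  vals <- vapply(traces, function(tr) {
    tr$total_fluorescence[match(all_t, tr$time)]
  }, numeric(length(all_t)))
  data.frame(time = all_t,
             total_fluorescence = rowMeans(as.matrix(vals), na.rm = TRUE))
}

#' Summarise maturation times per fluorescent protein
#'
#' Per FP and replicate: lineage traces are averaged, the model is chosen on
#' that replicate's traces, and the averaged curve is fitted; replicates with
#' `min_traps` or fewer decoded traps are excluded. Across the remaining
#' replicates: mean tau_m, with the standard error of the mean reported only
#' when `sem_replicates` replicates qualify; the summary is censored when the
#' mean exceeds `t_acq`.
#'
#' @param lineage_df data.frame with one row per lineage frame and columns
#'   `fp`, `replicate`, `trap_id`, `lineage_id`, `time`,
#'   `total_fluorescence`.
#' @param min_traps Replicates need strictly more decoded traps than this
#'   (default 4, i.e. "> 4").
#' @param min_lineages FPs need strictly more lineages than this per
#'   qualifying replicate to be reported (default 5, i.e. "> 5").
#' @param t_acq Acquisition window, minutes.
#' @param bleach_threshold Passed to [choose_model()].
#' @param sem_replicates Number of replicates required for a SEM (default 3).
#' @return A list with `per_replicate` (data.frame `fp, replicate, model,
#'   tau_m, censored, n_traps, n_lineages, qualifies`) and `summary`
#'   (data.frame `fp, mean_tau_m, sem, n_replicates, censored, reported`).
#' @export
summarize_fp <- function(lineage_df, min_traps = 4L, min_lineages = 5L,
                         t_acq = 300, bleach_threshold = 0.85,
                         sem_replicates = 3L) {
  stopifnot(all(c("fp", "replicate", "trap_id", "lineage_id", "time",
                  "total_fluorescence") %in% names(lineage_df)))
  per_rep <- list()
  for (fp in unique(lineage_df$fp)) {
    fp_df <- lineage_df[lineage_df$fp == fp, ]
    for (rep_ in unique(fp_df$replicate)) {
      rd <- fp_df[fp_df$replicate == rep_, ]
      traces <- split(rd[, c("time", "total_fluorescence")], rd$lineage_id)
      n_traps <- length(unique(rd$trap_id))
      n_lineages <- length(traces)
      model <- choose_model(traces, threshold = bleach_threshold)
      avg <- average_traces(traces)
      fit <- tryCatch(
        fit_maturation(avg$time, avg$total_fluorescence, model, t_acq = t_acq),
        error = function(e) NULL
      )
      per_rep[[length(per_rep) + 1L]] <- data.frame(
        fp = fp, replicate = rep_, model = model,
        tau_m = if (!is.null(fit) && fit$converged) fit$tau_m else NA_real_,
        censored = if (!is.null(fit) && fit$converged) fit$censored else NA,
        n_traps = n_traps, n_lineages = n_lineages,
        qualifies = n_traps > min_traps & n_lineages > min_lineages &
          !is.null(fit) && isTRUE(fit$converged),
        stringsAsFactors = FALSE
      )
    }
  }
  per_replicate <- do.call(rbind, per_rep)

  summ <- list()
  for (fp in unique(per_replicate$fp)) {
    q <- per_replicate[per_replicate$fp == fp & per_replicate$qualifies &
                         !is.na(per_replicate$tau_m), ]
    if (nrow(q) == 0L) {
      message("FP ", fp, " omitted: no qualifying replicates")
      next
    }
    m <- mean(q$tau_m)
    summ[[length(summ) + 1L]] <- data.frame(
      fp = fp, mean_tau_m = m,
      sem = if (nrow(q) >= sem_replicates)
        stats::sd(q$tau_m) / sqrt(nrow(q)) else NA_real_,
      n_replicates = nrow(q),
      censored = m > t_acq,
      reported = if (m > t_acq) paste0("> ", t_acq, " min")
        else sprintf("%.1f min", m),
      stringsAsFactors = FALSE
    )
  }
  list(per_replicate = per_replicate,
       summary = if (length(summ)) do.call(rbind, summ) else
         data.frame(fp = character(0), mean_tau_m = numeric(0),
                    sem = numeric(0), n_replicates = integer(0),
                    censored = logical(0), reported = character(0)))
}
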