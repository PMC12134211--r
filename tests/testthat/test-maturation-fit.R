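test_that("model evaluators match direct substitution", {
  expect_equal(single_exp_value(0, 100, 2, 60), 100)
  expect_equal(single_exp_value(60, 1, 1, 60), 2 - exp(-1))
  # t -> Inf plateau at c (alpha + 1)
  expect_equal(single_exp_value(1e9, 100, 2, 60), 300)
  # non-decreasing in t for alpha >= 0
  t <- seq(0, 300, 5)
  for (a in c(0, 0.5, 2)) {
    expect_true(all(diff(single_exp_value(t, 10, a, 45)) >= 0))
  }

  # double model: F(0) = c tau_b / (tau_b - tau_m); F(Inf) = 0
  expect_equal(double_exp_value(0, 100, 2, 60, 300), 100 * 300 / 240)
  expect_lt(double_exp_value(1e9, 100, 2, 60, 300), 1e-12)
  expect_error(double_exp_value(10, 1, 1, 60, 60), "singular")
})

test_that("double model converges to the single model as tau_b grows", {
  t <- seq(0, 300, 1)
  y1 <- single_exp_value(t, 100, 2, 60)
  y2 <- double_exp_value(t, 100, 2, 60, 1e9 * 60)
  expect_lt(max(abs(y2 - y1) / y1), 1e-6)
})

test_that("model choice uses the mean end/peak ratio with a strict cut", {
  flat <- data.frame(time = seq(0, 300, 5),
                     total_fluorescence = single_exp_value(seq(0, 300, 5),
                                                           100, 2, 30))
  expect_equal(choose_model(list(flat)), "single")

  # construct traces whose end/peak is exactly controllable
  mk <- function(ratio) {
    f <- c(seq(1, 100, length.out = 40), rep(100 * ratio, 21))
    f[40] <- 100
    data.frame(time = seq(0, 300, 5), total_fluorescence = f)
  }
  expect_equal(choose_model(list(mk(0.80))), "double")
  expect_equal(choose_model(list(mk(0.85))), "single")  # boundary: strict <
  # averaging across traces: 0.80 and 0.95 mean to 0.875 -> single
  expect_equal(choose_model(list(mk(0.80), mk(0.95))), "single")
})

test_that("noiseless fits recover the generating parameters", {
  t <- seq(0, 300, 5)
  y <- single_exp_value(t, 100, 2, 60)
  f <- fit_maturation(t, y, "single")
  expect_true(f$converged)
  expect_lt(abs(f$c - 100) / 100, 1e-6)
  expect_lt(abs(f$alpha - 2) / 2, 1e-6)
  expect_lt(abs(f$tau_m - 60) / 60, 1e-6)
  expect_false(f$censored)

  yd <- double_exp_value(t, 80, 3, 40, 250)
  fd <- fit_maturation(t, yd, "double")
  expect_true(fd$converged)
  expect_lt(abs(fd$tau_m - 40) / 40, 1e-5)
  expect_lt(abs(fd$tau_b - 250) / 250, 1e-5)
  expect_gt(fd$tau_b, fd$tau_m)

  # censoring: tau_m beyond the acquisition window
  slow <- single_exp_value(t, 100, 2, 500)
  fs <- fit_maturation(t, slow, "single", t_acq = 300)
  expect_true(fs$censored)
  # censoring is deterministic on noiseless input
  expect_identical(fs$censored,
                   fit_maturation(t, slow, "single", t_acq = 300)$censored)

  expect_error(fit_maturation(c(0, 5, 10), c(1, 2, 3), "single"), "5 post")
})

test_that("parameter recovery holds across the kinetic grid with noise", {
  # per-replicate estimates come from the lineage-averaged curve; at 100
  # lineages the averaged noise is small and recovery tight across the grid
  t <- seq(0, 300, 5)
  set.seed(42)
  n_lineages <- 100L
  for (tau in c(15, 60, 180)) {
    for (a in c(0.5, 2)) {
      for (noise in c(0, 0.05)) {
        y0 <- single_exp_value(t, 100, a, tau)
        traces <- lapply(seq_len(n_lineages), function(i) {
          data.frame(time = t, total_fluorescence =
                       y0 + rnorm(length(t), 0, noise * max(y0)))
        })
        avg <- average_traces(traces)
        f <- fit_maturation(avg$time, avg$total_fluorescence, "single")
        expect_true(f$converged)
        expect_lt(abs(f$tau_m - tau) / tau, 0.05)
      }
    }
  }
})

test_that("trace averaging aligns lineages on the common grid", {
  t <- seq(0, 20, 5)
  tr1 <- data.frame(time = t, total_fluorescence = rep(10, 5))
  tr2 <- data.frame(time = t, total_fluorescence = rep(20, 5))
  avg <- average_traces(list(tr1, tr2))
  expect_equal(avg$total_fluorescence, rep(15, 5))
})

test_that("per-FP summaries apply the trap and replicate rules", {
  t <- seq(0, 300, 5)
  mk_rep <- function(fp, rep_, n_lineages, n_traps, tau) {
    do.call(rbind, lapply(seq_len(n_lineages), function(i) {
      data.frame(
        fp = fp, replicate = rep_,
        trap_id = paste0(fp, "_r", rep_, "_t", ((i - 1) %% n_traps) + 1),
        lineage_id = paste0(fp, "_r", rep_, "_l", i),
        time = t,
        total_fluorescence = single_exp_value(t, 100, 2, tau),
        stringsAsFactors = FALSE
      )
    }))
  }
  df <- rbind(
    mk_rep("fpA", 1, 8, 6, 50), mk_rep("fpA", 2, 8, 6, 60),
    mk_rep("fpA", 3, 8, 6, 70),
    mk_rep("fpB", 1, 8, 4, 80)   # exactly 4 traps: excluded ("> 4" strict)
  )
  res <- suppressMessages(summarize_fp(df))
  a <- res$summary[res$summary$fp == "fpA", ]
  expect_equal(a$mean_tau_m, 60, tolerance = 1e-6)
  expect_equal(a$sem, sd(c(50, 60, 70)) / sqrt(3), tolerance = 1e-6)
  expect_equal(a$n_replicates, 3L)
  expect_false("fpB" %in% res$summary$fp)
  expect_false(res$per_replicate$qualifies[res$per_replicate$fp == "fpB"])

  # single qualifying replicate: mean reported, SEM absent
  res1 <- suppressMessages(summarize_fp(mk_rep("fpC", 1, 8, 6, 80)))
  expect_equal(res1$summary$mean_tau_m, 80, tolerance = 1e-6)
  expect_true(is.na(res1$summary$sem))

  # censored summary is reported as an exceedance
  slow <- mk_rep("fpD", 1, 8, 6, 500)
  resS <- suppressMessages(summarize_fp(slow))
  expect_true(resS$summary$censored)
  expect_match(resS$summary$reported, "^> 300")
})
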