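cb <- fixture_codebook()

test_that("background statistics recover a Gaussian despite a bright tail", {
  set.seed(1)
  px <- rnorm(1e5, 100, 10)
  bs <- background_stats(px)
  expect_lt(abs(bs$mu - 100), 0.3)
  expect_lt(abs(bs$sigma - 10), 0.3)

  # 1% of pixels at 1e4 (blob tail) must not drag the fit
  px_blob <- c(rnorm(99000, 100, 10), rep(1e4, 1000))
  bs2 <- background_stats(px_blob)
  expect_lt(abs(bs2$mu - 100), 1)

  expect_warning(bs3 <- background_stats(rep(7, 200)), "zero-variance")
  expect_equal(bs3$mu, 7)
  expect_equal(bs3$sigma, 0)
  expect_error(background_stats(rnorm(50)), "100 pixels")
})

test_that("blob masks threshold at mu + k sigma and catch injected blobs", {
  img <- matrix(100, 20, 20)
  params <- decode_params()
  expect_false(any(detect_blob_mask(img, 100, 10, params)))

  # blob of peak mu + 20 sigma at a known footprint
  blob <- outer(1:20, 1:20, function(y, x) {
    200 * exp(-((y - 10)^2 + (x - 10)^2) / (2 * 1.5^2))
  })
  m <- detect_blob_mask(img + blob, 100, 10, params)
  expect_true(any(m))
  inside <- which(m, arr.ind = TRUE)
  expect_true(all(sqrt((inside[, 1] - 10)^2 + (inside[, 2] - 10)^2) < 6))
})

test_that("consensus mask requires at least half of the rounds", {
  params <- decode_params()
  m_on <- matrix(TRUE, 2, 2)
  m_off <- matrix(FALSE, 2, 2)
  expect_true(all(accumulate_mask(rep(list(m_on), 7), params)))
  # 3 of 7 < 3.5: dropped; 4 of 7 >= 3.5: kept
  expect_false(any(accumulate_mask(c(rep(list(m_on), 3), rep(list(m_off), 4)),
                                   params)))
  expect_true(all(accumulate_mask(c(rep(list(m_on), 4), rep(list(m_off), 3)),
                                  params)))
  expect_false(any(accumulate_mask(rep(list(m_off), 7), params)))
})

test_that("round calling applies the area and dominance rules", {
  params <- decode_params(area_min_px = 4L)
  px <- c(10L, 10L, 10L, 10L)
  expect_equal(call_round(c(10, 0, 0, 0), px, params),
               list(call = "symbol", symbol = 0L))
  expect_equal(call_round(c(10, 4, 0, 0), px, params),
               list(call = "symbol", symbol = 0L))   # 10 >= 2 * 4
  expect_equal(call_round(c(10, 6, 0, 0), px, params)$call, "ambiguous")
  expect_equal(call_round(c(0, 0, 0, 0), c(0L, 0L, 0L, 0L), params)$call,
               "none")
  # a bright channel failing the area rule is void
  expect_equal(call_round(c(100, 10, 0, 0), c(2L, 10L, 0L, 0L), params),
               list(call = "symbol", symbol = 1L))
  expect_error(call_round(c(-1, 0, 0, 0), px, params), "non-negative")
})

test_that("trap classification follows the category precedence", {
  word <- cb$codes[5L, ]
  sym <- function(x) rep("symbol", length(x))
  res <- classify_trap(rep("none", 7), rep(NA_integer_, 7), cb)
  expect_equal(res$category, "no_signal")

  calls <- c(sym(word[1:6]), "ambiguous")
  res <- classify_trap(calls, c(word[1:6], NA), cb)
  expect_equal(res$category, "double_signal")

  calls <- c(sym(word[1:6]), "none")
  res <- classify_trap(calls, c(word[1:6], NA), cb)
  expect_equal(res$category, "unassigned")

  res <- classify_trap(sym(word), word, cb)
  expect_equal(res$category, "decoded")
  expect_equal(res$barcode_id, rownames(cb$codes)[5L])
  expect_equal(res$n_corrected, 0L)

  # ambiguity outranks an incomplete word
  calls <- c("none", "ambiguous", sym(word[3:7]))
  res <- classify_trap(calls, c(NA, NA, word[3:7]), cb)
  expect_equal(res$category, "double_signal")
})

test_that("experiment summaries match the generator's bookkeeping", {
  cfg <- genotyping_sim_config(n_traps = 2000L, occupancy_prob = 0.9,
                               p_round_error = 0, p_no_signal = 0.08,
                               p_double_signal = 0.05, seed = 13L)
  run <- run_simulate_decode(cfg)
  truth_counts <- table(run$truth$category[run$truth$occupied])
  expect_equal(unname(run$summary$counts["no_signal"]),
               unname(truth_counts["no_signal"]))
  expect_equal(unname(run$summary$counts["double_signal"]),
               unname(truth_counts["double_signal"]))
  expect_equal(unname(run$summary$counts["decoded"]),
               unname(truth_counts["clean"]))
  # categories partition the occupied traps
  expect_equal(sum(run$summary$counts), run$summary$n_occupied)
  # clean run: every clean trap decodes correctly
  expect_equal(run$accuracy$correct_fraction, 1)

  empty_occ <- data.frame(trap_id = "t1", occupied = FALSE)
  expect_error(summarize_experiment(run$decodes, empty_occ), "no occupied")
})

test_that("image-mode decoding agrees with the generator's ground truth", {
  cfg <- genotyping_sim_config(n_traps = 40L, occupancy_prob = 1,
                               p_round_error = 0, p_no_signal = 0.1,
                               p_double_signal = 0.1, seed = 9L)
  run <- run_simulate_decode(cfg, mode = "image")
  truth_counts <- table(run$truth$category[run$truth$occupied])
  expect_equal(unname(run$summary$counts["no_signal"]),
               unname(truth_counts["no_signal"]))
  expect_equal(unname(run$summary$counts["double_signal"]),
               unname(truth_counts["double_signal"]))
  expect_equal(run$accuracy$correct_fraction, 1)
})

test_that("amplicon counting demands exact single-barcode matches", {
  bcs <- c(a = paste0(strrep("ACGT", 7L), "GC"),
           b = paste0(strrep("TTGA", 7L), "CC"))
  reads <- c(
    paste0("AAAA", bcs[["a"]], "CCCC"),              # one exact hit
    paste0("AAAA", sub("^A", "T", bcs[["a"]]), "CC"), # 1 mismatch: unmatched
    paste0(bcs[["a"]], bcs[["b"]]),                  # both: multi-matched
    strrep("G", 40L)                                 # none
  )
  cnt <- count_amplicon_reads(reads, bcs)
  expect_equal(unname(cnt$counts), c(1, 0))
  expect_equal(cnt$n_unmatched, 2L)
  expect_equal(cnt$n_multi_matched, 1L)

  # reverse-complement matching is off by default, on by flag
  rc_read <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0("AAAA", bcs[["a"]], "CCCC"))
  ))
  expect_equal(unname(count_amplicon_reads(rc_read, bcs)$counts), c(0, 0))
  expect_equal(
    unname(count_amplicon_reads(rc_read, bcs, also_revcomp = TRUE)$counts),
    c(1, 0)
  )
})

test_that("frequency comparison normalises, averages and bands correctly", {
  counts <- c(a = 100, b = 200, c = 700)
  res <- compare_frequencies(counts, counts)
  expect_true(all(res$table$ratio == 1))
  expect_equal(res$n_within_twofold, 3L)

  insitu <- c(a = 0, b = 300, c = 700)
  res2 <- compare_frequencies(insitu, counts)
  expect_equal(res2$table$ratio[res2$table$barcode == "a"], 0)
  expect_equal(res2$n_within_twofold, 2L)

  # zero NGS frequency: undefined ratio, excluded from the band count
  res3 <- compare_frequencies(counts, c(a = 0, b = 500, c = 500))
  expect_true(is.na(res3$table$ratio[res3$table$barcode == "a"]))

  # multinomial subsampling of one composition stays within two-fold
  set.seed(2)
  base <- rep(1 / 85, 85)
  x <- stats::rmultinom(3, 2e4, base)
  y <- stats::rmultinom(3, 2e4, base)
  rownames(x) <- rownames(y) <- sprintf("bc%03d", 1:85)
  res4 <- compare_frequencies(x, y)
  expect_equal(res4$n_within_twofold, 85L)
})
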