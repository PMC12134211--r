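cb <- fixture_codebook()

test_that("codebook construction respects the minimum distance, exhaustively", {
  d <- codebook_distances(cb)
  expect_equal(nrow(cb$codes), 85L)
  expect_true(all(d[upper.tri(d)] >= 3L))  # all C(85,2) = 3570 pairs
  expect_true(all(cb$codes >= 0L & cb$codes <= 3L))

  one <- build_codebook(codebook_spec(n_codes = 1L, seed = 1L))
  expect_equal(nrow(one$codes), 1L)

  expect_error(codebook_spec(n_codes = 4L^7L + 1L), "exceeds")
  # infeasible beyond pigeonhole: too many words for the distance at tiny N
  expect_error(
    build_codebook(codebook_spec(n_codes = 16L, n_rounds = 2L, n_colors = 4L,
                                 min_distance = 3L, correction_radius = 1L),
                   max_attempts = 2000L),
    "construction failed"
  )
})

test_that("construction is deterministic under the spec seed", {
  expect_identical(fixture_codebook(seed = 42L)$codes,
                   fixture_codebook(seed = 42L)$codes)
  expect_false(identical(fixture_codebook(seed = 1L)$codes,
                         fixture_codebook(seed = 2L)$codes))
})

test_that("decoding corrects exactly one error and refuses anything further", {
  ids <- rownames(cb$codes)
  # exact matches decode with zero corrections
  for (i in c(1L, 40L, 85L)) {
    res <- decode_word(cb$codes[i, ], cb)
    expect_equal(res$status, "decoded")
    expect_equal(res$barcode_id, ids[i])
    expect_equal(res$n_corrected, 0L)
  }

  # all 85 x 7 x 3 = 1785 single-symbol corruptions decode to the original
  words <- matrix(0L, 85L * 21L, 7L)
  truth <- character(85L * 21L)
  k <- 0L
  for (i in seq_len(85L)) for (r in seq_len(7L)) for (s in 0:3) {
    if (s == cb$codes[i, r]) next
    k <- k + 1L
    w <- cb$codes[i, ]
    w[r] <- s
    words[k, ] <- w
    truth[k] <- ids[i]
  }
  expect_equal(k, 1785L)
  res <- decode_words(words, cb)
  expect_true(all(res$decoded))
  expect_identical(res$barcode_id, truth)
  expect_true(all(res$n_corrected == 1L))

  # words at distance >= 2 from every codeword are unassigned; find such
  # words by exhaustive distance scan from two-symbol corruptions
  set.seed(1)
  n_checked <- 0L
  while (n_checked < 50L) {
    i <- sample.int(85L, 1L)
    w <- cb$codes[i, ]
    rr <- sample.int(7L, 2L)
    w[rr] <- (w[rr] + sample.int(3L, 2L, replace = TRUE)) %% 4L
    dmin <- min(apply(cb$codes, 1L, function(code) sum(code != w)))
    if (dmin < 2L) next  # the corruption landed near another codeword
    n_checked <- n_checked + 1L
    expect_equal(decode_word(w, cb)$status, "unassigned")
  }

  # missing symbols are never decoded
  w <- cb$codes[3L, ]
  w[4L] <- NA
  expect_equal(decode_word(w, cb)$status, "unassigned")
  expect_error(decode_word(cb$codes[1L, 1:6], cb), "length")
})

test_that("misassignment Monte Carlo behaves at the boundaries", {
  eb0 <- simulate_misassignment(cb, p_round = 0, n_trials = 1e4, seed = 2L)
  expect_equal(eb0$p_wrong, 0)
  expect_equal(eb0$p_correct, 1)
  expect_equal(eb0$p_wrong + eb0$p_unassigned + eb0$p_correct, 1)
  expect_error(simulate_misassignment(cb, 0.038, n_trials = 0), "positive")
})

test_that("wrong and unassigned probabilities grow with the round error", {
  ps <- c(0, 0.05, 0.1, 0.2, 0.3)
  ebs <- lapply(ps, function(p) {
    simulate_misassignment(cb, p, n_trials = 5e4, seed = 9L)
  })
  pw <- vapply(ebs, `[[`, numeric(1), "p_wrong")
  pu <- vapply(ebs, `[[`, numeric(1), "p_unassigned")
  # statistically non-decreasing: allow 3 SE of slack between neighbours
  se <- sqrt(0.25 / 5e4)
  expect_true(all(diff(pw) > -3 * se))
  expect_true(all(diff(pu) > -3 * se))
  expect_true(all(vapply(ebs, function(e) {
    abs(e$p_wrong + e$p_unassigned + e$p_correct - 1) < 1e-12
  }, logical(1))))
})

test_that("round-error estimator matches hand arithmetic and closed form", {
  # 10 traps, one corrected symbol in total, 7 rounds -> 1/70
  expect_equal(
    estimate_round_error(n_corrected = c(1L, rep(0L, 9L)), n_rounds = 7L),
    1 / 70
  )
  obs <- rbind(c(0L, 1L, 2L), c(3L, 3L, 3L))
  asg <- rbind(c(0L, 1L, 2L), c(3L, 0L, 3L))
  expect_equal(estimate_round_error(obs, asg), 1 / 6)
  expect_error(estimate_round_error(n_corrected = integer(0), n_rounds = 7L),
               "undefined")

  # conditioning on decodable traps biases the estimate to p/(1+6p) at C = 4
  p <- 0.06
  eb <- simulate_misassignment(cb, p, n_trials = 1e5, seed = 4L,
                               detail = TRUE)
  dec <- eb$trials[eb$trials$decoded & eb$trials$barcode_id ==
                     eb$trials$truth_id, ]
  est <- estimate_round_error(n_corrected = dec$n_corrected, n_rounds = 7L)
  closed <- p / (1 + 6 * p)
  se <- sqrt(closed * (1 - closed) / (7 * nrow(dec)))
  expect_lt(abs(est - closed), 3 * se)
})

test_that("codebook JSON round-trips with sorted, stable keys", {
  path <- withr::local_tempfile(fileext = ".json")
  write_codebook_json(cb, path)
  back <- read_codebook_json(path)
  expect_identical(back$codes[rownames(cb$codes), ], cb$codes)
  expect_identical(unclass(back$spec), unclass(cb$spec))
  txt1 <- readLines(path)
  write_codebook_json(back, path)
  expect_identical(readLines(path), txt1)
})
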