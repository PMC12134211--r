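test_that("clean genotyping simulations decode perfectly and reproducibly", {
  cfg <- genotyping_sim_config(n_traps = 100L, occupancy_prob = 1,
                               p_round_error = 0, p_no_signal = 0,
                               p_double_signal = 0, seed = 3L)
  run <- run_simulate_decode(cfg)
  expect_equal(run$accuracy$n_clean, 100L)
  expect_equal(run$accuracy$n_decoded_correct, 100L)
  expect_equal(run$accuracy$correct_fraction, 1)

  # byte-identical regeneration under the same config and seed
  s1 <- gen_genotyping(cfg)
  s2 <- gen_genotyping(cfg)
  expect_identical(s1$signals, s2$signals)
  expect_identical(s1$truth, s2$truth)
})

test_that("signals and ground truth are mutually consistent", {
  cfg <- genotyping_sim_config(n_traps = 300L, occupancy_prob = 0.8,
                               p_no_signal = 0.1, p_double_signal = 0.1,
                               seed = 5L)
  sim <- gen_genotyping(cfg)
  renders <- sim$truth$trap_id[sim$truth$category %in%
                                 c("clean", "double_signal")]
  expect_setequal(unique(sim$signals$trap_id), renders)
  # every decodeable trap has exactly one true barcode
  occ <- sim$truth[sim$truth$category != "empty", ]
  expect_true(all(!is.na(occ$barcode_id)))
  expect_true(all(is.na(sim$truth$barcode_id[sim$truth$category == "empty"])))
})

test_that("injected per-round error frequency matches p_round_error", {
  p <- 0.038
  cfg <- genotyping_sim_config(n_traps = 20000L, occupancy_prob = 1,
                               p_round_error = p, p_no_signal = 0,
                               p_double_signal = 0, seed = 8L)
  sim <- gen_genotyping(cfg)
  words <- as.matrix(sim$truth[, paste0("word_r", 1:7)])
  truth_codes <- sim$codebook$codes[sim$truth$barcode_id, ]
  err_rate <- mean(words != truth_codes)
  se <- sqrt(p * (1 - p) / length(words))
  expect_lt(abs(err_rate - p), 3 * se)

  # fraction with exactly one wrong round ~ 7 p (1-p)^6
  one_err <- mean(rowSums(words != truth_codes) == 1L)
  expected <- 7 * p * (1 - p)^6
  se1 <- sqrt(expected * (1 - expected) / nrow(words))
  expect_lt(abs(one_err - expected), 3 * se1)
})

test_that("noiseless phenotype traces equal the kinetic model exactly", {
  strains <- fixture_strains()
  cfg <- pheno_sim_config(strains, n_lineages_per_strain = 2L,
                          noise_sd = 0, bleed_fraction = 0, seed = 4L)
  sim <- gen_phenotyping(cfg)
  traces <- build_lineage_traces(sim$observations)

  for (lin in unique(sim$truth$lineage_id)) {
    s <- sim$truth[sim$truth$lineage_id == lin, ]
    tr <- traces[traces$lineage_id == lin, ]
    post <- if (is.na(s$tau_b)) {
      single_exp_value(pmax(tr$time, 0), s$c, s$alpha, s$tau_m)
    } else {
      double_exp_value(pmax(tr$time, 0), s$c, s$alpha, s$tau_m, s$tau_b)
    }
    # pre-swap plateau is continuous with the model at t = 0
    model <- ifelse(tr$time < 0, post[tr$time == 0][1], post)
    expect_equal(tr$total_fluorescence, model, tolerance = 1e-12)
    # F(0) = c for the single-exponential model
    if (is.na(s$tau_b)) {
      expect_equal(tr$total_fluorescence[tr$time == 0], s$c)
    }
  }
})

test_that("phenotype generator conserves mass at divisions", {
  cfg <- pheno_sim_config(fixture_strains(), n_lineages_per_strain = 2L,
                          noise_sd = 0.5, seed = 6L)
  sim <- gen_phenotyping(cfg)
  obs <- sim$observations
  # at each frame, summed daughter areas/intensities equal the lineage total
  # reconstructed by aggregation; divisions happened (cells multiply)
  n_cells <- tapply(obs$cell_id, list(obs$lineage_id, obs$time),
                    function(x) length(unique(x)))
  expect_gt(max(n_cells, na.rm = TRUE), 1L)
  traces <- build_lineage_traces(obs)
  redo <- tapply(obs$raw_total_intensity, list(obs$lineage_id, obs$time), sum)
  for (lin in rownames(redo)) {
    tr <- traces[traces$lineage_id == lin, ]
    expect_equal(tr$total_fluorescence, unname(redo[lin, ]), tolerance = 1e-9)
  }
})

test_that("phenotype config validation rejects inconsistent kinetics", {
  strains <- fixture_strains()
  strains$tau_b[1] <- strains$tau_m[1] / 2
  expect_error(pheno_sim_config(strains), "tau_b")
  s2 <- fixture_strains()
  s2$tau_m[2] <- -1
  expect_error(pheno_sim_config(s2), "tau_m")
  expect_error(pheno_sim_config(fixture_strains(), dt_fluor = 5, dt_phase = 2),
               "multiple")
})

test_that("amplicon reads embed barcodes at the requested frequencies", {
  p <- design_params(n_candidates = 85L, k = 30L, seed = 1L)
  bcs <- generate_candidates(p)
  amp <- gen_amplicon(bcs, n_reads = 8500L, read_len = 60L, seed = 2L)
  expect_equal(sum(amp$truth_counts), 8500L)
  # multinomial spread: each count near 100 within 5 sd (85 simultaneous bins)
  sd_multi <- sqrt(8500 * (1 / 85) * (84 / 85))
  expect_true(all(abs(amp$truth_counts - 100) < 5 * sd_multi))
  # every read contains its embedded barcode
  cnt <- count_amplicon_reads(amp$reads, bcs)
  expect_equal(unname(cnt$counts), unname(as.numeric(amp$truth_counts)))

  single <- gen_amplicon(bcs[1], barcode_freqs = 1, n_reads = 50L,
                         read_len = 60L, seed = 3L)
  expect_true(all(grepl(bcs[1], single$reads, fixed = TRUE)))

  f1 <- gen_amplicon(bcs, n_reads = 100L, seed = 9L,
                     path = withr::local_tempfile(fileext = ".fastq"))
  f2 <- gen_amplicon(bcs, n_reads = 100L, seed = 9L,
                     path = withr::local_tempfile(fileext = ".fastq"))
  expect_identical(readLines(f1$path), readLines(f2$path))
  expect_error(gen_amplicon(bcs, n_reads = 0L), "positive")
  expect_error(gen_amplicon(bcs, n_reads = 10L, read_len = 20L), "at least")
})
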