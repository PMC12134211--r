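#' Simulate a genotyping experiment and decode it
#'
#' Generator, decoder and summary in one seeded run, with a confusion check
#' of decoded genotypes against the generator's ground truth.
#'
#' @param config A [genotyping_sim_config()].
#' @param codebook Optional [build_codebook()] result (built from the config
#'   seed when `NULL`).
#' @param params A [decode_params()] (geometry is taken from `config`).
#' @param mode `"table"` or `"image"`.
#' @return A list with `summary` ([summarize_experiment()] output),
#'   `decodes`, `truth`, `codebook`, and `accuracy`: a list
#'   `(n_clean, n_decoded_correct, n_decoded_wrong, correct_fraction,
#'   wrong_fraction)` computed over clean occupied traps.
#' @export
run_simulate_decode <- function(config, codebook = NULL,
                                params = NULL, mode = "table") {
  sim <- gen_genotyping(config, codebook = codebook, mode = mode)
  if (is.null(params)) {
    params <- decode_params(n_rounds = config$n_rounds,
                            n_channels = config$n_colors,
                            area_min_px = config$area_min_px)
  }
  signals <- if (mode == "table") sim$signals else
    signals_from_images(sim$images, params)
  decodes <- decode_traps(signals, sim$codebook, params)
  summary <- summarize_experiment(
    decodes, sim$truth[, c("trap_id", "occupied")], n_rounds = config$n_rounds
  )

  truth <- sim$truth
  clean <- truth[truth$category == "clean", c("trap_id", "barcode_id")]
  joined <- merge(clean, decodes[, c("trap_id", "category", "barcode_id")],
                  by = "trap_id", suffixes = c("_true", "_called"),
                  all.x = TRUE)
  decoded <- !is.na(joined$category) & joined$category == "decoded"
  correct <- decoded & joined$barcode_id_called == joined$barcode_id_true
  accuracy <- list(
    n_clean = nrow(joined),
    n_decoded_correct = sum(correct, na.rm = TRUE),
    n_decoded_wrong = sum(decoded) - sum(correct, na.rm = TRUE),
    correct_fraction = sum(correct, na.rm = TRUE) / nrow(joined),
    wrong_fraction = (sum(decoded) - sum(correct, na.rm = TRUE)) / nrow(joined)
  )
  list(summary = summary, decodes = decodes, truth = truth,
       codebook = sim$codebook, accuracy = accuracy)
}

#' Run a full synthetic screen: genotyping plus maturation phenotyping
#'
#' Simulates `n_replicates` chloramphenicol-chase experiments for a strain
#' table, joins phenotype lineages to decoded genotypes by trap, applies the
#' bleed and coverage filters, fits maturation times per FP and replicate,
#' and reports recovery against the generator's kinetic ground truth.
#'
#' Genotype decoding is simulated per replicate at `p_round_error`; lineages
#' in traps that fail to decode (or decode to the wrong barcode) carry that
#' wrong label into the join, as in a real screen.
#'
#' @param strains Strain table as for [pheno_sim_config()] (strain names
#'   double as barcode ids).
#' @param n_replicates Number of replicate experiments.
#' @param n_lineages_per_strain Lineages per strain per replicate.
#' @param p_round_error Per-round decode error probability.
#' @param noise_sd,bleed_fraction Passed to the phenotype generator.
#' @param t_acq Acquisition window, minutes.
#' @param seed Global seed; per-replicate seeds are derived from it.
#' @return A list with `fits` ([summarize_fp()] output), `recovery`
#'   (data.frame `fp, true_tau_m, est_tau_m, rel_error, censored`),
#'   `join_diagnostics` (per replicate: lineages in, genotyped, mislabelled,
#'   filtered) and `lineages` (the joined per-frame table).
#' @export
run_full <- function(strains, n_replicates = 3L, n_lineages_per_strain = 10L,
                     p_round_error = 0.038, noise_sd = 0, bleed_fraction = 0,
                     t_acq = 300, seed = 1L) {
  n_strains <- nrow(strains)
  lineage_rows <- list()
  diagnostics <- list()

  for (r in seq_len(n_replicates)) {
    # stay within 32-bit integer range for any base seed
    rep_seed <- as.integer((as.numeric(seed) * 1009 + r) %%
                             .Machine$integer.max)
    pconf <- pheno_sim_config(
      strains, n_lineages_per_strain = n_lineages_per_strain,
      noise_sd = noise_sd, bleed_fraction = bleed_fraction,
      t_post_chl = t_acq, seed = rep_seed
    )
    pheno <- gen_phenotyping(pconf)
    traces <- build_lineage_traces(pheno$observations,
                                   bg_per_px = pconf$bg_per_px)

    # genotype the phenotyping traps: one trap per lineage, clean occupancy,
    # each trap carrying the phenotype strain's barcode
    gconf <- genotyping_sim_config(
      n_traps = nrow(pheno$truth), occupancy_prob = 1,
      n_barcodes = n_strains, n_rounds = 7L, n_colors = 4L,
      p_round_error = p_round_error, p_no_signal = 0, p_double_signal = 0,
      seed = rep_seed
    )
    cb <- build_codebook(codebook_spec(n_codes = n_strains, seed = seed),
                         ids = strains$strain)
    assignment <- match(pheno$truth$strain, strains$strain)
    gsim <- gen_genotyping(gconf, codebook = cb,
                           barcode_assignment = assignment)
    decode <- decode_traps(gsim$signals, cb,
                           decode_params(n_rounds = 7L, n_channels = 4L))
    # genotyping trap i corresponds to phenotype trap i by construction
    map <- data.frame(ptrap = pheno$truth$trap_id,
                      gtrap = gsim$truth$trap_id,
                      true_strain = pheno$truth$strain,
                      stringsAsFactors = FALSE)
    dec <- merge(map, decode[, c("trap_id", "category", "barcode_id")],
                 by.x = "gtrap", by.y = "trap_id", all.x = TRUE)
    dec$called_strain <- ifelse(!is.na(dec$category) &
                                  dec$category == "decoded",
                                dec$barcode_id, NA_character_)
    mislabelled <- sum(!is.na(dec$called_strain) &
                         dec$called_strain != dec$true_strain)

    joined <- merge(traces, dec[, c("ptrap", "called_strain")],
                    by.x = "trap_id", by.y = "ptrap")
    n_in <- length(unique(traces$lineage_id))
    joined <- joined[!is.na(joined$called_strain), ]

    # inclusion filters
    keep_bleed <- vapply(split(joined, joined$lineage_id), bleed_filter,
                         logical(1))
    joined <- joined[joined$lineage_id %in%
                       names(keep_bleed)[keep_bleed], ]
    joined <- filter_lineages(joined, t_chl = 0, t_end = t_acq)

    diagnostics[[r]] <- data.frame(
      replicate = r, lineages_in = n_in,
      lineages_genotyped = length(unique(joined$lineage_id)),
      traps_mislabelled = mislabelled,
      stringsAsFactors = FALSE
    )
    if (nrow(joined) > 0L) {
      joined$fp <- joined$called_strain
      joined$replicate <- r
      lineage_rows[[r]] <- joined[, c("fp", "replicate", "trap_id",
                                      "lineage_id", "time",
                                      "total_fluorescence")]
    }
  }

  lineages <- do.call(rbind, lineage_rows)
  fits <- summarize_fp(lineages, t_acq = t_acq)
  recovery <- merge(
    fits$summary[, c("fp", "mean_tau_m", "censored")],
    data.frame(fp = strains$strain, true_tau_m = strains$tau_m,
               stringsAsFactors = FALSE),
    by = "fp"
  )
  recovery$rel_error <- abs(recovery$mean_tau_m - recovery$true_tau_m) /
    recovery$true_tau_m
  names(recovery)[names(recovery) == "mean_tau_m"] <- "est_tau_m"

  list(fits = fits, recovery = recovery,
       join_diagnostics = do.call(rbind, diagnostics),
       lineages = lineages)
}
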