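#' Decoding parameters for genotype calling
#'
#' @param sd_multiplier Blob detection threshold in background standard
#'   deviations above the fitted background mean (default 5).
#' @param mask_min_rounds_fraction Fraction of rounds a pixel must appear in
#'   to enter the consensus mask (default 0.5, "at least half").
#' @param dominance_factor A channel is called over competitors only if its
#'   total intensity is at least this multiple of every other surviving
#'   channel's total (default 2).
#' @param area_min_px Minimum above-threshold pixel count for a channel to
#'   count as signal (default 4).
#' @param n_rounds,n_channels Experiment geometry.
#' @return A list of class `decode_params`.
#' @export
decode_params <- function(sd_multiplier = 5, mask_min_rounds_fraction = 0.5,
                          dominance_factor = 2, area_min_px = 4L,
                          n_rounds = 7L, n_channels = 4L) {
  stopifnot(sd_multiplier > 0, dominance_factor >= 1,
            mask_min_rounds_fraction > 0, mask_min_rounds_fraction <= 1)
  structure(list(
    sd_multiplier = sd_multiplier,
    mask_min_rounds_fraction = mask_min_rounds_fraction,
    dominance_factor = dominance_factor, area_min_px = as.integer(area_min_px),
    n_rounds = as.integer(n_rounds), n_channels = as.integer(n_channels)
  ), class = "decode_params")
}

#' Background statistics from a pixel-intensity sample
#'
#' Fits a Gaussian to the binned intensity histogram by least squares, which
#' is robust to the bright right tail contributed by fluorescent blobs (the
#' tail's bins carry few counts and the fit is dominated by the background
#' peak). Falls back to median/MAD if the nonlinear fit fails.
#'
#' @param pixels Numeric vector of pixel intensities (>= 100 values).
#' @param n_bins Histogram bins.
#' @return A list `(mu, sigma)`.
#' @export
background_stats <- function(pixels, n_bins = 100L) {
  if (length(pixels) < 100L) stop("need at least 100 pixels")
  if (stats::sd(pixels) == 0) {
    warning("zero-variance pixel sample; sigma = 0")
    return(list(mu = pixels[1L], sigma = 0))
  }
  h <- graphics::hist(pixels, breaks = n_bins, plot = FALSE)
  x <- h$mids
  y <- h$counts
  mu0 <- stats::median(pixels)
  s0 <- stats::mad(pixels)
  if (s0 == 0) s0 <- stats::sd(pixels)
  a0 <- max(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-(x - mu)^2 / (2 * s^2)),
      start = list(a = a0, mu = mu0, s = s0),
      lower = c(a = 0, mu = -Inf, s = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(list(mu = mu0, sigma = s0))
  cf <- stats::coef(fit)
  list(mu = unname(cf["mu"]), sigma = unname(cf["s"]))
}

#' Threshold a trap image into a blob mask
#'
#' @param img Numeric matrix (one trap tile, one channel).
#' @param mu,sigma Background statistics from [background_stats()].
#' @param params A [decode_params()].
#' @return Logical matrix: pixels above `mu + sd_multiplier * sigma`.
#' @export
detect_blob_mask <- function(img, mu, sigma, params = decode_params()) {
  img > mu + params$sd_multiplier * sigma
}

#' Accumulate per-round masks into a consensus mask
#'
#' A pixel is retained iff it appears in at least
#' `mask_min_rounds_fraction * n_rounds` rounds; with 7 rounds and the
#' default fraction 0.5 that is a count of at least 4 (3.5 rounded up by the
#' `>=` comparison on the real-valued threshold).
#'
#' @param masks List of equal-shape logical matrices, one per round.
#' @param params A [decode_params()].
#' @return Logical consensus matrix.
#' @export
accumulate_mask <- function(masks, params = decode_params()) {
  stopifnot(length(masks) >= 1L)
  counts <- Reduce(`+`, masks)
  counts >= params$mask_min_rounds_fraction * length(masks)
}

#' Call the colour of one round from per-channel signals
#'
#' Channels failing the area rule (fewer than `area_min_px` above-threshold
#' pixels) or with non-positive total intensity are void. One surviving
#' channel is called directly; with several, the brightest is called only if
#' its total intensity is at least `dominance_factor` times every other
#' survivor's, otherwise the round is `ambiguous`. No survivors gives
#' `none`.
#'
#' @param intensities Numeric vector of per-channel total intensities within
#'   the consensus mask.
#' @param n_pixels Integer vector of per-channel above-threshold pixel
#'   counts.
#' @param params A [decode_params()].
#' @return A list `(call, symbol)` with `call` in
#'   `c("none", "symbol", "ambiguous")` and `symbol` the 0-based channel
#'   (`NA` unless `call == "symbol"`).
#' @export
call_round <- function(intensities, n_pixels, params = decode_params()) {
  res <- call_rounds(matrix(intensities, nrow = 1L),
                     matrix(n_pixels, nrow = 1L), params)
  list(call = res$call[1L], symbol = res$symbol[1L])
}

#' Vectorised round calling
#'
#' @param intensity_mat,n_pixel_mat Matrices with one (trap, round) per row
#'   and one column per channel.
#' @param params A [decode_params()].
#' @return data.frame `(call, symbol)`, one row per input row.
#' @export
call_rounds <- function(intensity_mat, n_pixel_mat, params = decode_params()) {
  stopifnot(all(dim(intensity_mat) == dim(n_pixel_mat)))
  if (any(intensity_mat < 0)) stop("intensities must be non-negative")
  surviving <- n_pixel_mat >= params$area_min_px & intensity_mat > 0
  masked <- ifelse(surviving, intensity_mat, -Inf)
  n_surv <- rowSums(surviving)

  top_ch <- max.col(masked, ties.method = "first")
  nr <- nrow(masked)
  top <- masked[cbind(seq_len(nr), top_ch)]
  masked2 <- masked
  masked2[cbind(seq_len(nr), top_ch)] <- -Inf
  second <- masked2[cbind(seq_len(nr), max.col(masked2, ties.method = "first"))]

  call <- rep("none", nr)
  symbol <- rep(NA_integer_, nr)
  one <- n_surv == 1L
  call[one] <- "symbol"
  symbol[one] <- top_ch[one] - 1L
  multi <- n_surv > 1L
  dominant <- multi & top >= params$dominance_factor * second
  call[dominant] <- "symbol"
  symbol[dominant] <- top_ch[dominant] - 1L
  call[multi & !dominant] <- "ambiguous"
  data.frame(call = call, symbol = symbol, stringsAsFactors = FALSE)
}

#' Classify a trap from its round calls
#'
#' Category precedence: all rounds `none` gives `no_signal`; any `ambiguous`
#' round gives `double_signal`; any remaining `none` (incomplete word) gives
#' `unassigned`; otherwise the complete colour word is decoded against the
#' codebook (`decoded` or `unassigned`). Categories are therefore mutually
#' exclusive and exhaustive.
#'
#' @param calls Character vector of round calls
#'   (`"none"`/`"symbol"`/`"ambiguous"`).
#' @param symbols Integer vector of called symbols (`NA` where not
#'   `"symbol"`).
#' @param codebook A [build_codebook()] result.
#' @return A list `(category, barcode_id, n_corrected, word)`.
#' @export
classify_trap <- function(calls, symbols, codebook) {
  n_rounds <- codebook$spec$n_rounds
  stopifnot(length(calls) == n_rounds, length(symbols) == n_rounds)
  if (all(calls == "none")) {
    return(list(category = "no_signal", barcode_id = NA_character_,
                n_corrected = NA_integer_, word = symbols))
  }
  if (any(calls == "ambiguous")) {
    return(list(category = "double_signal", barcode_id = NA_character_,
                n_corrected = NA_integer_, word = symbols))
  }
  if (any(calls == "none")) {
    return(list(category = "unassigned", barcode_id = NA_character_,
                n_corrected = NA_integer_, word = symbols))
  }
  res <- decode_word(symbols, codebook)
  list(category = if (res$status == "decoded") "decoded" else "unassigned",
       barcode_id = res$barcode_id, n_corrected = res$n_corrected,
       word = symbols)
}

#' Decode a whole experiment's signal table
#'
#' Vectorised end-to-end decoding of the long signal table
#' `(trap_id, round, channel, total_intensity, n_pixels)`: per-round colour
#' calls, category assignment and codebook decoding for every trap present
#' in the table. Traps absent from the table (no signal rows at all) are not
#' decoded here; join against the occupancy ground truth or trap list to
#' account for them.
#'
#' @param signals Signal data.frame (rounds 1-based, channels 0-based).
#' @param codebook A [build_codebook()] result.
#' @param params A [decode_params()].
#' @return data.frame `(trap_id, category, barcode_id, n_corrected,
#'   word_r1..word_rN)` with one row per trap.
#' @export
decode_traps <- function(signals, codebook, params = decode_params()) {
  spec <- codebook$spec
  trap_levels <- sort(unique(signals$trap_id))
  ti <- match(signals$trap_id, trap_levels)
  n_traps <- length(trap_levels)
  n_r <- spec$n_rounds
  n_c <- spec$n_colors

  int_arr <- array(0, dim = c(n_traps, n_r, n_c))
  px_arr <- array(0L, dim = c(n_traps, n_r, n_c))
  idx <- cbind(ti, signals$round, signals$channel + 1L)
  int_arr[idx] <- signals$total_intensity
  px_arr[idx] <- signals$n_pixels

  # flatten to (trap*round) x channel
  int_mat <- matrix(aperm(int_arr, c(1, 2, 3)), n_traps * n_r, n_c)
  px_mat <- matrix(aperm(px_arr, c(1, 2, 3)), n_traps * n_r, n_c)
  rc <- call_rounds(int_mat, px_mat, params)

  call_mat <- matrix(rc$call, n_traps, n_r)
  sym_mat <- matrix(rc$symbol, n_traps, n_r)

  all_none <- rowSums(call_mat == "none") == n_r
  any_amb <- rowSums(call_mat == "ambiguous") > 0L
  any_none <- rowSums(call_mat == "none") > 0L
  category <- rep("unassigned", n_traps)
  category[all_none] <- "no_signal"
  category[!all_none & any_amb] <- "double_signal"

  complete <- !all_none & !any_amb & !any_none
  barcode_id <- rep(NA_character_, n_traps)
  n_corrected <- rep(NA_integer_, n_traps)
  if (any(complete)) {
    dec <- decode_words(sym_mat[complete, , drop = FALSE], codebook)
    category[complete][dec$decoded] <- "decoded"
    barcode_id[complete] <- dec$barcode_id
    n_corrected[complete] <- dec$n_corrected
  }

  out <- data.frame(trap_id = trap_levels, category = category,
                    barcode_id = barcode_id, n_corrected = n_corrected,
                    stringsAsFactors = FALSE)
  word_df <- as.data.frame(sym_mat)
  names(word_df) <- paste0("word_r", seq_len(n_r))
  cbind(out, word_df)
}

#' Convert image-mode tiles into a signal table
#'
#' Runs the pixel-level pipeline: per-channel background statistics pooled
#' over all traps, per-round blob masks, the cross-round consensus mask, and
#' per-channel totals of above-threshold pixels within the consensus mask.
#'
#' @param images Nested list `images[[trap]][[round]]` of
#'   `rows x cols x channels` arrays (as produced by image-mode
#'   [gen_genotyping()]).
#' @param params A [decode_params()].
#' @return Signal data.frame as consumed by [decode_traps()], with
#'   backgrounds subtracted from reported intensities.
#' @export
signals_from_images <- function(images, params = decode_params()) {
  stopifnot(length(images) >= 1L)
  n_r <- length(images[[1L]])
  n_c <- dim(images[[1L]][[1L]])[3]

  # pooled background per channel across traps and rounds
  bg <- lapply(seq_len(n_c), function(ch) {
    px <- unlist(lapply(images, function(tr) {
      lapply(tr, function(arr) as.vector(arr[, , ch]))
    }), use.names = FALSE)
    background_stats(px)
  })

  rows <- vector("list", length(images) * n_r * n_c)
  k <- 0L
  for (tid in names(images)) {
    tr <- images[[tid]]
    masks_by_round <- lapply(seq_len(n_r), function(r) {
      per_ch <- lapply(seq_len(n_c), function(ch) {
        detect_blob_mask(tr[[r]][, , ch], bg[[ch]]$mu, bg[[ch]]$sigma, params)
      })
      Reduce(`|`, per_ch)
    })
    consensus <- accumulate_mask(masks_by_round, params)
    for (r in seq_len(n_r)) {
      for (ch in seq_len(n_c)) {
        img <- tr[[r]][, , ch]
        above <- detect_blob_mask(img, bg[[ch]]$mu, bg[[ch]]$sigma, params)
        sel <- above & consensus
        k <- k + 1L
        rows[[k]] <- data.frame(
          trap_id = tid, round = r, channel = ch - 1L,
          total_intensity = sum(img[sel] - bg[[ch]]$mu),
          n_pixels = sum(sel), stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Summarise a decoded experiment
#'
#' Counts traps per category over the occupied traps, the decoded fraction,
#' and the per-round error estimated from the corrections among decoded
#' traps.
#'
#' @param decodes data.frame from [decode_traps()].
#' @param occupancy data.frame `(trap_id, occupied)`; traps occupied but
#'   absent from `decodes` count as `no_signal`.
#' @param n_rounds Rounds per trap.
#' @return A list with `counts` (named vector over categories),
#'   `n_occupied`, `decoded_fraction` and `round_error_estimate`.
#' @export
summarize_experiment <- function(decodes, occupancy, n_rounds = 7L) {
  occ_ids <- occupancy$trap_id[occupancy$occupied]
  if (length(occ_ids) == 0L) stop("no occupied traps")
  d <- decodes[decodes$trap_id %in% occ_ids, ]
  missing <- setdiff(occ_ids, d$trap_id)
  cats <- c(d$category, rep("no_signal", length(missing)))
  counts <- table(factor(cats, levels = c("no_signal", "double_signal",
                                          "unassigned", "decoded")))
  corrected <- d$n_corrected[d$category == "decoded"]
  list(
    counts = c(counts),
    n_occupied = length(occ_ids),
    decoded_fraction = unname(counts["decoded"]) / length(occ_ids),
    round_error_estimate = if (length(corrected) > 0)
      estimate_round_error(n_corrected = corrected, n_rounds = n_rounds)
    else NA_real_
  )
}

#' Count exact barcode matches in amplicon reads
#'
#' A read increments a barcode's count iff the barcode occurs as an exact
#' substring of the read (forward orientation by default). Reads matching no
#' barcode or more than one barcode are tallied separately and do not
#' contribute counts.
#'
#' @param reads Character vector of read sequences, or a FASTQ path.
#' @param barcodes Named character vector of barcode sequences.
#' @param also_revcomp Also search the reverse complement of each read.
#' @return A list with `counts` (per-barcode), `n_unmatched` and
#'   `n_multi_matched`.
#' @export
count_amplicon_reads <- function(reads, barcodes, also_revcomp = FALSE) {
  if (length(reads) == 1L && file.exists(reads)) {
    x <- Biostrings::readDNAStringSet(reads, format = "fastq")
  } else {
    x <- Biostrings::DNAStringSet(reads)
  }
  if (is.null(names(barcodes))) {
    names(barcodes) <- sprintf("bc%03d", seq_along(barcodes))
  }
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(unname(barcodes)))
  hit <- Biostrings::vcountPDict(pd, x) > 0L  # barcodes x reads
  if (also_revcomp) {
    hit <- hit | (Biostrings::vcountPDict(pd, Biostrings::reverseComplement(x)) > 0L)
  }
  per_read <- colSums(hit)
  single <- per_read == 1L
  counts <- rowSums(hit[, single, drop = FALSE])
  names(counts) <- names(barcodes)
  list(counts = counts,
       n_unmatched = sum(per_read == 0L),
       n_multi_matched = sum(per_read > 1L))
}

#' Compare in situ and amplicon barcode frequencies
#'
#' Count vectors are normalised to frequencies per experiment, averaged
#' across replicates, and the per-barcode ratio in-situ / NGS is reported
#' together with the number of barcodes within a two-fold band
#' (`0.5 < ratio < 2`). Barcodes with zero mean NGS frequency get an
#' undefined ratio and are excluded from the two-fold count.
#'
#' @param insitu_counts Matrix or data.frame of in situ counts, one column
#'   per replicate, rows named by barcode (a vector is a single replicate).
#' @param ngs_counts Same layout for amplicon counts; same barcode universe.
#' @return A list with `table` (data.frame `barcode, freq_insitu, freq_ngs,
#'   ratio`) and `n_within_twofold`.
#' @export
compare_frequencies <- function(insitu_counts, ngs_counts) {
  norm_mean <- function(x) {
    m <- as.matrix(x)
    freqs <- sweep(m, 2L, colSums(m), "/")
    rowMeans(freqs)
  }
  fi <- norm_mean(insitu_counts)
  fn <- norm_mean(ngs_counts)
  if (!identical(names(fi), names(fn))) {
    stop("in situ and NGS tables must share the same barcode universe")
  }
  ratio <- ifelse(fn > 0, fi / fn, NA_real_)
  tab <- data.frame(barcode = names(fi), freq_insitu = unname(fi),
                    freq_ngs = unname(fn), ratio = unname(ratio),
                    stringsAsFactors = FALSE)
  list(table = tab,
       n_within_twofold = sum(!is.na(ratio) & ratio > 0.5 & ratio < 2))
}
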