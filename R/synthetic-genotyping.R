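#' Configuration for the synthetic genotyping generator
#'
#' Describes a mother-machine genotyping experiment: occupied traps carry one
#' strain each, probed over `n_rounds` rounds in `n_colors` colours. Per
#' round, an occupied signal-producing trap renders its codeword colour with
#' probability `1 - p_round_error` and a uniformly chosen wrong colour
#' otherwise (errors independent across rounds). A fraction of occupied traps
#' produce no signal at all, and a fraction fluoresce in two colours.
#'
#' @param n_traps Number of traps on the chip.
#' @param occupancy_prob Probability a trap holds cells (DAPI-positive).
#' @param n_barcodes Number of strains/barcodes in the library.
#' @param barcode_freqs Loading frequencies (length `n_barcodes`, sums to 1);
#'   default uniform.
#' @param n_rounds,n_colors Code geometry (must match the codebook used).
#' @param p_round_error Per-round probability that the rendered colour is
#'   wrong (the measured reference point is 0.038).
#' @param p_no_signal Fraction of occupied traps producing no signal.
#' @param p_double_signal Fraction of occupied traps fluorescing in two
#'   colours every round.
#' @param bg_mean,bg_sd Gaussian pixel background (image mode), intensity
#'   units.
#' @param blob_intensity_scale Blob peak scale above background; each blob's
#'   peak is `blob_intensity_scale * exp(rnorm(1, 0, 0.3))`.
#' @param blob_sigma_px Isotropic Gaussian blob sigma in pixels.
#' @param trap_shape_px Trap tile shape `c(rows, cols)` (image mode).
#' @param area_min_px Minimum above-threshold pixel count a real blob attains.
#' @param seed Integer seed.
#' @return A list of class `genotyping_sim_config`.
#' @export
genotyping_sim_config <- function(n_traps = 4000L, occupancy_prob = 0.9,
                                  n_barcodes = 85L, barcode_freqs = NULL,
                                  n_rounds = 7L, n_colors = 4L,
                                  p_round_error = 0.038,
                                  p_no_signal = 0.05, p_double_signal = 0.03,
                                  bg_mean = 100, bg_sd = 10,
                                  blob_intensity_scale = 500,
                                  blob_sigma_px = 1.5,
                                  trap_shape_px = c(12L, 12L),
                                  area_min_px = 4L, seed = 1L) {
  if (is.null(barcode_freqs)) barcode_freqs <- rep(1 / n_barcodes, n_barcodes)
  probs <- c(occupancy_prob, p_round_error, p_no_signal, p_double_signal)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p_no_signal + p_double_signal > 1) {
    stop("p_no_signal + p_double_signal must not exceed 1")
  }
  if (length(barcode_freqs) != n_barcodes ||
      abs(sum(barcode_freqs) - 1) > 1e-9) {
    stop("barcode_freqs must have length n_barcodes and sum to 1")
  }
  stopifnot(n_colors >= 2, n_rounds >= 1, length(trap_shape_px) == 2)
  structure(list(
    n_traps = as.integer(n_traps), occupancy_prob = occupancy_prob,
    n_barcodes = as.integer(n_barcodes), barcode_freqs = barcode_freqs,
    n_rounds = as.integer(n_rounds), n_colors = as.integer(n_colors),
    p_round_error = p_round_error, p_no_signal = p_no_signal,
    p_double_signal = p_double_signal, bg_mean = bg_mean, bg_sd = bg_sd,
    blob_intensity_scale = blob_intensity_scale,
    blob_sigma_px = blob_sigma_px,
    trap_shape_px = as.integer(trap_shape_px),
    area_min_px = as.integer(area_min_px), seed = as.integer(seed)
  ), class = "genotyping_sim_config")
}

#' Generate a synthetic genotyping experiment
#'
#' Produces per-trap round signals with full ground truth. In `"table"` mode
#' (the default, fast) the output is a long table of per-trap, per-round,
#' per-channel blob totals; in `"image"` mode each trap/round/channel becomes
#' a small pixel tile with Gaussian background and a rendered blob, feeding
#' the pixel-level decoder entry points.
#'
#' Double-signal traps render the true colour *and* a second colour at equal
#' intensity in every round, so the dominance rule can never rescue them —
#' their ground-truth category is exact.
#'
#' @param config A [genotyping_sim_config()].
#' @param codebook A [build_codebook()] result with matching geometry; built
#'   from the config's seed when `NULL`.
#' @param mode `"table"` or `"image"`.
#' @param barcode_assignment Optional integer vector (length `n_traps`,
#'   values in `1..n_barcodes`) fixing which barcode each trap carries;
#'   sampled from `barcode_freqs` when `NULL`.
#' @return A list with:
#'   \describe{
#'     \item{signals}{table mode: data.frame `(trap_id, round, channel,
#'       total_intensity, n_pixels)`, one row per occupied-trap round channel.}
#'     \item{images}{image mode: nested list `images[[trap]][[round]]` of
#'       `rows x cols x n_colors` arrays.}
#'     \item{truth}{data.frame `(trap_id, occupied, category, barcode_id)`
#'       with the intended decode category (`empty`, `no_signal`,
#'       `double_signal`, `clean`) and true rendered words (`word` columns).}
#'     \item{codebook, config}{echoes.}
#'   }
#' @export
gen_genotyping <- function(config, codebook = NULL, mode = c("table", "image"),
                           barcode_assignment = NULL) {
  stopifnot(inherits(config, "genotyping_sim_config"))
  mode <- match.arg(mode)
  if (is.null(codebook)) {
    codebook <- build_codebook(codebook_spec(
      n_codes = config$n_barcodes, n_rounds = config$n_rounds,
      n_colors = config$n_colors, seed = config$seed
    ))
  }
  stopifnot(codebook$spec$n_rounds == config$n_rounds,
            codebook$spec$n_colors == config$n_colors,
            nrow(codebook$codes) >= config$n_barcodes)
  set.seed(config$seed)
  n <- config$n_traps

  occupied <- stats::runif(n) < config$occupancy_prob
  barcode_idx <- if (is.null(barcode_assignment)) {
    sample.int(config$n_barcodes, n, replace = TRUE,
               prob = config$barcode_freqs)
  } else {
    stopifnot(length(barcode_assignment) == n,
              all(barcode_assignment >= 1L),
              all(barcode_assignment <= config$n_barcodes))
    as.integer(barcode_assignment)
  }
  u <- stats::runif(n)
  category <- rep("empty", n)
  category[occupied] <- "clean"
  category[occupied & u < config$p_no_signal] <- "no_signal"
  category[occupied & u >= config$p_no_signal &
             u < config$p_no_signal + config$p_double_signal] <- "double_signal"

  # rendered colour per trap x round: codeword symbol, corrupted per round
  words <- codebook$codes[barcode_idx, , drop = FALSE]
  err <- matrix(stats::runif(n * config$n_rounds) < config$p_round_error,
                n, config$n_rounds)
  n_err <- sum(err)
  if (n_err > 0L) {
    shift <- sample.int(config$n_colors - 1L, n_err, replace = TRUE)
    words[err] <- (words[err] + shift) %% config$n_colors
  }
  # second colour for double-signal traps: fixed offset per trap
  second <- (words + sample.int(config$n_colors - 1L, n, replace = TRUE)) %%
    config$n_colors

  trap_id <- sprintf("trap%06d", seq_len(n))
  truth <- data.frame(
    trap_id = trap_id, occupied = occupied, category = category,
    barcode_id = ifelse(occupied & category != "empty",
                        rownames(codebook$codes)[barcode_idx], NA_character_),
    stringsAsFactors = FALSE
  )
  truth$barcode_id[truth$category %in% c("empty")] <- NA_character_
  word_df <- as.data.frame(words)
  names(word_df) <- paste0("word_r", seq_len(config$n_rounds))
  truth <- cbind(truth, word_df)

  renders <- occupied & category %in% c("clean", "double_signal")
  out <- list(truth = truth, codebook = codebook, config = config, mode = mode)

  if (mode == "table") {
    out$signals <- .render_signal_table(config, trap_id, renders,
                                        category, words, second)
  } else {
    out$images <- .render_signal_images(config, trap_id, occupied, renders,
                                        category, words, second)
  }
  out
}

# Table mode: above-threshold blob totals per trap x round x channel.
# Signal channels get a lognormally spread blob; silent channels read zero
# pixels (below the area rule by construction).
.render_signal_table <- function(config, trap_id, renders, category,
                                 words, second) {
  idx <- which(renders)
  n_r <- config$n_rounds
  n_c <- config$n_colors
  if (length(idx) == 0L) {
    return(data.frame(trap_id = character(0), round = integer(0),
                      channel = integer(0), total_intensity = numeric(0),
                      n_pixels = integer(0)))
  }
  # one row per rendered trap x round
  trap_rep <- rep(idx, each = n_r)
  round_rep <- rep(seq_len(n_r), times = length(idx))
  prim_chan <- words[cbind(trap_rep, round_rep)]
  blob_px <- pmax(config$area_min_px,
                  stats::rpois(length(trap_rep), lambda = 12))
  blob_int <- config$blob_intensity_scale *
    exp(stats::rnorm(length(trap_rep), 0, 0.3)) * blob_px

  rows <- data.frame(
    trap_id = trap_id[trap_rep], round = round_rep, channel = prim_chan,
    total_intensity = blob_int, n_pixels = blob_px, stringsAsFactors = FALSE
  )
  dbl <- category[trap_rep] == "double_signal"
  if (any(dbl)) {
    rows2 <- data.frame(
      trap_id = trap_id[trap_rep[dbl]], round = round_rep[dbl],
      channel = second[cbind(trap_rep[dbl], round_rep[dbl])],
      total_intensity = blob_int[dbl], n_pixels = blob_px[dbl],
      stringsAsFactors = FALSE
    )
    rows <- rbind(rows, rows2)
  }
  # silent channels: zero pixels, zero intensity
  all_rows <- expand.grid(trap_id = trap_id[idx], round = seq_len(n_r),
                          channel = seq_len(n_c) - 1L,
                          stringsAsFactors = FALSE)
  key_all <- paste(all_rows$trap_id, all_rows$round, all_rows$channel)
  key_sig <- paste(rows$trap_id, rows$round, rows$channel)
  silent <- all_rows[!(key_all %in% key_sig), ]
  silent$total_intensity <- 0
  silent$n_pixels <- 0L
  sig <- rbind(rows, silent)
  sig <- sig[order(sig$trap_id, sig$round, sig$channel), ]
  rownames(sig) <- NULL
  sig
}

# Image mode: per trap/round a rows x cols x channels array of Gaussian
# background plus an isotropic Gaussian blob on each rendered channel.
.render_signal_images <- function(config, trap_id, occupied, renders,
                                  category, words, second) {
  shp <- config$trap_shape_px
  n_r <- config$n_rounds
  n_c <- config$n_colors
  images <- vector("list", sum(occupied))
  names(images) <- trap_id[occupied]
  for (t in which(occupied)) {
    # the rolling-circle amplicon sits at a fixed spot: one blob position per
    # trap, re-probed (in varying colours) every round
    cy <- stats::runif(1, 3, shp[1] - 2)
    cx <- stats::runif(1, 3, shp[2] - 2)
    shape <- outer(seq_len(shp[1]), seq_len(shp[2]), function(y, x) {
      exp(-((y - cy)^2 + (x - cx)^2) / (2 * config$blob_sigma_px^2))
    })
    per_round <- vector("list", n_r)
    for (r in seq_len(n_r)) {
      arr <- array(stats::rnorm(shp[1] * shp[2] * n_c,
                                config$bg_mean, config$bg_sd),
                   dim = c(shp[1], shp[2], n_c))
      if (renders[t]) {
        chans <- words[t, r]
        if (category[t] == "double_signal") chans <- c(chans, second[t, r])
        peak <- config$blob_intensity_scale * exp(stats::rnorm(1, 0, 0.3))
        for (ch in chans) arr[, , ch + 1L] <- arr[, , ch + 1L] + peak * shape
      }
      per_round[[r]] <- arr
    }
    images[[trap_id[t]]] <- per_round
  }
  images
}

#' Write image-mode tiles as a multi-page TIFF
#'
#' Pages are ordered trap-major, then round, then channel; the companion
#' index data.frame is returned so pages can be mapped back.
#'
#' @param images The `images` element of an image-mode [gen_genotyping()] run.
#' @param path Output TIFF path.
#' @return Invisibly, a data.frame `(page, trap_id, round, channel)`.
#' @export
write_trap_tiff <- function(images, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export")
  }
  pages <- list()
  index <- list()
  p <- 0L
  for (tid in names(images)) {
    for (r in seq_along(images[[tid]])) {
      arr <- images[[tid]][[r]]
      for (ch in seq_len(dim(arr)[3])) {
        p <- p + 1L
        pages[[p]] <- arr[, , ch] / max(1, max(arr))  # [0,1] for storage
        index[[p]] <- data.frame(page = p, trap_id = tid, round = r,
                                 channel = ch - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(do.call(rbind, index))
}
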