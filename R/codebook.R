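#' Specification of a colour codebook
#'
#' A codebook assigns each barcode a codeword: one detection colour per
#' genotyping round. With `n_rounds` rounds and `n_colors` colours the code
#' space holds `n_colors^n_rounds` words; enforcing a minimum pairwise Hamming
#' distance of `min_distance = 3` permits correction of a single round error.
#'
#' @param n_codes Number of codewords (one per barcode).
#' @param n_rounds Rounds of sequential probing (codeword length N).
#' @param n_colors Detection colours per round (alphabet size C).
#' @param min_distance Minimum pairwise Hamming distance between codewords.
#' @param correction_radius Maximum number of corrected symbols during
#'   decoding; must satisfy `min_distance >= 2 * correction_radius + 1`.
#' @param seed Integer seed for the randomised construction.
#'
#' @return A list of class `codebook_spec`.
#' @export
codebook_spec <- function(n_codes = 85L, n_rounds = 7L, n_colors = 4L,
                          min_distance = 3L, correction_radius = 1L,
                          seed = 1L) {
  stopifnot(
    n_codes >= 1, n_rounds >= 1, n_colors >= 2,
    min_distance >= 2L * correction_radius + 1L
  )
  if (n_codes > n_colors^n_rounds) {
    stop("n_codes exceeds the code space size n_colors^n_rounds = ",
         n_colors^n_rounds)
  }
  structure(list(
    n_codes = as.integer(n_codes), n_rounds = as.integer(n_rounds),
    n_colors = as.integer(n_colors), min_distance = as.integer(min_distance),
    correction_radius = as.integer(correction_radius), seed = as.integer(seed)
  ), class = "codebook_spec")
}

#' Build a random minimum-distance codebook
#'
#' Seeded rejection sampling: codewords are drawn uniformly at random and
#' accepted only if their Hamming distance to every previously accepted word
#' is at least `spec$min_distance`. Construction fails loudly after
#' `max_attempts` rejected draws.
#'
#' Symbols are 0-based integers in `[0, n_colors)`; mapping them to dye names
#' is presentation only.
#'
#' @param spec A [codebook_spec()].
#' @param ids Optional character vector of barcode ids (length `n_codes`).
#' @param max_attempts Total rejected draws tolerated before erroring.
#' @return A list of class `codebook` with elements `codes` (an
#'   `n_codes x n_rounds` integer matrix, rownames = ids) and `spec`.
#' @export
build_codebook <- function(spec, ids = NULL, max_attempts = 1e6) {
  stopifnot(inherits(spec, "codebook_spec"))
  if (is.null(ids)) ids <- sprintf("bc%03d", seq_len(spec$n_codes))
  stopifnot(length(ids) == spec$n_codes, !anyDuplicated(ids))
  set.seed(spec$seed)

  codes <- matrix(NA_integer_, nrow = spec$n_codes, ncol = spec$n_rounds)
  n_accepted <- 0L
  attempts <- 0L
  while (n_accepted < spec$n_codes) {
    cand <- sample.int(spec$n_colors, spec$n_rounds, replace = TRUE) - 1L
    ok <- if (n_accepted == 0L) TRUE else {
      d <- rowSums(codes[seq_len(n_accepted), , drop = FALSE] !=
                     matrix(cand, n_accepted, spec$n_rounds, byrow = TRUE))
      all(d >= spec$min_distance)
    }
    if (ok) {
      n_accepted <- n_accepted + 1L
      codes[n_accepted, ] <- cand
    } else {
      attempts <- attempts + 1L
      if (attempts >= max_attempts) {
        stop("codebook construction failed: ", attempts, " rejections while ",
             n_accepted, "/", spec$n_codes, " codewords placed; the spec may ",
             "be infeasible (distance ", spec$min_distance, " over ",
             spec$n_colors, "^", spec$n_rounds, " words)")
      }
    }
  }
  rownames(codes) <- ids
  structure(list(codes = codes, spec = spec), class = "codebook")
}

#' Pairwise Hamming distances between all codewords
#'
#' @param codebook A [build_codebook()] result.
#' @return Symmetric integer matrix of distances.
#' @export
codebook_distances <- function(codebook) {
  codes <- codebook$codes
  n <- nrow(codes)
  d <- matrix(0L, n, n, dimnames = list(rownames(codes), rownames(codes)))
  for (i in seq_len(n)) {
    d[i, ] <- as.integer(rowSums(codes != matrix(codes[i, ], n, ncol(codes),
                                                 byrow = TRUE)))
  }
  d
}

#' Decode one observed colour word
#'
#' An observation decodes to a codeword if it matches exactly, or if exactly
#' one codeword lies at Hamming distance 1 (single-error correction, whose
#' uniqueness is guaranteed when the codebook's minimum distance is >= 3).
#' Observations with any missing symbol (`NA`), or at distance >= 2 from every
#' codeword, are unassigned.
#'
#' @param word Integer vector of length `n_rounds` with symbols in
#'   `[0, n_colors)`; `NA` marks a missing round.
#' @param codebook A [build_codebook()] result.
#' @return A list with `status` (`"decoded"` or `"unassigned"`), `barcode_id`
#'   (`NA` when unassigned) and `n_corrected` (0 or 1; `NA` when unassigned).
#' @export
decode_word <- function(word, codebook) {
  spec <- codebook$spec
  if (length(word) != spec$n_rounds) {
    stop("word length ", length(word), " != n_rounds ", spec$n_rounds)
  }
  res <- decode_words(matrix(as.integer(word), nrow = 1L), codebook)
  list(status = if (res$decoded[1L]) "decoded" else "unassigned",
       barcode_id = res$barcode_id[1L],
       n_corrected = res$n_corrected[1L])
}

#' Decode many observed colour words at once
#'
#' Vectorised form of [decode_word()]: distances to all codewords are computed
#' by a one-hot matrix product, in chunks to bound memory.
#'
#' @param words Integer matrix, one observation per row, `n_rounds` columns;
#'   `NA` marks missing symbols (those rows are unassigned).
#' @param codebook A [build_codebook()] result.
#' @param chunk_size Rows decoded per chunk.
#' @return A data.frame with columns `decoded` (logical), `barcode_id`
#'   (character, `NA` if unassigned) and `n_corrected` (integer, `NA` if
#'   unassigned).
#' @export
decode_words <- function(words, codebook, chunk_size = 100000L) {
  spec <- codebook$spec
  stopifnot(is.matrix(words), ncol(words) == spec$n_rounds)
  n <- nrow(words)
  codes <- codebook$codes
  ids <- rownames(codes)
  code_onehot <- .symbols_onehot(codes, spec$n_colors)

  decoded <- logical(n)
  barcode_id <- rep(NA_character_, n)
  n_corrected <- rep(NA_integer_, n)

  has_na <- rowSums(is.na(words)) > 0L
  todo <- which(!has_na)
  starts <- if (length(todo)) seq(1L, length(todo), by = chunk_size) else
    integer(0)
  for (start in starts) {
    idx <- todo[start:min(start + chunk_size - 1L, length(todo))]
    w_onehot <- .symbols_onehot(words[idx, , drop = FALSE], spec$n_colors)
    d <- spec$n_rounds - tcrossprod(w_onehot, code_onehot)  # chunk x n_codes
    dmin <- d[cbind(seq_len(nrow(d)), max.col(-d, ties.method = "first"))]
    nearest <- max.col(-d, ties.method = "first")
    n_at_min <- rowSums(d == dmin)
    ok <- dmin <= spec$correction_radius & n_at_min == 1L
    ok[dmin == 0L] <- TRUE  # exact matches are unique by construction
    decoded[idx] <- ok
    barcode_id[idx[ok]] <- ids[nearest[ok]]
    n_corrected[idx[ok]] <- as.integer(dmin[ok])
  }
  data.frame(decoded = decoded, barcode_id = barcode_id,
             n_corrected = n_corrected, stringsAsFactors = FALSE)
}

.symbols_onehot <- function(mat, n_colors) {
  do.call(cbind, lapply(seq_len(n_colors) - 1L, function(s) (mat == s) * 1))
}

#' Monte-Carlo misassignment probability of a codebook
#'
#' Draws a true codeword uniformly per trial; independently in each round,
#' with probability `p_round` the symbol is replaced by a uniformly chosen
#' *different* symbol (errors uncorrelated between rounds); the corrupted word
#' is decoded with single-error correction; outcomes are tallied.
#'
#' Probabilities are reported as fractions of all trials, so they sum to one
#' exactly; `p_wrong_given_decoded` gives the alternative normalisation
#' conditional on the trap being decoded at all.
#'
#' @param codebook A [build_codebook()] result.
#' @param p_round Per-round symbol error probability.
#' @param n_trials Number of Monte-Carlo trials.
#' @param seed Integer seed.
#' @param detail Also return the per-trial outcome table (`truth_id`,
#'   `decoded`, `barcode_id`, `n_corrected`) as `$trials`, for estimator
#'   studies.
#' @return A list of class `error_budget`: `p_round`, `p_wrong`,
#'   `p_unassigned`, `p_correct`, `p_wrong_given_decoded`, `n_trials`, and
#'   `n_corrected_total` (sum of corrections over decoded trials, for
#'   round-error estimation); plus `trials` when `detail = TRUE`.
#' @export
simulate_misassignment <- function(codebook, p_round, n_trials = 1e6,
                                   seed = 1L, detail = FALSE) {
  stopifnot(p_round >= 0, p_round <= 1)
  n_trials <- as.integer(n_trials)
  if (n_trials <= 0L) stop("n_trials must be positive")
  spec <- codebook$spec
  set.seed(seed)

  truth_idx <- sample.int(spec$n_codes, n_trials, replace = TRUE)
  words <- codebook$codes[truth_idx, , drop = FALSE]
  err <- matrix(stats::runif(n_trials * spec$n_rounds) < p_round,
                n_trials, spec$n_rounds)
  n_err <- sum(err)
  if (n_err > 0L) {
    # shift by 1..C-1 modulo C: uniform over the other colours
    shift <- sample.int(spec$n_colors - 1L, n_err, replace = TRUE)
    words[err] <- (words[err] + shift) %% spec$n_colors
  }

  res <- decode_words(words, codebook)
  truth_id <- rownames(codebook$codes)[truth_idx]
  n_correct <- sum(res$decoded & res$barcode_id == truth_id, na.rm = TRUE)
  n_wrong <- sum(res$decoded) - n_correct
  n_unassigned <- n_trials - n_correct - n_wrong

  trials <- if (detail) {
    data.frame(truth_id = truth_id, decoded = res$decoded,
               barcode_id = res$barcode_id, n_corrected = res$n_corrected,
               stringsAsFactors = FALSE)
  } else NULL
  structure(list(
    trials = trials,
    p_round = p_round,
    p_wrong = n_wrong / n_trials,
    p_unassigned = n_unassigned / n_trials,
    p_correct = n_correct / n_trials,
    p_wrong_given_decoded = if (n_correct + n_wrong > 0)
      n_wrong / (n_correct + n_wrong) else NA_real_,
    n_trials = n_trials,
    n_corrected_total = sum(res$n_corrected[res$decoded])
  ), class = "error_budget")
}

#' Estimate the per-round error probability from decoded traps
#'
#' The observed corrections among decoded traps, divided by the total number
#' of rounds in those traps. Because traps with two or more errors are mostly
#' excluded (unassigned), the estimator has a known downward bias: for C = 4
#' colours its expectation is approximately `p / (1 + 6 p)`.
#'
#' @param observed Integer matrix of observed words (one decoded trap per
#'   row), or `NULL` when `n_corrected` is supplied directly.
#' @param assigned Integer matrix of the assigned codewords, matching
#'   `observed` row for row.
#' @param n_corrected Alternative input: integer vector of corrections per
#'   decoded trap.
#' @param n_rounds Rounds per trap; taken from `observed` when given.
#' @return Estimated per-round error probability.
#' @export
estimate_round_error <- function(observed = NULL, assigned = NULL,
                                 n_corrected = NULL, n_rounds = NULL) {
  if (!is.null(observed)) {
    stopifnot(is.matrix(observed), is.matrix(assigned),
              all(dim(observed) == dim(assigned)))
    n_corrected <- rowSums(observed != assigned)
    n_rounds <- ncol(observed)
  }
  if (length(n_corrected) == 0L) stop("no decoded traps: estimate undefined")
  if (is.null(n_rounds)) stop("n_rounds required when passing n_corrected")
  sum(n_corrected) / (n_rounds * length(n_corrected))
}

#' Analytic upper bound on the wrong-genotype probability
#'
#' A trap can only be assigned the wrong genotype if at least two of its
#' rounds err (zero or one error always decodes to the truth when the minimum
#' distance is 3), so `p_wrong <= 1 - (1-p)^N - N p (1-p)^(N-1)`.
#'
#' @param p_round Per-round error probability.
#' @param n_rounds Number of rounds.
#' @return The bound.
#' @export
p_wrong_bound <- function(p_round, n_rounds = 7L) {
  1 - (1 - p_round)^n_rounds -
    n_rounds * p_round * (1 - p_round)^(n_rounds - 1L)
}

#' Write a codebook to JSON
#'
#' Keys are sorted for diffability; symbols are stored as 0-based arrays.
#'
#' @param codebook A [build_codebook()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codebook_json <- function(codebook, path) {
  codes <- codebook$codes[order(rownames(codebook$codes)), , drop = FALSE]
  obj <- list(
    spec = unclass(codebook$spec),
    codes = stats::setNames(
      lapply(seq_len(nrow(codes)), function(i) unname(codes[i, ])),
      rownames(codes)
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a codebook from JSON
#'
#' @param path Path written by [write_codebook_json()].
#' @return A `codebook` object.
#' @export
read_codebook_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(codebook_spec, as.list(obj$spec))
  codes <- do.call(rbind, obj$codes)
  storage.mode(codes) <- "integer"
  structure(list(codes = codes, spec = spec), class = "codebook")
}
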