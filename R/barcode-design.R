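#' Design parameters for barcode generation and selection
#'
#' Bundles the composition and distance constraints used to turn a pool of
#' random DNA k-mers into a set of mutually distant barcodes suitable for
#' chromosomal integration and padlock-probe detection.
#'
#' @param n_candidates Number of random candidate sequences to draw.
#' @param k Barcode length in nucleotides.
#' @param gc_min,gc_max Allowed GC-content range (fractions).
#' @param max_homopolymer Longest allowed single-base run, in nucleotides.
#' @param allowed_end_bases Bases allowed at both the 5' and 3' ends.
#'   The default `c("G", "C")` requires a G or a C at each end; set to `"G"`
#'   to require a G at both ends.
#' @param min_pairwise_hamming Minimum Hamming distance each retained barcode
#'   must have to every *other* sequence in the candidate pool. The default 8
#'   encodes a strict "distance greater than 7".
#' @param seed Integer seed for candidate generation.
#'
#' @return A list of class `design_params`.
#' @export
design_params <- function(n_candidates = 10000L, k = 30L,
                          gc_min = 0.40, gc_max = 0.60,
                          max_homopolymer = 3L,
                          allowed_end_bases = c("G", "C"),
                          min_pairwise_hamming = 8L,
                          seed = 1L) {
  stopifnot(
    n_candidates >= 1, k >= 1,
    gc_min >= 0, gc_min <= gc_max, gc_max <= 1,
    max_homopolymer >= 1, max_homopolymer <= k,
    min_pairwise_hamming <= k,
    all(allowed_end_bases %in% c("A", "C", "G", "T"))
  )
  structure(list(
    n_candidates = as.integer(n_candidates), k = as.integer(k),
    gc_min = gc_min, gc_max = gc_max,
    max_homopolymer = as.integer(max_homopolymer),
    allowed_end_bases = allowed_end_bases,
    min_pairwise_hamming = as.integer(min_pairwise_hamming),
    seed = as.integer(seed)
  ), class = "design_params")
}

#' GC fraction of a DNA sequence
#'
#' @param seq A character string over the alphabet A, C, G, T.
#' @return `(#G + #C) / nchar(seq)`.
#' @export
#' @examples
#' gc_fraction("ACGT")  # 0.5
gc_fraction <- function(seq) {
  chars <- .check_dna(seq)
  mean(chars == "G" | chars == "C")
}

#' Length of the longest homopolymer run
#'
#' @param seq A non-empty DNA string.
#' @return Length (nt) of the longest run of a single base.
#' @export
max_homopolymer_run <- function(seq) {
  chars <- .check_dna(seq)
  max(rle(chars)$lengths)
}

#' Hamming distance between two equal-length strings
#'
#' @param a,b Character strings of equal length.
#' @return Number of positions at which the strings differ.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("hamming() requires equal-length strings (", nchar(a), " vs ",
         nchar(b), ")")
  }
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

.check_dna <- function(seq) {
  if (length(seq) != 1L || !is.character(seq) || nchar(seq) == 0L) {
    stop("expected a single non-empty DNA string")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    stop("sequence contains non-ACGT characters: ", paste(bad, collapse = ", "))
  }
  chars
}

#' Generate random candidate barcode sequences
#'
#' Draws `n_candidates` i.i.d. sequences of length `k` with equal probability
#' of all four bases, reproducibly from `params$seed`.
#'
#' @param params A [design_params()] object.
#' @return Character vector of candidate sequences, named `cand0001`, ...
#' @export
generate_candidates <- function(params) {
  stopifnot(inherits(params, "design_params"))
  set.seed(params$seed)
  mat <- matrix(
    sample(c("A", "C", "G", "T"), params$n_candidates * params$k, replace = TRUE),
    nrow = params$n_candidates
  )
  seqs <- apply(mat, 1L, paste0, collapse = "")
  names(seqs) <- sprintf("cand%0*d", nchar(params$n_candidates), seq_along(seqs))
  seqs
}

#' Select barcodes from a candidate pool
#'
#' Applies the composition filters (GC content, homopolymer runs, end bases)
#' and the all-against-all distance rule: a candidate is retained only if its
#' Hamming distance to every *other* sequence in the input pool — not merely
#' in the output — is at least `params$min_pairwise_hamming`. Duplicated
#' sequences therefore eliminate each other (distance 0).
#'
#' @param candidates Character vector of equal-length DNA sequences.
#' @param params A [design_params()] object.
#' @return The retained subset of `candidates`, names preserved.
#' @export
select_barcodes <- function(candidates, params) {
  stopifnot(inherits(params, "design_params"))
  if (length(candidates) == 0L) return(character(0))
  k <- unique(nchar(candidates))
  if (length(k) != 1L) stop("all candidates must have the same length")

  chmat <- matrix(unlist(strsplit(candidates, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(candidates), byrow = TRUE)

  gc <- rowMeans(chmat == "G" | chmat == "C")
  hp <- vapply(seq_len(nrow(chmat)),
               function(i) max(rle(chmat[i, ])$lengths), integer(1))
  ends_ok <- chmat[, 1L] %in% params$allowed_end_bases &
    chmat[, k] %in% params$allowed_end_bases
  comp_ok <- gc >= params$gc_min & gc <= params$gc_max &
    hp <= params$max_homopolymer & ends_ok

  # all-against-all minimum distance over the full input pool
  dist_ok <- .min_cross_distance(chmat) >= params$min_pairwise_hamming
  candidates[comp_ok & dist_ok]
}

# For each row, the minimum Hamming distance to any other row.
# One-hot encoding turns Hamming distance into k - (match count), so a single
# matrix product gives all pairwise distances.
.min_cross_distance <- function(chmat) {
  n <- nrow(chmat)
  if (n == 1L) return(ncol(chmat))  # vacuously distant
  onehot <- do.call(cbind, lapply(c("A", "C", "G", "T"), function(b) {
    (chmat == b) * 1
  }))
  matches <- tcrossprod(onehot)
  d <- ncol(chmat) - matches
  diag(d) <- Inf
  apply(d, 1L, min)
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over A, C, G, T.
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  chars <- .check_dna(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste0(rev(unname(comp[chars])), collapse = "")
}

#' Design a padlock probe for a barcode target
#'
#' The target is reverse-complemented and split in half: the first half of the
#' reverse complement becomes the 5' hybridisation arm and the second half the
#' 3' arm (a documented convention; the two arms concatenated reconstruct the
#' full reverse complement). The scaffold — readout barcode, RCA priming site
#' and any accessory sequence — sits between the arms.
#'
#' @param target Even-length DNA string.
#' @param scaffold DNA string inserted between the arms (may be empty).
#' @return A list with `padlock`, `arm5`, `arm3`, `scaffold`, and 1-based
#'   `scaffold_start`/`scaffold_end` coordinates within the padlock (both 0
#'   when the scaffold is empty).
#' @export
design_padlock <- function(target, scaffold = "") {
  k <- nchar(target)
  if (k %% 2L != 0L) stop("target length must be even to split arms in half")
  if (nchar(scaffold) > 0L) .check_dna(scaffold)
  rc <- revcomp(target)
  arm5 <- substr(rc, 1L, k %/% 2L)
  arm3 <- substr(rc, k %/% 2L + 1L, k)
  list(
    padlock = paste0(arm5, scaffold, arm3),
    arm5 = arm5, arm3 = arm3, scaffold = scaffold,
    scaffold_start = if (nchar(scaffold)) k %/% 2L + 1L else 0L,
    scaffold_end = if (nchar(scaffold)) k %/% 2L + nchar(scaffold) else 0L
  )
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file path.
#' @param descriptions Optional per-sequence description strings appended to
#'   the header lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, descriptions = NULL) {
  x <- Biostrings::DNAStringSet(seqs)
  if (!is.null(descriptions)) names(x) <- paste(names(seqs), descriptions)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
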