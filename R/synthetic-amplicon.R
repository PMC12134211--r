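#' Generate synthetic amplicon-sequencing reads
#'
#' Each read embeds one barcode, sampled from `barcode_freqs`, between fixed
#' primer-derived flanks; random bases pad the read to `read_len`. Base
#' qualities are constant. The embedded counts are returned as ground truth.
#'
#' @param barcodes Named character vector of barcode sequences.
#' @param barcode_freqs Sampling probabilities (recycled to uniform when
#'   `NULL`); must sum to 1.
#' @param n_reads Number of reads to generate (> 0).
#' @param read_len Read length; must be at least
#'   `nchar(flank5) + barcode length + nchar(flank3)`.
#' @param flank5,flank3 Fixed flanking context around the barcode.
#' @param seed Integer seed.
#' @param path Optional FASTQ output path; reads are written when non-`NULL`.
#' @return A list with `reads` (named character vector), `truth_counts`
#'   (integer vector of embedded barcodes, named by barcode), and `path`.
#' @export
gen_amplicon <- function(barcodes, barcode_freqs = NULL, n_reads = 1000L,
                         read_len = 60L, flank5 = "CTCGGT", flank3 = "GCTAGC",
                         seed = 1L, path = NULL) {
  if (n_reads <= 0) stop("n_reads must be positive")
  blen <- unique(nchar(barcodes))
  stopifnot(length(blen) == 1L)
  core <- nchar(flank5) + blen + nchar(flank3)
  if (read_len < core) {
    stop("read_len must be at least ", core, " to hold flanks and barcode")
  }
  if (is.null(barcode_freqs)) {
    barcode_freqs <- rep(1 / length(barcodes), length(barcodes))
  }
  stopifnot(length(barcode_freqs) == length(barcodes),
            abs(sum(barcode_freqs) - 1) < 1e-9)
  if (is.null(names(barcodes))) {
    names(barcodes) <- sprintf("bc%03d", seq_along(barcodes))
  }
  set.seed(seed)

  pick <- sample.int(length(barcodes), n_reads, replace = TRUE,
                     prob = barcode_freqs)
  pad_n <- read_len - core
  pad <- if (pad_n > 0) {
    apply(matrix(sample(c("A", "C", "G", "T"), n_reads * pad_n,
                        replace = TRUE), n_reads), 1L, paste0, collapse = "")
  } else rep("", n_reads)
  reads <- paste0(flank5, unname(barcodes[pick]), flank3, pad)
  names(reads) <- sprintf("read%0*d", nchar(n_reads), seq_len(n_reads))

  truth_counts <- tabulate(pick, nbins = length(barcodes))
  names(truth_counts) <- names(barcodes)

  if (!is.null(path)) {
    x <- Biostrings::DNAStringSet(reads)
    qual <- Biostrings::PhredQuality(
      vapply(reads, function(r) strrep("I", nchar(r)), character(1))
    )
    qx <- Biostrings::QualityScaledDNAStringSet(x, qual)
    Biostrings::writeQualityScaledXStringSet(qx, filepath = path)
  }
  list(reads = reads, truth_counts = truth_counts, path = path)
}
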