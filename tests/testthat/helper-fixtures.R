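# Shared fixtures, built in code at load time.

# small default codebook reused across tests (85 codes, 7 rounds, 4 colours)
fixture_codebook <- function(seed = 7L) {
  build_codebook(codebook_spec(seed = seed))
}

# three-strain kinetics table: fast single-exp, slow single-exp, bleaching
fixture_strains <- function() {
  data.frame(
    strain = c("fastFP", "slowFP", "bleachFP"),
    c = c(100, 50, 80),
    alpha = c(2, 1, 3),
    tau_m = c(15, 60, 40),
    tau_b = c(NA, NA, 250),
    stringsAsFactors = FALSE
  )
}

# brute-force barcode filter: the O(n^2 k) oracle for select_barcodes
oracle_select <- function(candidates, params) {
  n <- length(candidates)
  keep <- logical(n)
  for (i in seq_len(n)) {
    s <- candidates[i]
    ok <- gc_fraction(s) >= params$gc_min && gc_fraction(s) <= params$gc_max &&
      max_homopolymer_run(s) <= params$max_homopolymer &&
      substr(s, 1, 1) %in% params$allowed_end_bases &&
      substr(s, nchar(s), nchar(s)) %in% params$allowed_end_bases
    if (ok) {
      for (j in seq_len(n)) {
        if (j == i) next
        if (hamming(s, candidates[j]) < params$min_pairwise_hamming) {
          ok <- FALSE
          break
        }
      }
    }
    keep[i] <- ok
  }
  candidates[keep]
}
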