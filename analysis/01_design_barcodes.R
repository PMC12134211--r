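#!/usr/bin/env Rscript
# Barcode design: draw 10,000 random 30-mers, filter on composition
# (40-60% GC, homopolymers < 4 nt, G/C at both ends) and mutual Hamming
# distance > 7 over the whole pool, then derive padlock hybridisation arms
# for the first 85 survivors.

suppressMessages(library(optipool))
dir.create("results", showWarnings = FALSE)

params <- design_params(n_candidates = 10000L, k = 30L, seed = 20260924L)
candidates <- generate_candidates(params)
selected <- select_barcodes(candidates, params)

cat(sprintf("candidates: %d; survivors after all filters: %d (%.1f%%)\n",
            length(candidates), length(selected),
            100 * length(selected) / length(candidates)))

write_fasta(selected, "results/selected_barcodes.fasta")

# the G-at-both-ends subset used when hand-picking sequences for integration
g_ends <- selected[substr(selected, 1, 1) == "G" &
                     substr(selected, 30, 30) == "G"]
cat(sprintf("survivors with G at both ends: %d\n", length(g_ends)))

# padlock probes for the library-sized subset: reverse-complement arms with a
# placeholder scaffold carrying the readout/RCA-priming insert
library_bcs <- selected[seq_len(min(85L, length(selected)))]
scaffold <- "TCCTATTCGGATACCTGATGCTCCTCGTTAGG"
padlocks <- vapply(library_bcs, function(b) design_padlock(b, scaffold)$padlock,
                   character(1))
names(padlocks) <- sprintf("plp%03d", seq_along(padlocks))
write_fasta(padlocks, "results/padlocks.fasta",
            descriptions = sprintf("arms=1-15,%d-%d scaffold=16-%d",
                                   16 + nchar(scaffold),
                                   30 + nchar(scaffold),
                                   15 + nchar(scaffold)))
cat(sprintf("wrote %d padlocks (%d nt each) to results/padlocks.fasta\n",
            length(padlocks), unique(nchar(padlocks))))
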