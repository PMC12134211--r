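---
title: "Decoding and maturation kinetics in pooled optical screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and maturation kinetics in pooled optical screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optipool)
```

## The problem

A pooled optical screen grows a library of chromosomally barcoded *E. coli*
strains together in a mother-machine microfluidic chip, one strain lineage
per dead-end trap. Each strain carries a 30-nt DNA barcode that is read out
*in situ*: padlock probes hybridise to the transcribed barcode, are ligated
and amplified by rolling-circle amplification, and over seven sequential
hybridisation rounds the amplicon lights up in one of four detection
colours per round. The colour sequence — the trap's codeword — identifies
the genotype. The same chip then measures a phenotype per trap; here,
fluorescent-protein maturation kinetics after a chloramphenicol chase.

`optipool` implements the complete computational side of such a screen:
barcode and padlock design, error-correcting codebook construction and
decoding, signal-to-colour-word calling, lineage-level fluorescence
phenotyping, maturation-time fitting, and density-based phenotype outlier
detection. Because the microscopy data itself is not required for any of
this logic, a seeded synthetic-data generator produces every input the
pipeline consumes, with full ground truth, and the test suite runs the
pipeline against that truth.

## Barcode design

Candidate barcodes are i.i.d. uniform random 30-mers. Selection applies,
at the selection stage, composition filters (GC content in [0.40, 0.60],
homopolymer runs shorter than 4 nt, a G or C at both ends) and a mutual
distinguishability rule: a candidate survives only if its Hamming distance
to **every other candidate in the pool** is at least 8 ("greater than 7").
Applying the distance rule against the whole pool, not just the survivors,
is deliberate: two near-identical candidates eliminate each other, which
is the conservative reading and makes selection idempotent on its own
output. With all filters at selection, roughly 15% of 10,000 random
30-mers survive. The literature pipeline this mirrors reports a smaller
survivor list; since the expected survivor count under either placement of
the composition filters differs from that report, the survivor count is
not used as a validation target — the brute-force filter equivalence on
small pools is.

Padlock arms: the target is reverse-complemented and split in half; the
first half of the reverse complement is taken as the 5′ hybridisation arm
(a convention — orientation is not dictated by the chemistry description),
and the scaffold (readout barcode, RCA priming site, accessory sequence)
sits between the arms.

## Codebook and error correction

Each strain receives a codeword of 7 symbols over a 4-colour alphabet.
Codewords are drawn uniformly at random and accepted only if they keep
Hamming distance ≥ 3 to every accepted word (rejection sampling, seeded,
bounded at $10^6$ rejections). Minimum distance 3 makes single-error
correction sound: an observed word is decoded iff it matches a codeword
exactly or lies at distance 1 from exactly one codeword; any missing
symbol, or distance ≥ 2 from all codewords, leaves the trap unassigned.

With independent per-round symbol errors at rate $p$, a trap decodes to
the **wrong** genotype only if at least two rounds err, so

$$p_\text{wrong} \le 1 - (1-p)^7 - 7p(1-p)^6,$$

about 0.0267 at $p = 0.038$. The realised wrong-genotype probability of a
random minimum-distance-3 codebook is far below the bound (most ≥2-error
words land nowhere near a different codeword): Monte Carlo at $p = 0.038$
gives ≈ 0.002 per trap. This value is a property of the codebook
*ensemble*; individual random codebooks of identical spec scatter mildly
around it, which is why the package treats it as a characteristic value
rather than a constant.

The per-round error rate is estimated in reverse from decoded traps:
corrections counted by the error-correcting decoder, divided by total
rounds in those traps. Conditioning on traps whose errors were fully
corrected (0 or 1 error) biases this estimator downward to
$p(1-p)^6 / \left[(1-p)^7 + 7p(1-p)^6\right] = p/(1+6p)$ — about 0.031 at
$p = 0.038$. Tests assert the estimator against this closed form on trials
decoded back to the true codeword, which is exactly the population the
closed form describes; traps decoded to a wrong codeword (order $10^{-3}$
of trials) are excluded there because they contaminate the estimate by an
amount comparable to the Monte-Carlo tolerance without being part of the
derivation.

## Signal calling

Trap signals arrive either as per-trap/round/channel totals ("table mode")
or as pixel tiles ("image mode"); both feed the same decoder.

In image mode, the background is a Gaussian fitted by least squares to the
binned intensity histogram pooled over traps — least squares on the
histogram, rather than moments, so the bright-blob right tail (few pixels,
many grey levels) barely moves the fit; a median/MAD fallback guards
degenerate fits. Blob masks are pixels above $\mu + 5\sigma$; the
consensus mask keeps pixels present in at least half the rounds (≥ 4 of
7); per round, a channel is void unless it has ≥ 4 above-threshold pixels
(configurable; the source pipeline states an area threshold without a
value), and among surviving channels one is called only when its total
intensity is at least twice every competitor's, otherwise the round is
ambiguous.

Trap categories are made mutually exclusive with a fixed precedence:
all-rounds-silent → `no_signal`; any ambiguous round → `double_signal`;
any silent round (incomplete word) → `unassigned`; otherwise the decode
outcome (`decoded` / `unassigned`). The source material does not define an
ordering and its published category counts do not sum to trap totals, so
exclusivity-by-precedence is this package's own, documented resolution.

## Phenotyping and maturation kinetics

Per cell, fluorescence is the background-subtracted pixel sum over the
segmented outline; per lineage and frame, areas and fluorescence are
summed over all living descendants of the founder. Lineages must exist at
the swap to chloramphenicol (t = 0) and be tracked to the end of
acquisition. Bleed-through from bright neighbours is handled by exclusion:
a lineage is kept only if its in-cell intensity density is on average
≥ 3-fold its immediate surroundings (boundary inclusive; zero surroundings
with signal counts as clean). The ratio is averaged over all frames — the
source is silent on pre- versus post-swap averaging, and all-frames is the
default.

After the swap, translation stops and only maturation (and possibly
photobleaching) changes total fluorescence:

- plateauing signal: $F(t) = c\,(\alpha + 1 - \alpha e^{-t/\tau_m})$;
- clearly decaying signal:
  $F(t) = c\left[\tfrac{\tau_b}{\tau_b-\tau_m}(\alpha+1)e^{-t/\tau_b}
  - \alpha\tfrac{\tau_b}{\tau_b-\tau_m}e^{-t/\tau_m}\right]$,
  with $\tau_b > \tau_m$ the bleaching time.

Model choice: the mean over lineages of end-point/peak fluorescence
(end point = mean of the last two samples, for noise robustness) is
compared against 0.85 — strictly below means the signal bleached by more
than 15% and selects the double model. The source's Methods sentence
states the inverted ratio; its Results wording ("bleached by more than
15%") fixes the intent, and end/peak < 0.85 is what is implemented.

Fitting is Levenberg–Marquardt least squares with bounds $c>0$,
$\alpha\ge 0$, $\tau_m>0$ and, through the parameterisation
$\tau_b = \tau_m + \Delta$, $\tau_b > \tau_m$ (resolving the two-exponential
label-swap ambiguity; bleaching is slower than maturation in every case
this models). Initialisation: $c_0 = F(0)$ clamped positive,
$\alpha_0 = \max(F_\text{end}/F_0 - 1,\, 0.1)$, $\tau_{m,0}$ = time of
half rise, $\tau_{b,0} = 2\,t_\text{acq}$; because this start can sit on a
singular Jacobian for strongly bleached curves, a small fixed set of
fallback starts is tried and the lowest-residual convergent fit kept.
Fits with $\hat\tau_m$ beyond the acquisition window (default 300 min)
are censored and reported as "> 300 min". Non-convergence is a flagged
result, not an error.

Per FP and replicate, the primary estimate is the fit of the
lineage-averaged curve (per-lineage fits are also produced, feeding the
scatter outputs and the outlier module); replicates qualify only with
more than 4 decoded traps and more than 5 lineages; the across-replicate
mean is reported, with a SEM only when three replicates qualify. Whether
the per-replicate value should be the averaged-curve fit or the average
of per-lineage fits is genuinely open; averaged-curve is primary here
because it is the quantity the replicate-level displays correspond to,
and it is far more robust at realistic noise (per-lineage fits of slow
maturers at 5% noise carry tens of percent of error; the averaged curve
at 100 lineages recovers $\tau_m$ to a few percent across
$\tau_m \in \{15, 60, 180\}$ min, $\alpha \in \{0.5, 2\}$).

## Outlier detection

Per FP, the per-lineage points (maturation time, pre-swap fluorescence —
mean of the last three pre-swap frames) are pooled across replicates and
clustered with DBSCAN. No R DBSCAN was available to build on, so the
package carries a small, exact implementation of the classic algorithm
(core/border/noise, $O(n^2)$ distances — phenotype tables are small); it
reproduces a reference implementation on a frozen fixture. The largest
cluster is the major cluster; a trap counts only with more than 2
lineages, all unanimously inside or outside the major cluster; an FP is
reported only when the major cluster holds more than 5 traps; the
deviating fraction is deviating/(deviating + major). The source names
neither $\varepsilon$, minPts, nor the axis scaling; defaults here are
standardised axes (minutes and arbitrary units are incomparable),
$\varepsilon = 0.5$, minPts = 5, all configurable.

## The synthetic generator

The generator's defaults encode the study conditions: 4000 traps, 85
barcodes, 7 rounds × 4 colours, per-round error 0.038, occupancy 0.9,
with 5% no-signal and 3% double-signal traps (the latter two are plumbing
rates, chosen once at realistic magnitudes — a few percent — since the
source gives counts only for its specific chips). Genotyping corruption
replaces a round's colour by a uniformly chosen different colour,
independently across rounds, matching the uncorrelated-errors assumption
of the error model. Double-signal traps render two equal-intensity
colours in every round, so the dominance rule can never rescue them and
their ground-truth category is exact — marginal, rescuable double signals
are deliberately *not* emulated, keeping generator bookkeeping and
decoder output comparable one-to-one. In image mode the blob sits at one
position per trap across rounds (it is one rolling-circle amplicon being
re-probed), on Gaussian background with a lognormal peak-intensity spread
(σ = 0.3) around the configured scale.

Phenotype lineages grow exponentially (30-min doubling) with symmetric
division on doubling; after the swap the growth rate decays exponentially
(20-min time constant) to a stop. Measurement noise is added to the
lineage total and partitioned among descendants proportionally to area,
so lineage totals conserve mass exactly at divisions — by construction,
which is what lets aggregation tests assert exact reconstruction.
Pre-swap fluorescence sits at the model's t = 0 value (continuity at the
swap; for the double model that is $c\,\tau_b/(\tau_b-\tau_m)$, not $c$).
Bleed-through adds a configurable fraction of the two linear neighbours'
mean density to a trap's surroundings. The generator does not emulate
segmentation or tracking errors, phase-contrast imagery, or correlated /
channel-asymmetric decode errors — passing tests therefore demonstrate
correctness of the decoding and fitting logic under the stated error
model, not robustness to upstream image-analysis failure modes.

Amplicon reads embed one barcode each between fixed flanks with random
padding; counting is exact substring matching (forward-only by default,
reverse complement by flag — the source does not state its orientation
handling), with zero- and multi-match reads tallied separately.

## Problem sizes and numerical choices

The test suite and acceptance analyses use $10^6$ Monte-Carlo trials for
the misassignment probability, $10^5$ traps for end-to-end decode
fractions, 200 lineages for noisy-fit medians, and 200-candidate pools
for brute-force filter equivalence — sizes at which the 3-standard-error
tolerances used throughout are meaningful while a full run stays in the
minutes range on one core. Seeds are explicit everywhere; identical
configs reproduce byte-identical outputs. Probabilities in the error
budget are exact count ratios and sum to one by construction.

Known limitations: the codebook's ~0.002 wrong-assignment probability is
an ensemble property (realisations vary by tens of percent); category
exclusivity is this package's resolution of an under-specified
classification; the growth model is deliberately minimal (no size
regulation beyond doubling, no asymmetric division); and maturation is
modelled as a single-step reaction, as in the models fitted.
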