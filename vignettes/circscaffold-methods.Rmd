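---
title: "Models and methods behind circscaffold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind circscaffold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circscaffold)
```

`circscaffold` analyses the determinants of inverted-Alu-mediated
backsplicing from two directions: genome-wide annotation statistics
(which exons circularize, and how are they flanked?) and chemical
structure probing of a single pre-mRNA construct (are the flanking Alu
elements actually paired, and to each other?). This vignette explains the
models, the tunable parameters and their defaults, what the synthetic
data emulate, and the numerical choices, in enough detail that any result
the package produces can be traced to a decision documented here.

## Flanking-Alu classification

Coordinates are 0-based half-open everywhere (BED-native); the
RepeatMasker reader converts its 1-based inclusive coordinates at the
boundary. An Alu qualifies as flanking an exon when it lies on the same
chromosome, does not overlap the exon, the gap between the closest
boundaries is at most `window` nucleotides (default **2000 nt**; 0 for
abutting features), and its length is at least `min_full_length`. Sides
are assigned in transcript orientation: upstream of a `+` exon means
lower genomic coordinates, upstream of a `-` exon means higher ones;
unstranded (`.`) exons are treated as `+`.

Three choices here were genuinely open and are worth stating:

- **"Full length"** is not a standard constant. The default
  `min_full_length = 250` nt admits near-complete ~300-nt Alu elements
  while rejecting heavily truncated fragments; it is a plain argument on
  every entry point, and the length-distribution analysis
  (`downstream_alu_lengths()`) bypasses it entirely, since the question
  there *is* the length distribution.
- **Pattern assignment with Alus on both sides.** An exon is `IR` when
  *any* upstream/downstream pair lies on opposite genomic strands — the
  most permissive reading, since one complementary pair suffices to form
  the inverted-repeat duplex. Both sides occupied but all pairs
  same-strand is a configuration the four classical categories do not
  cover; it gets its own `OTHER` label and is tabulated separately rather
  than folded silently into a neighbouring class.
- **Circularization labels** come from intersecting exons with
  *single-exon* circRNA records only (`block_count == 1`), any-overlap,
  strand-blind by default because circRNA databases and gene annotations
  do not reliably agree on strand conventions; `strict_strand = TRUE` is
  available.

The genome-wide classifier (`classify_exons()`) uses interval-index
overlap (GenomicRanges) of each Alu's exon-facing edge against the exon's
side window; the test suite holds it to 100% agreement with a naive
all-pairs scan, and to invariance under reflecting all coordinates and
flipping all strands.

## Enrichment model

For pattern *p* with `c_p` circularizing and `n_p` non-circularizing
exons, the report is the difference in log odds against a baseline
pattern (default `NONE`):

$$\Delta_p = \ln\frac{c_p}{n_p} - \ln\frac{c_b}{n_b}$$

Natural log throughout. When any of the four cells is zero, 0.5 is added
to all four at once (Haldane–Anscombe); otherwise counts are untouched.
Uncertainty comes from case resampling over exons. Because the statistic
depends on an exon only through its (pattern, circularizing) cell,
resampling n exons with replacement is *exactly* a multinomial redraw of
the ten contingency cells, which is how `bootstrap_log_odds()` implements
it (B = 1000 by default, seed mandatory, percentile intervals). Degenerate
replicates are recomputed with the pseudo-count, never dropped.

The Mann–Whitney U statistic counts pairs with `x > y` plus 0.5 per tie;
the exact two-sided p enumerates all C(n+m, n) group assignments when
n+m ≤ 12, otherwise a tie-corrected normal approximation with continuity
correction is used. Two distinct uses must not be conflated. Comparing
two *bootstrap distributions* of log-odds (the `mwu_p_vs_baseline` column
of `enrichment_table()`) is a descriptive contrast of resampled estimates
of two fixed quantities — it will reject for any real difference in point
estimates, and it is not a calibrated hypothesis test. The calibrated use
is on independent units, e.g. downstream-Alu lengths of circularizing vs
non-circularizing exons; that is the comparison whose type-I rate the
acceptance checks verify (~5% nominal under the null genome, observed
within [2%, 9%] over 200 simulated genomes).

## Synthetic genome

`gen_genome_annotations()` plants each exon's flank pattern
*geometrically* — concrete Alu coordinates obeying the window, length and
strand rules, one qualifying Alu per occupied side — so the interval
logic is exercised, not just the counting. Exons live in well-separated
slots (slot width > 2·(window + max gap + max Alu) so assignments cannot
leak between neighbours). Labels follow a logistic model:
P(circularize) = logistic(β₀ + β₁·[pattern = IR]), so the IR-vs-NONE log
odds difference equals β₁ by construction and effect recovery is exact in
expectation.

Defaults, chosen once as field-realistic and not revisited: Alu length
N(300, 20) truncated at `min_full_length` (the Alu consensus is ~300 nt),
gaps uniform in 50–1500 nt, pattern mix {NONE 0.40, IR 0.20, 5′-only
0.15, 3′-only 0.15, OTHER 0.10}, β₀ = −2.2 (circularizing exons a clear
minority, ~10% at baseline). Decoy features keep the filters honest: 10%
of exons get a sub-threshold short Alu (must not change any pattern), and
2% get an overlapping two-exon circRNA record (must be discarded by the
single-exon rule). What this generator does *not* emulate: clustered and
nested real Alu arrangements, shared flanks between neighbouring exons,
chromosome-scale heterogeneity, and any sequence content. Passing tests
demonstrate the statistics and interval logic are correct, not that real
GENCODE/RepeatMasker/circBase data are free of convention mismatches.

## Reactivity processing

Raw reactivity is (modified − untreated) mutation rate; positions with
effective depth below `min_depth` (default 1000 reads, configurable — the
conventional cutoff) in either channel are invalid. Undefined values stay
explicit (`NA` + mask), never zeros. Normalization is per nucleotide type
(A, C, G, U independently): values above Q3 + 1.5·IQR are set aside,
every value of the type is divided by the mean of the top decile of the
rest, and afterwards anything below −0.1 is set to −0.1 — a
treated-minus-untreated value below zero means fewer mutations with
reagent than without, which carries no structural signal and is
functionally zero. The floor comes after scaling; the normalized
top-decile mean is exactly 1 per type (asserted to 1e-9), and rescaling
all raw values of one type by any c > 0 leaves its normalized profile
unchanged. Types with fewer than 20 defined values are left unscaled with
a warning. DMS chemistry is restricted to adenosine and cytidine:
`apply_dms_mask()` invalidates G/U and lowercase (pre-masked) positions,
idempotently.

The windowed profile difference (`delta_shape()`) smooths both profiles
with a centered mean (window 3 nt), standardizes the difference, and
screens sites by a Z-factor 1 − 1.96·(se₁+se₂)/|d|; a site is significant
when the Z-factor is positive and |standard score| ≥ 1. Window and both
thresholds are exposed; the defaults are the cited convention for this
statistic. Windows touching an invalid position yield undefined
differences rather than silently shrinking.

The reactivity simulator draws one latent rate per position (exponential,
mean 0.005 paired / 0.05 unpaired — a ~10-fold contrast typical of
structured vs flexible nucleotides) and lets replicates observe it under
multiplicative lognormal noise (sdlog 0.1) plus exponential background
(mean 0.001). Replicate correlation therefore rises toward 1 as the noise
terms shrink. It does not emulate sequence-dependent reagent bias,
RT drop-off, or the denatured-control three-sample scheme.

## SHAPE-JuMP quantification

A JuMP event is a deletion (start, stop, count, depth) left by a
processive reverse transcriptase traversing a crosslink. Frequency is
count/depth with depth taken from the input per event (the upstream
aligner's definition, deliberately not recomputed). Events with
count < 20 are removed *before* anything else — a low count over a low
depth fakes a high frequency — and the boundary is sharp: 19 is dropped,
20 kept. Background subtraction matches treated and untreated events on
exact (start, stop) (±k-nt fuzzy matching available, off by default),
with missing untreated partners contributing 0. Negative differences are
kept in tabular output but clipped at zero for ranks and densities, where
only signal above background is meaningful. The triangular density bins
each event by midpoint and separation (bin 10 nt), so long-range contacts
sit at the apex; total matrix mass equals the clipped difference sum by
construction.

Deletion-mutant coordinates are lifted to the reference frame by adding
the total deleted length upstream of each position; the map is strictly
increasing, round-trips exactly, and is tested against a character-level
alignment oracle. The inverse map is undefined inside deleted intervals.
Replicates are combined by summing counts and depths before frequencies
(an averaging mode exists), so an event can clear the count filter only
jointly — the conservative direction.

The JuMP simulator plants contacts at Binomial(depth, 0.02) over shared
background pairs at Binomial(depth, 0.002), depth 5000, so planted events
expect 100 counts (comfortably past the filter) and background expects 10
(mostly filtered); untreated sees background only. Jitter defaults to 0
so the planted (start, stop) truth is exactly recoverable.

## Structure metrics and qPCR

Percent paired for a region is the percentage of its nucleotides paired
to *any* partner, inside the region or not; cross-region pairing is the
separate `inter_region_pair_fraction()`. CT parsing validates the pair
table as an involution with no self-pairs and accepts pseudoknots;
dot-bracket emission assigns pairs greedily to `()`, `[]`, `{}` tiers and
errors beyond three tiers.

Relative expression is 2^(−ΔCt) with first-order propagation
sd = ln 2 · value · sd(ΔCt); efficiency is the circ/pre ratio with
relative errors added in quadrature. A Monte-Carlo validator quantifies
the linearization: treating each target's ΔCt as an independently
measured quantity, the delta-method sd stays within 10% of the empirical
sd for ΔCt uncertainties up to 0.3 cycles. Beyond that the lognormal
curvature dominates (at four independent 0.3-cycle error sources the gap
is ~17%), which is exactly the regime the validator exists to expose.
Undetected circles (no-amplification sentinel) report efficiency 0 with a
`detected = FALSE` flag rather than being omitted.

## Problem sizes and limitations

The analysis drivers and acceptance checks run at 20,000 simulated exons
(100 seeds for effect recovery), 200 null genomes of 2,000 exons for
Mann–Whitney calibration, 100 seeds of 10 planted JuMP contacts, 100
reactivity simulations over a 420-nt construct, and 1,000 random
structures — sizes chosen so the full suite completes in minutes on one
core while keeping Monte-Carlo error well inside the asserted bounds.

Known limitations: no genome-assembly liftover (inputs must share an
assembly); folding itself is consumed as CT/dot-bracket/probability files
from external tools, never computed; the enrichment bootstrap treats
exons as exchangeable (no gene- or chromosome-level clustering); and the
reproduction of the reference construct's ~85% Alu pairing requires the
deposited structure files, which do not ship with the package — the
corresponding check states this explicitly rather than substituting a
synthetic stand-in.
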