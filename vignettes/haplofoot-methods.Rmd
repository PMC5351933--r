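---
title: "Methods: haplotype overlap with DNase-seq footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype overlap with DNase-seq footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question the pipeline answers

Sentinel variants from eQTL and GWAS studies tag haplotypes, not causal
bases. If the causal mechanism is disruption of a transcription-factor
binding site, then at least one variant in strong LD with the sentinel
should sit inside a DNase-seq footprint. `haplofoot` measures how often
that happens — the overlap proportion ∏ — and whether it happens more often
than chance placement within open chromatin would produce.

This vignette explains the models and procedures, the tunable parameters,
what the synthetic data emulate (and do not), and the numerical choices a
maintainer would want documented.

# Models and procedures

## LD expansion

r² between two biallelic variants is computed directly from phased
haplotype columns as the squared correlation of binary ALT indicators,
equivalently `(p_AB − p_A p_B)² / (p_A(1−p_A) p_B(1−p_B))`. There is no EM
step for unphased genotypes: the input is a phased panel by contract.
Monomorphic variants have undefined LD; they are reported as `NA` and
excluded from blocks (deliberately distinct from r² = 0, matching the
behaviour of standard LD tools that emit no record for such pairs).

A haplotype block is the sentinel plus all same-chromosome panel variants
within `window_bp` (default 10 Mb) at r² **≥** the threshold. The boundary
is inclusive because the convention is unstated in common usage; it is a
single exposed parameter, and block membership is nested across thresholds
by construction, which is what makes ∏ provably non-increasing along the
r² grid.

Sentinels sharing linked SNVs are kept as separate blocks, and duplicate
sentinels (one variant reported for two traits) stay distinct: ∏'s
denominator is per reported association, so merging would silently change
it.

## The overlap proportion ∏

A block is a "hit" for annotation layer A when any member's 1-bp interval
(variant positions are converted once, on read, from 1-based to 0-based
half-open) overlaps A by ≥ 1 bp. No weighting by the number of hitting
SNVs or their r²: the statistic is deliberately binary, because the
question is whether the haplotype *can* be explained, not how often. For
the footprint∩motif layer the SNV must lie in the intersection interval of
footprint and motif (the stricter of the two plausible readings; the layer
is constructed with `intersect_intervals()`, so relaxing it means passing
the union of the two sets instead).

The conditional variant (`conditional_pi()`) restricts one block set to
blocks sharing at least one member id with another block set — e.g. GWAS
haplotypes that contain an eQTL SNV — before evaluating ∏ on the subset.

## Workspace-constrained permutation enrichment

The null model re-places each query segment independently within a
workspace: a containing-capable segment is chosen with probability
proportional to `segment_length − item_length + 1`, then a uniform offset.
This makes every base-pair placement of the item equally likely across the
whole workspace, which is the exchangeability the type-I calibration test
relies on. The statistic is the count of query segments overlapping the
annotation (a bp-overlap mode is available; segment counting is the
default because ∏ and haplotype hits are counted the same way). Empirical
p-values use the add-one estimator `(#{null ≥ obs} + 1)/(n + 1)`, which can
never be 0; fold is observed over null mean. Stratified shuffling (each
query confined to workspace segments sharing its origin segment's label)
generalises GC-isochore correction to arbitrary strata; a helper assigns
1-Mb-bin quintile labels from a supplied GC track. With a constant label
the stratified run reproduces the unstratified one exactly at the same
seed.

Defaults: n = 10,000 randomisations in the pipeline configuration; the
test suite and acceptance script use 499–2,000 so the whole suite runs in
minutes on one CPU — the statistical checks (type-I calibration in
[0.02, 0.09] at α = 0.05; ±20% fold recovery) are sized for those n.

## Footprint QC

Filters are idempotent and order-commuting except the score-centile
threshold, whose cutoff depends on the current set; the pipeline applies
it last. The artefact filter reads "skew of the mean DNase profile by
> 50% within 100 bp of the footprint centre" as *single-position
dominance*: over the window centre ± 100 bp, remove the footprint iff
`max(values)/sum(values) > 0.5`. This targets the PCR/alignment spike
artefacts such filters exist for. An all-zero window is kept with ratio 0.
The centre of an even-length footprint is `start + floor(length/2)` —
stated once, used everywhere. An alternative left/right half-window
imbalance reading exists; the spike reading was chosen because it is the
one the planted-artefact recovery can verify unambiguously, and the window
and threshold are both exposed (`half_window_bp`, `skew_threshold`).

## Conservation-based calibration

TFs are classified from an RPKM expression matrix: *highly expressed*
(> 10 in every sample), *undetectable* (0 in every sample), *expressed*
(≥ 1 somewhere). The TP:FP proxy ratio for a footprint set is

    [frac. overlapping conserved highly-expressed-TF motifs / bp(hi track)]
  ÷ [frac. overlapping undetectable-TF motifs            / bp(und track)]

where "conserved" means Δlog conservation > 0.1 within the motif versus
its two abutting 50-bp flanks, evaluated per occurrence (not averaged per
TF — occurrences of one TF differ, and the per-occurrence gate is the one
the planted signal can validate). The conservation gate applies only to
the numerator: the expressed class is the true-positive proxy and
conservation is part of that proxy, while the undetectable side is the
false-positive yardstick and gating it would remove the very overlaps it
is meant to count. "Scaled for the size of motif tracks" is read as per-bp
density (divide by total motif-track bp) — the only scale-free reading
that makes the two classes comparable. The chosen threshold is the
smallest centile of the grid (default 0, 5, …, 95) whose ratio reaches 2.

## PWM scanning and disruption

Match p-values are exact under a 0-order background: the log₂-odds matrix
is discretised to 1e-3 bins and the full score distribution of a
background-drawn k-mer is built by convolution; the threshold is the
smallest achievable score with tail probability ≤ p. A 0-order background
(rather than 1st-order Markov) keeps the p-values exactly enumerable —
the test suite verifies the DP against exhaustive 4^k enumeration — at the
cost of realism on repeat-rich sequence; scanning skips masked (lowercase)
and ambiguous bases anyway, and 1st-order scanning is out of scope. When
even the maximal score has tail > p (short motifs at stringent p), the
threshold returns max + one bin with a warning: no window matches, which
is exactly what a stringent scanner reports. At p = 1 the minimum
achievable score is returned.

A variant is *disruptive* for a hit when substituting the alternate base
flips match status at the threshold in either direction — loss or gain;
gains are biologically meaningful and the two are not distinguished
downstream. The disruption test statistic is the fraction of
footprint-contained SNVs disruptive to ≥ 1 overlapping hit; its null
re-places footprints within DHS (1,000×, add-one p). Disruption status per
SNV is a fixed property of the hit set, so shuffling footprints only
changes the conditioning set — which is the point: it asks whether
footprints specifically concentrate disruptive variants.

# The synthetic-data generator

The generator is the study-conditions module, not a test fixture. For a
fixed seed the dataset is bit-identical across runs. It emulates:

* **Genome geometry** — abstract chromosomes (default 2 × 1 Mb); DHS
  placed without overlap (default 500 of 200–500 bp, the scale of real
  hypersensitivity sites); at most one footprint per DHS at probability
  0.25 (≈ the ~24% of DHS observed to contain a detectable footprint),
  11–22 bp wide.
* **LD structure** — panel SNVs share a Bernoulli(½) ancestral column per
  `ld_block_length_bp` window, each copied with independent flip
  probability ε = (1 − r²_target^¼)/2, giving expected pairwise
  r² = (1−2ε)⁴ = the target. Analytically tunable, no coalescent
  machinery; consequently LD does not decay with distance within a block
  and is ~0 between blocks, a deliberate simplification.
* **Planted sentinel enrichment** — sentinels are placed uniformly over
  DHS base pairs; with probability α = q(φ−1)/(1−q) (q = footprint bp /
  DHS bp, φ = `planted_fold`) a sentinel is forced into footprint
  territory instead (for φ < 1, forced out with probability 1 − φ), so the
  realized in-footprint rate is exactly φq in expectation and the truth
  record stores both q and the realized fold. Uniform-over-bp placement
  matches the shuffling null exactly, making null datasets exchangeable by
  construction.
* **Motifs, conservation, expression** — sharply informative PWMs (one
  0.85-probability base per position, length 8 by default: long enough
  that the 10⁻⁴ match threshold is achievable). High-scoring ("true")
  footprints carry a motif of a highly expressed TF; half of the
  low-scoring footprints carry an undetectable-TF motif; surplus
  expressed-TF occurrences land in DHS territory clear of footprints.
  Conservation is Gaussian noise (sd 0.3) over DHS neighbourhoods plus
  `conservation_signal` (default 0.5) added across every expressed-TF
  occurrence. Footprint scores are uniform on (50, 100) for true and
  (0, 50) for false footprints, so the score boundary sits at the ~50th
  centile, and the surplus outside-footprint expressed motifs keep the
  TP:FP ratio below 2 beneath the boundary: the ratio for centile c below
  the boundary is ≈ (B/(B−c)) · N_false/(N_true + N_extra), which stays
  < 2 until just under B and jumps above it there — that is the planted
  boundary the calibration must recover.
* **Cut profiles and artefacts** — Poisson(1) cut counts over DHS
  neighbourhoods; each footprint is an artefact with probability
  `artefact_spike_prob`, in which case one position within ±100 bp of its
  centre is set to 10× the window's background total. The spike is scaled
  to the window total (rather than multiplying a single Poisson draw,
  which would often be 0) so dominance of the window is guaranteed and the
  planted labels coincide exactly with the filter's output at the default
  threshold.
* **Disruption planting** — sentinels forced into a footprint that carries
  a motif are placed inside the motif with the least-probable base as
  their alternate allele; all other variants overlapping a hit get a
  reference base consistent with the hit sequence and a random alternate.

What the generator does **not** emulate: real nucleotide sequence (the
genome is coordinates; PWM scanning is exercised on separately generated
short sequences), LD decay with distance, allele-frequency spectra,
overlapping footprints within one DHS, multi-motif footprints, and
GC/mappability structure. Passing tests therefore demonstrate that the
statistical machinery is correct and recovers planted effects under the
assumed structure — not that any particular biological dataset would show
those effects.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; 1-based variant positions
  are converted once on read. Overlap requires ≥ 1 shared bp; touching
  intervals do not overlap. Strand is stored and ignored.
* Score binning for PWMs is 1e-3 log₂-odds units; threshold ties are
  included (≥); the tail comparison carries a 1e-12 absolute guard against
  floating-point accumulation.
* The score-centile threshold uses the inverse-ECDF (type-1) quantile:
  centile 0 keeps everything, centile 100 keeps the maximal-score ties.
* Empirical p-values can never be 0 (add-one); an annotation-free or
  null-mean-0 enrichment reports fold `NA` with a warning rather than
  dividing by zero.
* Undefined statistics (zero blocks, no footprint SNVs, no shared members)
  return `NA` with a warning and, where useful, a count attribute — they
  are signals, not silent zeros.
* The panel writer emits one phased `a|b` column per individual, so the
  panel must have an even haplotype count (the generator default is 200).
* Seeds: every randomised function takes an explicit `seed` and restores
  the caller's RNG state; the pipeline derives stage seeds from one
  top-level seed. For a fixed seed, enrichment nulls are prefix-consistent
  across different n.

# Problem sizes

The suite and the acceptance script size their simulations to run on one
CPU in minutes: LD/∏ checks use 10,000 sentinels over 4 × 1 Mb chromosomes
with a 100-haplotype panel; fold recovery uses 2,000 randomisations;
type-I calibration uses 200 replicate null datasets at 499 randomisations;
calibration recovery uses ~1,200 footprints and ~7,500 motif occurrences;
the disruption test uses 1,000 shuffles. These are the package's chosen
study conditions; all are plain configuration parameters.

# Known limitations

* The artefact filter's "skew" reading is one of two plausible
  operationalisations (see above); both cannot be validated against the
  same planted truth simultaneously.
* ∏ treats a single overlapping SNV as explaining a haplotype; it cannot
  distinguish causal from coincidental overlap, and LD blocks with many
  members saturate the DHS layer quickly.
* Exact PWM p-values are 0-order; repeat-rich or strongly biased genomes
  need a Markov background the package does not provide.
* The enrichment null preserves segment lengths and workspace geometry but
  not inter-segment spacing; clustered queries are treated as independent.
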