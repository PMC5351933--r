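# haplofoot

Most trait- and expression-associated variants are non-coding, and a popular
way to nominate the causal variant on an associated haplotype is to ask
whether any linked SNV falls inside a DNase-seq **footprint** — the short
(~11–22 bp) stretch of open chromatin protected from DNase digestion by a
bound transcription factor. `haplofoot` implements that whole analysis as a
tested, reusable R pipeline: it expands sentinel eQTL/GWAS variants into LD
haplotype blocks from a phased panel, applies footprint quality control,
measures what fraction of haplotypes a footprint annotation can explain, and
tests whether that fraction exceeds what random placement within open
chromatin would give.

It is aimed at regulatory-genomics analysts who want the statistical
machinery without the original large external datasets: a first-class
synthetic-data generator reproduces the structure the analysis assumes (DHS
containing footprints, block-structured LD, planted sentinel enrichment,
conserved motifs of expressed TFs, cut-profile artefacts) so every stage is
exercisable, and calibratable, end to end.

## The statistics

**LD expansion.** For two biallelic variants with ALT-allele frequencies
p_A, p_B and joint ALT–ALT haplotype frequency p_AB,

    r² = (p_AB − p_A·p_B)² / (p_A(1−p_A) · p_B(1−p_B))

computed on phased haplotypes. A *haplotype block* is a sentinel plus every
panel variant within a window (default 10 Mb) with r² ≥ a threshold
(default grid 0.5–1.0).

**The overlap proportion ∏.** For an annotation layer A (DHS, footprints,
footprint∩motif),

    ∏(A, r²) = #{blocks with ≥ 1 member SNV inside A} / #blocks.

∏ is non-increasing in the r² threshold and nested across layers
(∏(DHS) ≥ ∏(footprints) ≥ ∏(footprint∩motif)).

**Workspace-constrained enrichment.** Observed overlap counts are compared
against a null in which each query segment is independently re-placed
uniformly within a *workspace* (e.g. sentinels within DHS — footprints
cannot occur elsewhere, so neither should the null). Empirical p-values use
the add-one rule (#{null ≥ obs}+1)/(n+1); Benjamini–Hochberg q-values
correct across tests.

**Footprint QC and calibration.** Blacklist removal, width bounds
(11–22 bp), and an artefact filter that removes footprints whose DNase cut
profile within ±100 bp of the centre is dominated (> 50%) by a single
position. Footprint score thresholds are calibrated by the TP:FP proxy
ratio — density-normalised overlap with centrally conserved
(Δlog conservation > 0.1 vs 50-bp flanks) motifs of highly expressed TFs
(RPKM > 10 in all samples) versus motifs of undetectable TFs (RPKM = 0) —
choosing the smallest score centile with ratio ≥ 2.

**Motif disruption.** PWM scanning with exact p-value thresholds (dynamic
programming over the discretised log-odds distribution, FIMO-style,
P < 10⁻⁴), and a disruption test: the fraction of footprint SNVs whose
alternate allele flips match status, against a null of footprints shuffled
1,000× within DHS.

## Worked example

```r
library(haplofoot)

cfg <- synthetic_config(n_sentinels = 2000, planted_fold = 1.65, seed = 7)
ds  <- generate_dataset(cfg)
ds
#> synthetic_dataset: 2 chromosome(s), 500 DHS, 130 footprints,
#>   4000 panel variants (2000 sentinels), 400 motif occurrences

# enrichment of sentinel variants in footprints, DHS workspace
v    <- ds$panel$variants
sent <- v[v$id %in% ds$sentinels$id, ]
sent_iv <- interval_set(sent$chrom, sent$pos - 1, sent$pos, name = sent$id)
fold_enrichment(sent_iv, ds$footprints, ds$dhs, n = 2000, seed = 1)
#> enrichment: observed 48, null 24.65 +/- 4.89, fold 1.947,
#>   p = 0.0004998 (n = 2000, segment mode)

# haplotype overlap proportion across r2 thresholds and layers
pi_curve(ds$sentinels$id, ds$panel,
         list(dhs = ds$dhs, footprints = ds$footprints),
         r2_grid = c(0.5, 0.8))
#>   r2_threshold      layer    pi n_blocks
#> 1          0.5        dhs 1.000     2000
#> 2          0.5 footprints 0.409     2000
#> 3          0.8        dhs 1.000     2000
#> 4          0.8 footprints 0.255     2000
```

The planted 1.65-fold sentinel enrichment is recovered by the permutation
test (the estimate, 1.95 here, carries binomial noise at 2,000 sentinels;
the dedicated recovery checks use 10,000). Every block contains its
sentinel and sentinels are placed in open chromatin, so ∏(DHS) = 1; the
footprint layer explains 41% of haplotypes at r² ≥ 0.5, falling to 25% at
r² ≥ 0.8 — the characteristic decay as blocks shrink.

`run_pipeline()` (or the `exec/haplofoot` CLI with a YAML config) chains
all stages — sentinel significance filtering, footprint QC, calibration,
∏ curves, enrichment with BH correction, and the disruption test — into a
single seeded, reproducible report.

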