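---
title: "ChIPtiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ChIPtiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChIPtiling)
library(GenomicRanges)
```

ChIPtiling analyses transcription-factor occupancy measured by ChIP-chip on
high-density tiling arrays of small circular genomes — the setting typical
of archaeal and bacterial regulators, where the whole chromosome is tiled at
a few tens of base pairs and binding is probed with a handful of biological
replicates plus a mock immunoprecipitation. This vignette explains the
statistical models the package implements, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the methodology was genuinely open.

## The enriched-region model

Each array reports, per probe, a log2 ratio of ChIP over input DNA. The
calling chain is:

1. **Normalization** (`normalizeScan`): technical duplicate spots are
   averaged per probe and each array is median-centred, so the genome-wide
   median log2 ratio is exactly zero. Median-centring is scale-free and
   robust: with sparse binding, the vast majority of probes are unbound and
   define the null level. No between-array scale adjustment is applied —
   the replicate-consistency rule below operates on each array separately.
2. **Smoothing** (`smoothScan`): a running median over all probes within
   ±400 bp. The window is positional, not a fixed probe count, so irregular
   tiling is handled correctly; on circular genomes the window wraps. A
   median (rather than mean) window suppresses single-probe outliers
   entirely while preserving plateau heights — smoothing a constant signal
   is the identity, and the interior of a wide plateau is a fixed point.
3. **Calling** (`callRegions`): maximal runs of probes with smoothed value
   ≥ `y0` (default 1, i.e. 2-fold on the smoothed scale), allowing gaps up
   to twice the probe spacing, kept when they contain at least 3 probes. A
   region spans the first probe start to the last probe end. Runs crossing
   the origin of a circular genome are merged into one region.
4. **Replicate combination** (`combineReplicates`): a candidate is the
   intersection of overlapping calls across *all* replicates — the
   strictest reading of a replicate-consistency rule; it is retained only
   if every replicate's maximum smoothed log2 over the candidate exceeds
   `log2(foldThreshold)` (default fold 2) *and* the mock scan stays below
   `y0` there. The reported fold enrichment is `2^mean(per-replicate
   maxima)`.

The defaults `y0 = 1`, `foldThreshold = 2`, three replicates and one mock
reflect the study design this chain targets. The smoothing half-width
(400 bp) is of the order of the sonication fragment size; the methodology
literature rarely states a window, and results are insensitive to factor-2
changes because the kernel-smeared peaks are 2 × fragment wide.

The mock filter deliberately reuses the same smoothed statistic and the
same threshold `y0` as calling: a region "enriched in the mock" then means
exactly "the mock alone would have called it", which is the most
interpretable reading.

## The binding-energy motif model

A binding-energy position weight matrix assigns each base at each motif
position a free-energy penalty in kT units relative to the consensus word.
`EnergyPWM` stores min-zero rows (a constant per-row shift changes nothing
observable, so it is removed on construction), and a word's energy is the
sum of its per-position penalties. The theoretical dissociation constant
follows the Boltzmann factor

K_D(w) = K_D(consensus) · e^{ε(w)},

anchored at a user-supplied consensus K_D. This is the canonical
biophysical reading of an additive energy matrix; any monotone
recalibration of the energy scale only rescales thresholds, never
reorders sites. Energies are supplied already in kT, so no explicit
temperature parameter exists.

Scanning (`scanSequence`) scores every window on both strands — even for a
palindromic consensus, since measured matrices are never exactly
strand-symmetric — and applies an *inclusive* K_D threshold (default
14 µM). Circular genomes include origin-spanning windows. `scanUpstream`
restricts to the 200 bp 5′ of each ORF start, respecting gene strand;
`bestHitInRegion` returns the minimum-K_D window fully inside a region,
with ties broken by smaller start, then plus strand.

The bundled matrix (`inst/extdata/lrpB_energy_matrix_synthetic.tsv`) is a
clearly-labelled synthetic example with the 15-bp consensus
`TTGCAAAATTTGCAA` and a 63 nM consensus anchor; real analyses must supply a
measured matrix, whose file format (kT penalties, one row per position,
plus a `kd_consensus` header) is defined by this package.

## Annotation and co-occupancy classes

`classifyLocation` partitions regions into five mutually exclusive
categories: regions touching at least one intergenic base, subdivided by
the number of ORFs also overlapped (0, 1, ≥2), and purely intragenic
regions within one ORF or spanning several. `locationSummary` collapses
this to the coarse intergenic/intragenic split. Region centres are floor
midpoints — peaks have probe-level resolution, so sub-bp precision would
be spurious — and TSS distances are minimal circular distances with the
sign orientation-corrected (negative = upstream of the gene).

For two factors A and B, `overlapRegions` extends each A region by 500 bp
on both ends before intersecting with the B set. The extension models the
span over which a sonication fragment can report binding (half a fragment
on each side); the exact value is exposed as a parameter because no single
number is canonical. The overlap percentage uses the extended A region as
denominator. `assignCoClass` implements the three co-occupancy classes —
I: A-motif and in vitro A binding without B binding; II: the symmetric B
case; III: neither motif nor binding — and deliberately returns
`unclassified` for any other combination: a record with, say, both motifs
present violates the inverse-correlation pattern these classes encode and
must surface for review rather than be forced. `geneClass` adds class IV
(in vivo A binding without B co-binding) and class V (in vitro A binding
at a locus with no in vivo enrichment — the signature of a non-permissive
chromatin context).

## Wet-lab quantitation

`fitKd` fits the single-site isotherm f = P/(K_D + P) by nonlinear least
squares (Levenberg–Marquardt), with the standard error taken from the fit
covariance. A Hill variant is available behind a flag but is not the
default: fast-migrating EMSA complexes indicate one (at most two) dimers,
and a plain K_D is the reported quantity. Titrations that never reach 30%
bound trigger a warning instead of an error — the fit is then legitimate
but poorly constrained.

`ddct` implements the 2^−ΔΔCt estimator with per-replicate pairing:
ΔCt = Cq(target) − Cq(reference) within each biological replicate, so any
constant per-replicate offset (input amount, efficiency of that run)
cancels exactly; ΔΔCt is the difference of strain means and the fold is
2^−ΔΔCt. The standard deviation is delta-method propagated from the
between-replicate variance of ΔCt, and significance is a two-sided Welch
t-test on the ΔCt values (unequal variances is the safer default when only
"a t-test" is specified). No amplification-efficiency correction is
applied — the estimator is the pure 2^−ΔΔCt form. With noise-free input
the t statistic is undefined; the fold is then exact and the p-value is
reported as 1 when the strains are identical.

## What the synthetic generator emulates

`generateGenome`, `plantMotifs`, `simulateChip`, `simulateIsotherm` and
`simulateCqTable` produce every input of the chain with planted truth, so
each stage can be validated end to end. The study conditions are fixed by
the defaults of `simConfig` and `studySites`:

| parameter | default | rationale |
|---|---|---|
| genome | 200 kb, circular, GC 0.5 | desk-scale stand-in for a ~3 Mb chromosome; keeps a full study under a few seconds |
| probes | every 25 bp, 50-mers, technical duplicates | high-density tiling with duplicate spots |
| fragment length | 500 bp | sonication smear half-width |
| replicates | 3 ChIP + 1 mock | replicate-consistency design |
| probe noise | sd 0.25 log2 units | typical two-colour array noise |
| peak amplitude | 2.5 log2 (≈5.7-fold) | inside the observed 2.2–10.8 fold range of such experiments |
| protein concentration | 1 µM | converts a site's K_D into occupancy P/(K_D+P) |
| planted sites | 6 permissive (63–200 nM) + 2 non-permissive (63–100 nM) | high-occupancy targets plus permissivity controls |

The enrichment signal at a probe is the sum over permissive sites of
occupancy × a triangular kernel of half-width one fragment length centred
at the site. A triangular kernel is the simplest shape consistent with
random sonication breakpoints; nothing downstream depends on the exact
shape. Non-permissive sites keep their sequence (so motif scans find them)
but contribute no signal — the generator's model of a chromatin-blocked
locus. Mock scans are pure noise: cross-reactivity is out of scope.

The generator intentionally does *not* emulate sequence-composition realism
(repeats, insertion elements), dye bias, spatial array artefacts, or
copy-number heterogeneity. Tests passing on this generator therefore
demonstrate the correctness of the statistical chain under its stated
assumptions, not robustness to every artefact of real arrays.

The isotherm generator uses an 8-point geometric titration from 10 to
640 nM (a serial dilution, the standard EMSA design) with additive noise
(sd 0.03) on fraction bound; under these conditions the K_D estimator's
between-replicate spread is about 5% and its bias is negligible. The Cq
generator plants a fold change F by shifting the mutant target Cq by
−log2(F), adds a shared per-replicate offset that ΔΔCt must cancel, and
uses 0.15-cycle measurement noise over four biological replicates.

## Numerical conventions and degenerate inputs

* Coordinates are GenomicRanges-native (1-based, closed) in memory; BED and
  probe-table starts are 0-based half-open on disk and GFF3 is 1-based —
  all conversions live in the io layer only.
* Threshold comparisons (`y0`, K_D, fold) are inclusive where the quantity
  is "at or better": motif presence uses K_D ≤ threshold; region calling
  uses value ≥ y0; the replicate fold check is strict (> log2(fold)).
* Planted-word design (`designSiteWord`) hill-climbs over single-base
  substitutions from the consensus and must land within a factor 1.5 of
  the requested K_D, otherwise it errors naming the maximal attainable
  K_D — silent misses would corrupt planted truth.
* An all-identical scan normalizes to zeros with a warning; an empty
  candidate list propagates as an empty `GRanges`; a region narrower than
  the motif width has no best hit (`NULL`).
* Ties in best-hit selection go to the smaller start, then the plus
  strand; region centres round down.

## Problem sizes used in the test suite

The packaged validation runs the full chain on 200 kb genomes (8,000
probes) across 10 generator seeds for recovery and permissivity checks,
compares the vectorized callers against exhaustive oracles on 2,000-probe
scans and 5 kb sequences, and calibrates the two estimators over 100–200
seeds. These sizes were chosen so the whole suite completes in about a
minute while every stage is still exercised at realistic density (the
25 bp tiling step matches the probe-per-7.8-bp class of arrays scaled to a
desk-scale genome).

## Known limitations

* The replicate-combination rule intersects region spans; a caller that
  merges overlapping spans (union) would be slightly more sensitive at
  region boundaries. Intersection was chosen as the strictest defensible
  reading and the behaviour is parameter-free.
* Co-binding classes depend on in vitro binding flags that in silico runs
  cannot produce; `runPipeline` substitutes motif presence for in vitro
  binding (a documented assumption) unless measured flags are supplied.
* The K_D scale of a scanned genome is only as good as the supplied
  consensus anchor; the package makes no attempt to recalibrate energies
  against measured affinities.
* Wrapped (origin-spanning) regions are reported with end coordinates
  beyond the genome length; annotation handles them, but downstream BED
  consumers that enforce sequence bounds may need them split.
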