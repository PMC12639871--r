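---
title: "Methods: paralog-aware long-read screening of the 21-hydroxylase locus"
author: "CAHscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paralog-aware long-read screening of the 21-hydroxylase locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CAHscreen)
```

CAHscreen models the analytical core of long-read amplicon screening for
21-hydroxylase deficiency: distinguishing the functional gene *CYP21A2*
from its ~98%-identical pseudogene *CYP21A1P*, classifying recombinant
(chimeric) alleles by their junction position, calling and phasing small
variants, and turning per-sample evidence into a screening verdict. This
vignette documents the model, its assumptions, the tunable parameters, and
the numerical and design choices, in the order data flows through the
package.

## The toy locus

Real 21-OHD genetics plays out on a ~30 kb segmental duplication. The
packaged locus preserves that category structure at desk scale:

* a functional-gene reference of 3,120 nt — a 20-mer locus-specific forward
  primer, a 40 nt 5'UTR, five exons (coding lengths 150/142/308/300/200,
  CDS 1,100 nt) separated by 80 nt introns, a 1,360 nt 3'UTR, a 260 nt
  downstream flank standing in for the TNXB segment, and the reverse-primer
  site;
* a pseudogene reference generated from it by planting a configured edit
  script: 16 gene-region substitutions, one 2 nt deletion and one 2 nt
  insertion, two flank substitutions, and unrelated primers.

The 3'UTR is long enough to host the deep-UTR variant names observed in
affected alleles (up to `c.*1351G>C`); this is why the gene body is ~2.8 kb
rather than a more minimal 2.5 kb. Coordinates are 0-based half-open
internally; coding names are 1-based in the conventional style
(`c.518T>A`, `c.293-13C>G`, `c.923dup`, `c.*1316C>T`).

The paralog signature variants (PSVs) stored on the locus are **not** the
planted script itself: they are re-derived by globally aligning the two
homologous bodies (match +2, mismatch −4, gap open −6, extend −1 — standard
DNA scoring) and reading every mismatch column as a SNV PSV and every gap
run as one indel PSV. The unit tests verify that derivation reproduces a
known planted script and behaves symmetrically when the two references are
swapped. PSV density defaults to roughly one informative site per 150 nt;
fewer would starve the junction bins, many more would be unrealistic for a
96–98% identical pair.

Junction bins tile the PSV span: nine equal-count bins CH-1…CH-9 over the
gene-region PSVs (two PSVs per bin by default) plus one flank bin TNX-CH-1.
Bin boundaries sit halfway between the last PSV of one bin and the first of
the next, so a breakpoint placed between two PSVs of the same bin is always
recovered in that bin. The breakpoint naming scheme follows the field's
CH-*n* convention; the packaged bin table is configuration-overridable
because published junction coordinates for the real locus were not usable.

Reference alleles at the knowledge-base variant positions are pinned during
construction (with locally unique contexts around the indel variants and
indel PSVs), so every packaged variant name maps identically for any locus
seed. Two table-transcribed names cannot map: one VUS whose printed coding
position exceeds any plausible CDS (kept in the knowledge base by name
only; a VUS never changes a verdict) and one variant of a different gene
(*STAR*), outside this locus.

## What the simulator emulates — and what it does not

`simulateReads()` emulates demultiplexed-ready, high-accuracy circular
consensus amplicon sequencing:

* every read is a **full-length amplicon** — long-range PCR amplicons
  sequenced as single molecules; this is the property the phasing stage
  exploits, and fragmentation is deliberately not modelled;
* the default error model is substitution 0.3%, insertion 0.1%, deletion
  0.1% per base, a conservative stand-in for reads at or above the Q20
  accuracy floor; all rates are capped at 5%;
* depth is allocated deterministically: each amplicon of each haplotype is
  sampled `round(depth/2)` times, so small-depth tests are exact (a Poisson
  mode would only blur unit-test arithmetic); fixture depth defaults to
  100× because per-case depths in a screening run vary widely and 100× is
  a modest, easily exceeded floor;
* breakpoints for chimeric haplotypes are drawn uniformly between the two
  PSVs of the named bin, under the run seed.

Structures follow the locus biology: a `NORMAL` haplotype yields one gene
and one pseudogene amplicon; a 30-kb-deletion chimera (`DEL_CHIMERA`,
`TNX_CHIMERA`) collapses both into a single fused amplicon (pseudogene
before the breakpoint, gene after, pseudo-forward/gene-reverse primers) and
contributes **no** independent gene or pseudogene amplicon; a gene
conversion (`CONV_CHIMERA`) keeps gene primers but carries pseudogene
alleles over its 5' tract; a fusion duplication (`DUP_FUSION`) adds the
fused amplicon on top of one or more intact gene copies.

Not modelled: subread/CCS consensus formation, PCR chimera artifacts,
barcode sequencing errors beyond the generic error model, allele-specific
amplification bias, and any biochemical (17α-OHP) measurement. Passing
tests therefore demonstrate the *logic* of the analysis under realistic
read-level noise, not the wet-lab robustness of the assay.

## Classification and alignment

Reads are demultiplexed by their leading barcode (≤1 mismatch; barcode
tables must keep pairwise Hamming distance ≥3 so one error can never cross
samples) and then classified by the primer pair found at their termini:
gene-F/gene-R → functional gene, pseudo-F/pseudo-R → pseudogene,
pseudo-F/gene-R → deletion-chimera family. Matching tolerates one edit
(mismatch *or* indel — single indel errors are as likely as substitutions
in these reads) within a window of primer length + 5, both orientations are
tried, and unmatched reads are retained as UNASSIGNED, never dropped. Two
routes exist for the rarer classes, reflecting genuinely open assay design
space: conversion chimeras and TNXA/TNXB chimeras can be recognised by
dedicated primer pairs if the configuration provides them, but the default
locus resolves conversions at the phasing stage (pseudo-state 5' tract ≥2
PSVs on a functional consensus) and separates TNX chimeras from gene-body
deletion chimeras by junction bin alone.

Gene-family reads are aligned to the functional-gene reference with a
semi-global (fitting) affine-gap aligner: the read aligns end-to-end,
reference overhangs are free. The implementation is a banded dynamic
program in C++ (band 64 around the main diagonal by default — generous for
full-length amplicons whose true paths drift by at most a few bases — and
exact when the band covers the matrix, which is how the tests compare it
against an independent full-matrix implementation). Ties are broken by a
fixed preference order, and indel events are left-normalised against the
reference afterwards, so placement is deterministic and consistent with
VCF convention; duplication naming follows the coding-name convention
(`c.923dup`) by checking the reference copy on either side of the
insertion. Reads under 70% alignment identity are excluded from pileups
and logged. Pseudogene-classified reads never contribute variant calls.

## Variant calling, junctions and phasing

The pileup caller emits an allele when its fraction reaches 0.2 and calls
it homozygous at 0.8 — FreeBayes-like conventions; the source analysis did
not publish its thresholds. The minimum coverage floor is 30×; columns
below it are no-calls reported as a BED mask. PSV columns and primer
margins are never eligible for calls: they are paralog identity, not
sample variation. Base qualities are ignored (a documented simplification:
count-based calling is adequate at CCS accuracy).

Chimera junctions are localised per read: each read becomes a vector of
PSV states (GENE/PSEUDO/MISSING) and the caller minimises, over cut points
*c*, the number of GENE states before *c* plus PSEUDO states after *c*,
taking the leftmost minimum — a single-changepoint model matching the
deletion/conversion classes; multi-switch reads surface as high-cost
junctions and are excluded from bin groups rather than modelled. All-GENE
and all-PSEUDO vectors return sentinels; vectors with fewer than two
informative sites are errors. The junction is the open interval between
the flanking informative PSVs; its midpoint selects the bin, and an
interval straddling a boundary falls back to the left PSV's bin with an
ambiguity flag. Per-read localisation (rather than on a per-category
consensus) is the default because it lets read-level support and
discordance be counted; group bins are then majority votes.

Phasing exploits the full-length-read property: every functional read
votes at every heterozygous site, and additionally at PSV columns where
the reads disagree (that is how a conversion haplotype, invisible to the
variant caller, separates from a normal one). Clusters are seeded with the
two most frequent distinct allele vectors, reads join a consensus they
agree with at ≥80% of sites, one refinement pass recomputes majority
consensi, and reads conflicting with both at >20% of sites are set aside
as noise; a third well-supported vector raises a multi-allele flag
(expected for duplications). An exhaustive minimum-error oracle over tiny
instances backs this up in the tests; a general MEC solver is unnecessary
because full-length reads make the problem near-separable.

## Diplotype interpretation

Variant classification is a curated knowledge-base lookup (P / LP / VUS,
with SW / SV / NC phenotypes), not an ACMG evidence engine. The verdict
rule is:

> a haplotype is a pathogenic allele iff it has pathogenic content (≥1
> P/LP variant, or a deletion-class chimera structure) **and** does not
> retain an intact functional-gene copy free of P/LP variants.

Two pathogenic alleles → AFFECTED, one → CARRIER, none → NEGATIVE. The
intact-copy clause is the duplication-aware part: a fusion-duplication
haplotype whose pathogenic content sits on the fused copy while an intact
copy remains contributes nothing, which is exactly how a carrier with
"two remaining real-gene copies" is kept out of the affected bin. We state
the clause as "free of P/LP variants" (not merely "non-chimeric") because
an allele whose only intact copy carries a pathogenic SNV is, of course,
still pathogenic. LP counts toward pathogenic alleles (screening
convention); VUS never does, and the tests assert that adding a VUS to any
sample leaves its status unchanged.

When a sample shows one phased functional group plus one chimera group,
the chimera is the second allele and the functional group's variants —
even at apparent 100% allele fraction — belong to the retained allele
(hemizygous compound heterozygosity). Two functional groups plus a chimera
group means a fusion duplication; the fused copy attaches to the group
with the least pathogenic content, a heuristic that is correct whenever
the duplicated allele is the clean one (the observable cases — read
groups from different amplicons cannot be phased against each other, so
cis/trans of a fusion against a SNV allele is not directly measurable).
The predicted phenotype of an affected diplotype is the milder of the two
allele phenotypes under SW > SV > NC — standard genotype–phenotype
practice for 21-OHD, reported as predicted rather than diagnostic because
the combination rule is not part of the knowledge base itself.

## Screening statistics

Rates are percentages rounded half-up to two decimals and incidence ratios
are `1:N` with `N` rounded half-up — the conventions that reproduce every
printed cohort figure exactly (half-even rounding would not). Sensitivity
and specificity are estimated with the Jeffreys prior Beta(0.5, 0.5): the
posterior after x successes in n trials is Beta(x + 0.5, n − x + 0.5),
its mean is (x + 0.5)/(n + 1), and the 95% credible interval is
equal-tailed, computed by inverting the regularised incomplete beta
function (`qbeta`, cross-checked in the tests against root-finding on
`pbeta` to 1e−8). Equal-tailed intervals were chosen over HPD because the
published intervals are two-sided; note that published lower bounds for
such one-sided-data posteriors are not always exact equal-tailed
quantiles of the stated Beta distributions, so this package reports the
exact quantiles rather than matching any particular printed bound.

```{r posteriors}
jeffreysPosterior(12, 12)
jeffreysPosterior(61, 61)
```

## Degenerate inputs and edge rules

* Deriving PSVs from sequences under 50% alignment identity is an error
  (wrong inputs), as is parsing a name whose reference allele disagrees
  with the locus (a distinct condition class from a grammar error).
* A sample with >50% unassigned reads aborts with a diagnostic rather than
  guessing.
* Junction sentinels (no pseudo segment / no gene segment) cannot be
  binned; chimera reads whose junction fails to bin are counted and
  reported, not silently dropped.
* More than two well-supported chimera junction groups keeps the two
  best-supported with a warning note.
* An empty margin in the confusion matrix drops that posterior with a
  warning instead of inventing one.

## Problem sizes used by the test-suite

The suite simulates the twelve packaged confirmed-case diplotypes at 100×
with the default error model for the end-to-end recovery checks, a
73-sample cohort (12 affected, 4 carriers, 57 variant-free) at 100× for
the confusion matrix, error-free runs at total depth 60 for exact
round-trips (60 total puts every amplicon exactly at the 30× floor —
hemizygous deletion alleles halve functional coverage, so a total depth of
30 cannot satisfy a 30× floor on the remaining allele), 1,000 random PSV
vectors of up to 200 sites against the brute-force changepoint oracle,
500 random alignment instances against the full-matrix oracle, and 10⁴
binomial simulations for the credible-interval coverage check. These sizes
keep the whole suite in the minutes range on one CPU while leaving each
statistical check well-powered.

## Known limitations

The toy locus is a structural analogue, not a sequence homologue: no real
genome coordinates, no true TNXB gene model, and a simplified HGVS grammar
(single-base dup/del, intronic offsets, 3'UTR positions). Quality scores
are ignored; mapping quality and joint multi-sample calling are out of
scope. The duplication heuristic attaches the fused copy to the cleaner
functional group, which cannot be verified from amplicon data alone.
Conversion classes are pathogenic only when the knowledge base lists them,
and the bundled knowledge base contains exactly the alleles observed in
one screening cohort — it is a fixture, not a clinical database.
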