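---
title: "Methods: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitostructkit)
```

This vignette documents the statistical models behind each estimator in
`mitostructkit`, the parameters that matter and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical and design
choices made where the problem left room. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself compute.

## Repeat detection

`find_repeats()` performs a self-comparison of one circular genome: exact
k-mer seeds (`min_word`, default 7 bp) are grouped by diagonal, chained when
closer than 60 bp, and extended in both directions without gaps under an
X-drop rule (match +1, mismatch −2, X = 20). An alignment of score $S$ on a
genome of length $L$ is kept when its Karlin–Altschul e-value
$E = K L^2 e^{-\lambda S}$ is at most `evalue_max` (default $10^{-6}$), with
$\lambda$ solved from the score scheme under uniform base composition and $K$
fixed at 0.35. Both orientations are searched (the inverted search aligns the
sequence against its reverse complement), and hits crossing the circular
origin are recovered by re-scanning a half-length rotation and removing
duplicates whose arcs are contained, on the circle and in either locus
assignment, in a longer hit on the same (anti)diagonal.

The extension is substitution-only. The synthetic genomes diverge planted
repeat copies exclusively by point substitutions, so on the truth set a
gap-free aligner is exact; on real data containing indel-diverged repeats the
caller would fragment such repeats into collinear pieces. This is the main
deliberate simplification of the module, and validation is against planted
truth, not against any particular aligner's hit boundaries. Each repeat pair
is counted once in summaries (per-pair, not per-copy); length classes use
closed integer bins `<100`, `100–500`, `501–1000`, `>1000` bp.

## Plastid-derived sequence and homology totals

`identify_plastid_derived()` applies the same seed-and-extend engine between
the mitogenome and a plastid genome (word 7, e-value $10^{-6}$), then unions
hit intervals on the mitogenome. `merge_homology_hits()` does the interval
union for externally supplied hit tables after discarding hits shorter than
100 bp; keeping hits of exactly 100 bp is intentional so that the length
floor is inclusive.

## PGLS

`pgls_fit()` fits $y = \beta_0 + \beta_1 x + \varepsilon$ with
$\varepsilon \sim N(0, \sigma^2 C)$, where $C_{ij}$ is the shared path length
of tips $i, j$ on a dated tree (Brownian-motion covariance, `ape::vcv`). The
fit whitens both sides by the Cholesky factor of $C$ and solves ordinary
least squares in the whitened space; $R^2$ and the F-test compare against the
GLS intercept-only model. On a star tree with equal branch lengths $C$ is
proportional to the identity and the fit reduces exactly to OLS — this
identity, and unbiased slope recovery on Brownian-simulated data, are the
tested properties. The implementation is self-contained (a dozen lines of
linear algebra) rather than delegated, and is cross-checked against `lm()` in
the degenerate case.

## Recombination frequency from long reads

For a repeat pair with copies $b$ (locus A) and $e$ (locus B) and 200-bp
flanks $a,c$ and $d,f$, the reference arrangements are $a\!-\!b\!-\!c$ and
$d\!-\!e\!-\!f$. Recombinant arrangements are all flank/repeat/flank
combinations $\{a,d\}\times\{b,e\}\times\{c,f\}$ minus the references — six
forms — collapsing to the two distinguishable crossover products
$a\!-\!b\!-\!f$ and $d\!-\!b\!-\!c$ when the copies are exactly identical.
For inverted pairs, copy B is read in its recombining frame (reverse
complement, flanks swapped accordingly).

A read supports a form when its best gap-free local alignment to that form
has identity above 99% and covers at least 200 bp in each flank region; ties
in best score across the reference/recombinant categories make the read
uninformative, as does failing every form. The frequency is
$100\, n_{rec} / (n_{ref} + n_{rec})$; uninformative reads are excluded from
the denominator. "Active" pairs are those with at least one
recombinant-supporting read (`min_support` configurable), since no minimum is
standard.

Read-to-form alignment is anchor-based: shared 13-mers vote for a diagonal
and the alignment is scored (match +1, mismatch −1) at the modal offset. This
is a band-0 special case of banded local alignment, exact under the
substitution-only read error model of the generator, and is cross-checked
against `Biostrings::pairwiseAlignment` on fixture reads in the test suite.
The 99%-identity rule presumes self-corrected long reads; the read generator
is therefore run at a 0.5% substitution rate when exercising the assay
(post-correction error levels), while its default 5% models raw reads — the
per-sample platform error rate is a free parameter with no canonical value.

The simulated recombinant molecules are the true crossover products: a
direct-repeat exchange resolves the circle into two subcircles (one carrying
the $a\!-\!b\!-\!f$ junction, the other $d\!-\!b\!-\!c$), an inverted-repeat
exchange inverts the intervening segment. Reads are drawn uniformly over the
conformation sequence exactly as over the reference circle, so reference and
recombinant reads are equally likely to span a junction and the frequency
estimator is consistent for the planted mixture fraction $f$; the acceptance
suite checks that estimates fall inside the exact binomial 95% interval of
$f$ at the observed informative-read count in at least 90% of simulations.

## Inversion distance and rates

Block orders are circular signed permutations. `inversion_distance()` fixes
block 1 by rotation (reflecting first when block 1 carries a minus sign) and
solves the linear problem by Hannenhalli–Pevzner theory:
$d = b - c + h + f$ with $b$ black edges of the breakpoint graph, $c$ its
cycles, $h$ hurdles and $f$ the fortress indicator. Hurdles are unoriented
components of the cycle-interleaving graph that do not separate the other
unoriented components on the position circle; super-hurdles are detected by
deletion and recomputation. The implementation is exhaustively verified
against a breadth-first-search oracle over all circular signed permutations
with up to six blocks (BFS states are equivalence classes under rotation and
reflection; moves are arc inversions), and by sampled checks at larger sizes.

`blocks_from_anchors()` builds the permutation for genome B relative to
genome A from k-mers unique in both genomes (default k = 21): anchors are
chained into maximal collinear, consistently stranded runs with gaps at most
1 kb, and runs spanning at least `min_block` (default 500 bp) become blocks.
This is a deliberate desk-scale simplification of multiple-alignment LCB
detection; it assumes largely unique sequence between rearrangement
breakpoints and reports the fraction of A covered by blocks as the shared
percentage. Rates divide event counts by time: `pairwise_rate()` uses twice
the divergence time (both lineages evolve), `branch_rate()` the branch's own
duration; both modes are exposed because published per-branch figures follow
the second convention. Rates are point estimates; divergence-time uncertainty
is not propagated.

## Windowed diversity, F_ST and sweeps

Variants are haploid calls on a circular reference. Filtering drops sites
with minor-allele frequency at or below 0.01 (over non-missing calls; the
MAF is the second most common allele's frequency) or missingness at or above
0.1. Per-site diversity is the unbiased estimator
$\hat\pi = \frac{n}{n-1}(1 - \sum_a p_a^2)$; window π sums sites in each
1000-bp window (500-bp step, windows wrap across the origin) and divides by
the window length.

F_ST is the Weir–Cockerham weighted estimator specialized to haploid data:
with two populations of $n_1, n_2$ non-missing alleles and frequencies
$p_1, p_2$, the among-population component $a$ and total $a+b$ are summed
over sites in a window and $\hat\theta = \sum a / \sum(a+b)$; there is no
within-individual term, sites with fewer than two calls in either population
are skipped, and negative estimates are reported as computed. A window is a
sweep candidate when $\hat\theta > 0.1$ and $\pi_{wild}/\pi_{cul} > 2$; the
F_ST rule is the plain threshold (not a quantile), windows with
$\pi_{cul} = 0$ get an NA ratio and are never flagged unless
`allow_infinite_ratio` is set, and adjacent or overlapping flagged windows
merge into regions, joining across the origin.

The population generator draws shared neutral allele frequencies uniformly
on [0.1, 0.9] and, inside planted sweep windows, shifts the cultivated
frequency toward fixation so expected heterozygosity is divided by the
window's `reduction`. Default sizes are 20 haplotypes per population and one
variant site per 25 bp — denser than typical organelle polymorphism so that
1-kb windows carry enough sites for stable estimates at desk scale; the
generator emulates allele-frequency structure, not linkage, mutation-model or
demographic realism, so passing tests demonstrate estimator correctness, not
robustness to those factors.

## Deletion genotyping

Presence of a candidate region in an accession is decided from
$r = I_{dep}/W_{dep}$ (region mean over genome mean depth; mean by default,
median by option). Observed carrier and non-carrier ratios form two widely
separated empirical bands (0.24–0.72 and 6.94–142.98), so the default rule is
a single threshold of 2 — near the geometric midpoint of the gap — and a
two-band mode labels ratios inside the gap "ambiguous" instead. The depth
generator draws true ratios uniformly from the bands and adds Poisson
counting noise at the region (5 kb) and genome scales; with these bands the
classifier recovers truth exactly, which is the tested property. Carrier
percentages are compared by Pearson χ² without continuity correction (Yates
by option); the closed form is used directly and checked exhaustively against
`chisq.test` on small tables. ORFs are scanned on both strands in all three
frames, pairing every ATG with its nearest in-frame stop and keeping lengths
of at least 150 bp including the stop; nested ORFs are all reported with
forward-strand coordinates.

## Synthetic genomes and determinism

Genome backgrounds are i.i.d. uniform ACGT, rejection-sampled so that no
duplicated 25-mer (a necessary condition for any repeat of 50 bp or more, in
either orientation) survives outside planted loci; planted pairs are buffered
by at least 500 bp of unique sequence, making the truth set exact for the
repeat caller. Placement avoids the origin, which is exercised instead by
rotation tests. Read lengths are lognormal truncated to [500, 4×mean] — a
crude long-read model sufficient for junction-spanning assays. All
coordinates are 0-based half-open in code, 1-based only at I/O boundaries
(BED stays 0-based, VCF 1-based). Every generator is a deterministic function
of the configuration seed (with fixed per-generator offsets so stages draw
from distinct streams), and the pipeline's reruns are byte-identical, which
the manifest checksums make checkable.

## Problem sizes used in validation

The test and acceptance suites run at deliberately compact sizes chosen to
exercise every code path with exact oracles: 3–40 kb genomes, 50-seed read
mixtures of ~180 reads each on a 3-kb genome, 30-kb / 40-haplotype population
scans, 20-tip trees with 200 Brownian replicates, and the complete
enumeration of circular signed permutations up to six blocks. These sizes
are the package's validation design, scaled so that exhaustive and
brute-force oracles remain feasible.

## Known limitations

Gap-free alignment fragments indel-diverged repeats; the block finder
requires unique anchors and will under-segment highly repetitive genomes;
F_ST and π assume haploid, phased calls; recombination frequencies are per
repeat pair with no aggregation across pairs sharing sequence, and no attempt
is made to reconstruct full alternative genome conformations; rearrangement
events are inversions only (no translocations or fissions, appropriate for
single-circle mitogenomes); depth genotyping takes depth summaries as input
and does not compute them from alignments.
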