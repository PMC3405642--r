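---
title: "mtHaploDx: models, parameters and design choices"
author: "mtHaploDx maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mtHaploDx: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtHaploDx)
```

## The problem

Complex disorders such as Alzheimer's disease, Parkinson's disease and
type 2 diabetes, as well as extreme longevity, show associations with
mitochondrial DNA lineages. A mitochondrial haplogroup (G2a, N9b1, B5b,
D4b2a, ...) is characterised by a set of defining single-nucleotide
mutations relative to the rCRS reference, each a triple (locus, normal
allele, mutant allele) in 1-based rCRS coordinates. `mtHaploDx` covers two
connected tasks:

* **cohort analysis** — given genotype matrices for a case class and
  several control classes, find the haplogroups over-represented among the
  individuals most confidently classified into the case class;
* **individual diagnosis** — given one person's observed mtDNA mutations,
  quantify how completely they carry each class-associated haplogroup's
  defining mutations.

## The RBF network

Genotypes are encoded numerically: A, G, C, T become 1, 2, 3, 4 and
missing calls become 0 (`encodeGenotypes()`). Each individual is then a
vector $X \in \{0,\dots,4\}^{T_{SNP}}$ over the matrix's loci, and the
classifier is a Gaussian radial basis function network

$$f(X) = b + \sum_{i=1}^{m} w_i \,
  \exp\!\left(-\frac{\lVert X - M_i \rVert^2}{2\sigma_i^2}\right)$$

trained with targets 1 for the positive class and 0 for all others. The
cohort is first split per class into 2/3 training and 1/3 validation
(rounded to the nearest integer: 96 gives 64/32, 112 gives 75/37; for the
eight-class design of seven 96-person cohorts plus one 112-person cohort
the training set therefore totals $7 \times 64 + 75 = 523$ vectors).

The fitting recipe for $M_i$, $\sigma_i$ and $w_i$ is a design choice —
the network architecture alone does not determine it — and we use the
standard one:

* **centers** $M_i$: seeded k-means on the training rows (`stats::kmeans`,
  5 restarts). If the data have fewer distinct rows than requested
  centers, the center count collapses accordingly (all-identical data fall
  back to a single center).
* **widths** $\sigma_i$: the distance from center $i$ to its nearest
  other center; for $m = 1$ the standard deviation of training distances
  to the center. Non-finite or zero widths fall back to the smallest
  positive center distance, floored at 1.
* **weights and bias**: ridge-regularised least squares against the 0/1
  targets, penalty `ridge = 1e-6` on the weights (not the bias). The tiny
  default only guards against singular designs; it is not a tuning
  parameter.
* **center count** `m = "auto"`: picked from the grid 2, 4, 8, 16, 32 (or
  a stated integer) by validation accuracy at the 0.5 threshold, smaller
  $m$ winning ties.

The integer encoding imposes a spurious ordinal structure — code 1 (A) is
nearer code 2 (G) than code 4 (T), although the biological states are
categorical. We keep the plain Euclidean distance over the codes because
that is the encoding the method is defined with; a one-hot encoding would
change the geometry and is deliberately out of scope. The output unit is a
linear weighted sum: raw scores $f(X)$ can leave $[0,1]$, so reported
probabilities are clipped to $[0,1]$ while rankings use the raw values.

## Clusters, selection and association

`formClusters()` assigns each scored individual to its nearest center —
the hidden layer's grouping of similar input vectors — and reports member
counts and mean predicted probability per cluster, in percent. We define a
cluster's "predicted probability" as the mean clipped prediction of its
members times 100; an alternative reading (fraction of true-class members)
exists, but mean prediction is the direct interpretation of probabilities
attached to clusters and is what we implement.

`selectModifiedCluster()` ranks individuals by predicted probability and
takes either the top $N$ (ties broken by ascending sample id, for
determinism) or all individuals strictly above a threshold (strict `>`,
so raising the threshold never enlarges the selection). The classical
choice, used in our end-to-end checks, is the top 15 of a 96-person class.

For a selected subset, `summarizePositions()` reports each variable locus
as `locus N>M (Y/X)`: N the normal (reference) base, M the modal mutant
allele, Y its carrier count and X the normal-allele carrier count; members
with no recorded variant at a locus count as reference carriers, and
carriers of a third allele are reported in a separate column rather than
distorting Y or X. `associateSubset()` assigns each member to its
best-matching haplogroup (below) when the match fraction reaches
`minFraction` (default 0.5 — cohort association tolerates partial
profiles, unlike the stricter diagnostic threshold) and reports per-
haplogroup percentages rounded half away from zero to whole percent
(8 of 15 → 53%, 3 of 15 → 20%).

Haplogroup assignment is best-match-fraction over the flat profile tables:
the haplogroup maximising (matched entries)/(profile size), ties broken in
favour of the larger profile, then name order. A published phylogeny would
assign via tree paths instead; we do not reconstruct one, and the flat
rule is documented as a reconstruction.

## The match-ratio diagnostic

For a person's variant set $V$ and a profile $P$ of size $|P|$,

$$\mathrm{ratio}(V, P) = \frac{\#\{(l, a) \in P : V(l) = a\}}{|P|},$$

i.e. a profile entry is matched only when the person's observed allele at
that locus equals the entry's mutant allele (configurable via
`requireAlleleMatch = FALSE`, which accepts any non-normal call).
Mutations outside the profile never change the ratio. The entry is the
unit: a profile that lists one locus with two alternative mutant alleles
(the centenarian D4b2a table at 9824, T>A and T>C) contributes two
entries to the denominator, preserving the printed profile size of 15,
and a person — who carries one allele per locus — can match at most one
of the two. Whether a carrier of either allele should instead count
toward a 14-entry denominator is unresolved in the source tables; we
count entries independently and flag the case here.

A ratio strictly greater than the threshold (default 0.8) flags the
person for that profile's class. The threshold is exposed as
configuration, not validated as a clinical cutoff; `0.8` exactly is *not*
flagged, per the strict reading of "greater than". Ratios are stored as
exact fractions and rendered at three decimals, rounding half away from
zero: 11/13 → 0.846, 13/15 → 0.867, 10/12 → 0.833. (A truncated rendering
0.84 of 11/13 appears in some accounts; we treat the three-decimal form
as canonical since the same fraction is also printed as 0.846.)

## Reference handling

Profile tables are self-contained, so nothing requires a reference
sequence. Where one is useful — consistency checks
(`validateAgainstReference()`), sequence-to-variant comparison, position
summaries, simulation — the package accepts any 16,569-nt sequence. The
bundled `syntheticReference()` is a deterministic synthetic stand-in, not
the real rCRS: it fixes every profile locus to the tables' normal allele
(the eight tables are mutually consistent at shared loci) and fills the
remaining positions from a fixed pseudo-random stream. Every operation
the package performs touches the reference only at profile or variant
loci, where the stand-in is exact by construction; analyses needing true
off-profile rCRS bases should load the real sequence with
`readReferenceFasta()`.

## The cohort simulator

`simulateCohort()` generates cohorts with planted haplogroup-class
structure. Per class, a haplogroup mixture assigns individuals to source
profiles (deterministic rounded counts; the remainder are background
individuals with no planted profile). Each assigned individual carries
each entry of its source profile independently with probability
`carrierCompleteness` (default 0.9; where both alleles of a twice-listed
locus are drawn, one is kept at random), and every individual receives
Poisson(`noiseRate`, default 3) noise mutations at uniform loci outside
its own profile, each with a uniformly drawn non-reference allele.
Default cohort sizes mirror the classical study conditions: 96 per class,
112 for the semi-supercentenarian analogue. The simulation is a pure
function of (spec, seed).

What the simulator emulates: defining-SNP co-occurrence within
individuals, partial carriers, and unrelated private mutations. What it
does not: phylogenetic correlation between haplogroups (shared ancestral
mutations arise only where profiles share entries), realistic site-wise
mutation rates, heteroplasmy, sequencing error, or linkage between noise
sites. Passing end-to-end tests therefore shows the pipeline recovers
planted structure under independent noise — not that the classifier's
accuracy transfers to real cohorts, where class separation is far weaker.

## Numerical choices and problem sizes

* Rounding anywhere a value is rendered is half-away-from-zero
  (`renderRatio()`, percentage reports, the 2/3 split size).
* All randomness (splits, k-means, simulation) flows through explicit
  seeds; repeated calls with equal seeds are bit-identical.
* Model persistence (`writeRBFModel()`) uses a versioned plain-text
  format with hexadecimal floating-point literals, making the round-trip
  exact.
* The test suite exercises the end-to-end recovery at 96 individuals per
  class, completeness 0.95, noise rate 2, top-15 selection, 20 seeds —
  the scale we consider representative for a two-class planted design —
  expecting recovery in at least 18 of 20 seeds, and 20 of 20 in the
  noise-free limit. The simulator's mean-carrier check uses 10,000
  individuals.

## Known limitations

* Profiles are flat SNP sets; no hierarchical haplogroup nomenclature or
  phylogenetic placement.
* One allele per locus per person; heteroplasmy is out of the data model.
* The VCF reader is a minimal SNV-only subset (GT used solely to detect
  non-reference calls); no indels, no liftover.
* The diagnostic outputs a flag, not a calibrated disease probability.
* Report structures (cluster tables, association percentages) follow the
  classical layouts, but the original cohort data are not distributed, so
  numeric cohort results are illustrative, produced from simulated data.
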