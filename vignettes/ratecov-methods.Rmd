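---
title: "Methods: rate covariation and overlap enrichment in ratecov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rate covariation and overlap enrichment in ratecov}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratecov)
```

# Overview

`ratecov` implements two permutation-based procedures. The first detects
co-evolution between genes: proteins that work together experience the same
selective pressures, so their evolutionary rates accelerate and decelerate
in parallel across a phylogeny. The second asks whether a set of genomic
intervals (ChIP-seq peaks) is enriched at a class of fixed features
(replication origins, polymerase-occupancy regions). Both reduce a vague
biological question to a concrete exchangeability null that can be sampled
by computer.

# Relative evolutionary rates

## Model

The substrate is a genes × branches matrix of branch lengths
$l_{g,b} \ge 0$ (substitutions/site), one row per gene tree projected onto
a master species-tree branch index. Branches are identified by their
descendant leaf set, so "the same branch" is well defined across gene trees
with different taxon subsets; when pruning merges two master branches into
one gene-tree branch, both are treated as missing for that gene rather than
guessing an attribution.

Raw branch lengths confound three things: how fast the *branch* evolves
genome-wide, how fast the *gene* evolves overall, and the gene-by-branch
deviation that carries the covariation signal. The reference model
estimates the first two and removes them:

* $m_b$: trimmed mean of $l_{g,b}$ across genes (default trim fraction
  0.1 per tail). The trim makes the reference robust to a few genes with
  extreme rates on one branch. Branches observed in fewer than
  `min_genes_per_branch = 3` genes are dropped — their reference would be
  noise.
* $s_g = \sum_b l_{g,b} / \sum_b m_b$ over the gene's present, retained
  branches: the gene's overall rate relative to the reference. It is linear
  in the gene's lengths, so rescaling a gene rescales only its own $s_g$
  and leaves its relative rates unchanged (`refit_scales()` exposes this).

$$\mathrm{RER}_{g,b} = \log\frac{l_{g,b} + \epsilon}{s_g m_b + \epsilon}$$

The log-ratio is symmetric (a halving and a doubling are equally extreme),
scale-free, and zero when the gene behaves exactly as expected.
$\epsilon = 10^{-6}$ keeps zero-length branches finite; it is negligible
against typical branch lengths of order $10^{-1}$. A regression-based
residual (rates regressed on the reference across branches) is a common
alternative; the log-ratio was chosen because it needs no per-gene fit,
behaves identically under gene rescaling, and is directly testable by hand
computation.

## The ERC statistic

For genes $g$ and $h$, let $n$ be the number of branches where both have
rates. Each restricted vector is Winsorized — the $k = 3$ largest values
are condensed to the 4th largest and likewise for the smallest — because a
single shared outlier branch can otherwise manufacture a high correlation
on its own. Winsorization is applied per pair, to the restricted vectors,
so every pair's statistic is self-contained regardless of which branches
it shares. With $n \le 2k + 1$ the caps meet and the vector flattens to its
median; such pairs are invalid by construction, which the validity rule
below makes explicit.

The Pearson correlation $r$ of the Winsorized vectors is mapped to

$$\mathrm{erc} = \operatorname{atanh}(r)\,\sqrt{n - 3},$$

the variance-stabilized Fisher z-score. Under independence it is
approximately standard normal whatever $n$ is, which is what makes values
comparable across pairs with different shared-branch counts, and it ranges
over the whole real line. $r$ is clamped to $[-1 + 10^{-6},\,1 - 10^{-6}]$
first so identical vectors give a large finite value rather than infinity.
A pair is valid when $n \ge$ `min_branches` (default 10, and necessarily
$n > 3$) and both Winsorized vectors are non-constant; invalid pairs carry
`NA` and are excluded from set-level means.

## The complex permutation test

The set-level statistic for complexes $A$ (query) and $B$ is the mean erc
over all unordered between-set pairs (self-pairs excluded, duplicates from
shared members counted once). The null replaces $B$ with a random gene set
of size $|B|$ drawn without replacement from the universe — all genes in
the matrix except members of $A$ — and recomputes the mean;
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_{\mathrm{perm}})$,
one-sided for enrichment, never exactly zero. The default of 1000
permutations puts the p-value floor at $1/1001 \approx 0.001$.

Two readings of the null existed: whether $B$'s own members may re-enter
the random sets, and whether random *pairs* rather than random *sets*
should be drawn. Random sets with $B$ re-entry ("random gene sets drawn
from the genome") is the default because it is the most literal
exchangeability statement; the `universe` argument switches to any other
convention. With re-entry, a tiny universe can occasionally re-draw $B$
itself — irrelevant at genome scale, but visible in toy examples.

# Interval overlap enrichment

## Conventions

Intervals live in `GRanges`, the standard Bioconductor container (1-based,
closed). BED input (0-based half-open) and GFF3 input (1-based closed) are
converted at the boundary by `rtracklayer`; overlap semantics are identical
in both conventions — two intervals overlap iff they share at least one
base, so BED intervals abutting at a common boundary do not overlap.
Strand is ignored throughout: peaks and origin annotations are unstranded.
There is no minimum-overlap fraction; one shared base counts.

## The random-genome null

The observed statistic is the number of query intervals overlapping any
subject interval. One "random genome" re-places each query interval
independently and uniformly on its own chromosome (start uniform on
$[0, L - w]$), preserving its length and chromosome assignment; shuffled
intervals may overlap each other, as real peak sets may. The subject set
stays fixed: features like replication origins are positionally constrained
biology, while the peak set is the measured quantity whose positional
relationship is in question. A circular-shift mode
(`shuffle_intervals(..., mode = "shift")`) preserving inter-peak spacing is
provided as an alternative null; uniform re-placement is the default
because it matches the independence assumption of a normal-shaped null
count distribution.

The test reports the +1-corrected empirical p (primary) and, alongside it,
$z = (\mathrm{obs} - \bar{x}_{\mathrm{null}})/s_{\mathrm{null}}$ with its
normal tail probability, since these null distributions are customarily
drawn as fitted normals. When the null is degenerate (sd 0, e.g. the
subject covers everything), $z$ is `NA` and the empirical p stands alone.
The permutation loop runs on a flattened coordinate line with merged
subjects and a `findInterval` search, vectorized across permutations;
tests assert its exact agreement with `GenomicRanges::countOverlaps` and
with an all-pairs brute force.

# Synthetic data

## Correlated rates

The generator mirrors the multiplicative structure the RER model assumes:

$$l_{g,b} = s_g\, m_b\, \exp\!\big(\sigma(\rho f_{c(g),b} +
\sqrt{1-\rho^2}\,\varepsilon_{g,b})\big)$$

with $m_b$ the simulated tree's branch lengths, $s_g$ log-uniform on
$[0.5, 2]$, $\varepsilon$ i.i.d. standard normal, and $f$ a per-branch
factor shared by the members of a complex. Two members of a complex with
strength $\rho$ have log-rate correlation $\rho^2$; $\rho$ is therefore
the direct target of parameter recovery. Complexes given the same `group`
share one factor, planting covariation *between* complexes — the
co-evolving-machines scenario. Missingness is independent per cell
(default 5%), with a guard that leaves every gene at least one observation.

Defaults (40 species, 200 genes, $\sigma = 0.4$, $\rho = 0.8$ for planted
complexes) are the study conditions under which the package's calibration
and recovery properties are asserted. What the generator does *not*
emulate: phylogenetic covariance among branches (branch rates are
exchangeable here, while real branches share history), alignment-driven
estimation error correlated with branch depth, and gene-tree topology
error. Calibration under this generator therefore shows the statistic and
its null machinery are sound, not that real data meet their assumptions.

## Genomes with planted enrichment

Features of fixed length are placed uniformly without mutual overlap
(rejection sampling with an explicit failure cap); each peak is, with
probability $\pi$, centered uniformly inside a random feature (clipped to
the chromosome, which still guarantees coverage of the chosen point),
otherwise placed uniformly. $\pi = 0$ reproduces the shuffle null exactly
— the calibration case — and $\pi = 1$ pins every peak to a feature.
Defaults are yeast-scale: the 16-chromosome sacCer3 karyotype
(`yeast_genome()`), 350 origin-like features of 200 bp, 605 peaks of
250 bp. Real peak sets have variable widths and chromatin-biased
placement; neither matters to the null machinery being tested.

# Numerical and design notes

* All randomness flows through explicit integer seeds; identical seed and
  inputs give bit-identical results (asserted in tests). Pipelines write a
  JSON manifest with parameters, seed and input digests, into a fresh
  directory only.
* Matrix TSVs render doubles with `%.17g` and read back bit-exactly;
  `NA` is the missing sentinel. Newick branch lengths are written with 10
  significant digits.
* Under the null, erc values across random pairs have a small negative
  mean of order $-\sqrt{n-3}/G$ for $G$ genes, because every gene's rates
  share the estimated reference $m_b$; with hundreds of genes this is an
  order of magnitude below the null sd and the permutation test absorbs it
  (the null draws carry the same bias).
* Test-suite and acceptance problem sizes — 200-gene matrices, a few
  hundred replicate tests at 500–1000 permutations, 10-seed recovery runs
  — were chosen to give stable Monte-Carlo summaries (fractions accurate
  to a few percent) at interactive runtimes.
* Known limitations: no correction for phylogenetic non-independence of
  branches; ERC pairs sharing a gene are dependent, so set-level inference
  must come from the permutation test, not from treating pair values as
  independent; the overlap test is single-feature-class (no multiple-
  testing layer); gene trees must be topologically compatible with the
  species tree after restriction.
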