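---
title: "Methods: quantifying phylogenetic community structure from barcode BINs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying phylogenetic community structure from barcode BINs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bincomm)
```

## The question and the model

A local assemblage (say, the beetles of a sub-Arctic site) is a subset of a
regional species pool. If colonization were neutral with respect to
phylogeny, the local set would look like a uniform draw from the pool. Under
environmental filtering, shared physiological tolerances make close
relatives co-occur, so the local set is more *clustered* on the regional
phylogeny than a random draw; under competitive repulsion it is more
*overdispersed*. `bincomm` quantifies this with two standardized effect
sizes computed on a tip-to-tip distance matrix $d$ over the pool:

* mean pairwise distance, $\mathrm{MPD} = \binom{k}{2}^{-1}\sum_{i<j} d_{ij}$
  over the $k$ community members, sensitive to structure deep in the tree;
* mean nearest-taxon distance,
  $\mathrm{MNTD} = k^{-1}\sum_i \min_{j \ne i} d_{ij}$, sensitive to
  structure near the tips. The minima are directional, so a community of
  $k$ members contributes exactly $k$ terms.

The null distribution is obtained by drawing `n_iter` communities of the
same richness uniformly without replacement from the pool — equivalent to
shuffling the tip labels of the regional tree. The indices are sign-flipped
standardizations, $\mathrm{NRI} = -(\mathrm{MPD}_{obs} -
\bar{\mathrm{MPD}}_{null}) / s_{null}$ and analogously NTI from MNTD, so
positive values mean clustering. The primary p-value is one-tailed for
clustering, $p = (r+1)/(n_{iter}+1)$ with $r$ the number of null values at
or below the observed one. This convention cannot return $p = 0$ and its
floor at 1000 randomizations is $1/1001 \approx .001$, which is consistent
with the smallest p-values reported in per-family analyses run at that
setting. Because overdispersion is equally interpretable, a two-tailed
quantile p-value is reported alongside; the one-tailed value is what the
Holm correction is applied to in the pipeline table.

Species are proxied by Barcode Index Numbers (BINs), algorithmic clusters
of COI barcode sequences. Working at the BIN level trades taxonomic
familiarity for completeness and comparability between regions; for
beetles, BINs match morphological species in roughly nine cases out of ten,
which is the assumption under which per-family BIN counts and communities
are interpreted here.

## Pipeline stages and the choices behind them

**Ingestion and filtering.** Records arrive as a BOLD-style TSV plus FASTA.
Quality filters run in a fixed order — BIN assignment, GPS coordinates,
marker identity (default `COI-5P`), minimum length (default 500 bp counting
A/C/G/T/N, gaps excluded), and an ambiguity budget (N plus gap characters
at most 1% of the raw sequence length). A record failing several rules is
counted under the first, so per-rule counts plus the retained count always
sum to the input size; this makes filter accounting checkable against
planted faults. Bounding-box membership is closed on all four edges:
"between" coordinates are read inclusively so boundary specimens are never
silently dropped. Groups (families or genera) enter the analysis when they
have at least three distinct BINs in the local community — distinctness of
BINs, not record counts.

**Centroids.** Each BIN is reduced to the member with the minimum average
distance to all others in its BIN. The distance used is the uncorrected
p-distance with pairwise deletion of N and gap sites. Within a BIN,
divergences are far below saturation, and every standard correction is
monotone in p there, so the argmin — the only thing the centroid step
consumes — is unaffected by the choice. Ties are broken by the
lexicographically smallest record id, making the reduction deterministic
and order-invariant. Sequences are assumed aligned within a BIN: the
synthetic generator emits aligned sequences by construction, and real data
should be re-imported as aligned FASTA from an external aligner.

**Trees.** Per-group trees are built natively by neighbor joining on p,
JC69 or K80 distances (default JC69, matching the generator's
Jukes-Cantor simulation). Maximum-likelihood refinement is deliberately
out of scope: externally optimized or constrained trees can be supplied as
Newick and dropped into the same metric machinery. NJ follows the classical
Q-criterion with two documented conventions: ties in Q resolve to the
lexicographically smallest label pair (labels of original tips represent
their clusters), and a negative branch length is clamped to zero with the
deficit transferred to its sister so the pair's total is preserved. On
additive matrices the result reproduces the input distances exactly, which
the tests verify. Bootstrap support resamples alignment columns with
replacement; replicates whose matrix saturates or degenerates are skipped
and counted rather than silently dropped. Replicate sets can be summarized
as a majority-rule consensus or a maximum clade credibility tree (the
replicate maximizing the sum of its bipartitions' replicate frequencies,
first index winning ties).

**Distance modes.** The community metrics default to patristic
(branch-length) distances. A `nodal` mode — the number of internal nodes on
the tip-to-tip path — exists because the standard worked example for these
indices is stated in node counts: on the caterpillar `(((A,B),C),D)` the
six pairwise values are 1, 2, 3, 2, 3, 2, giving MPD $13/6 \approx 2.17$
and MNTD $1.5$. Note the convention: sisters are at nodal distance 1 (one
internal node between them), i.e. edges-on-path minus one. Which mode a
published analysis used is often unstated; both are provided and the
default is patristic.

**Trait statistics.** One-way ANOVA treats each group as an independent
unit; a fully constant response is reported as $F = 0,\ p = 1$ rather than
the 0/0 form. The chi-square test is uncorrected Pearson by default (a
continuity-correction option exists); the representation table it is
usually applied to — local BIN counts versus the remainder of the regional
counts per trait category — is one natural construction, but published
chi-square statistics are not always reproducible from printed tables, so
the operation is exposed generically rather than hard-wired to one layout.
PGLS under Brownian motion takes the backbone tree as an *input* (unit
branch lengths are the convention for literature-derived family
topologies). The estimator is the explicit GLS solution; the Brownian rate
$\sigma^2$ is the ML estimate $\mathrm{RSS}_V/n$, while coefficient
standard errors use $\mathrm{RSS}_V/(n-k)$ with $t$ on $n-k$ df — the
convention of standard GLS summary tables, against which the fit is
cross-checked. Categorical predictors use treatment contrasts with the
alphabetically first level as reference; published analyses often report
per-level contrasts without naming a reference, so the choice is stated
here once. With an identity covariance the fit reduces to OLS to numerical
precision, and rescaling $V$ leaves coefficients, $t$ and $p$ unchanged.

## What the synthetic generator emulates

The generator produces the statistical structure the analysis assumes, with
known ground truth at every stage:

* a pure-birth (Yule) regional tree — with $k$ lineages the next split
  waits $\mathrm{Exp}(k\lambda_b)$, and one further $\mathrm{Exp}(n\lambda_b)$
  interval runs after the $n$-th lineage, so the expected root-to-tip depth
  is $\sum_{k=2}^{n} 1/(k\lambda_b)$;
* Jukes-Cantor sequences (no indels, so alignment is the identity — this is
  what justifies excluding the aligner from the tested core), default 658
  bp at substitution rate 0.05 per unit branch length, giving within-pool
  divergences in the range typical of a beetle family's COI barcodes;
* BINs as noisy copies of each tip sequence (default 5 per BIN at expected
  p-distance 0.005 to a planted zero-noise centroid, mimicking low
  intra-BIN variation), coordinates inside/outside a configurable local
  box, and quality faults planted with exact counts rather than rates so
  filter accounting is deterministic;
* community assembly in three regimes sharing one strength parameter
  $\lambda$: uniform draws (neutral); a uniform focal tip plus draws
  weighted $\propto e^{-\lambda d(\text{focal}, i)}$ (filtering); and
  sequential draws weighted $\propto e^{+\lambda \min_j d(i, j)}$ over
  already-selected members $j$ (repulsion). $\lambda = 0$ provably reduces
  every mode to neutral, which is tested distributionally. The exponential
  kernel is the simplest one-parameter family spanning the clustered and
  overdispersed regimes with a neutral limit. In the tests and acceptance
  script, $\lambda = 5$ on a 100-tip unit-rate Yule tree (mean pairwise
  patristic distance around 6–7) serves as "strong" filtering: the weight
  declines by more than an order of magnitude per unit distance, far
  steeper than the null's spread.

What it does **not** emulate: real barcode data have indels and alignment
error, rate heterogeneity across sites and lineages, geographically
structured sampling effort, BIN boundaries that occasionally split or lump
species, and regional pools that are themselves incompletely sampled.
Passing the calibration and power checks therefore shows the machinery is
correct and well calibrated under its own assumptions — not that any
particular empirical dataset meets those assumptions.

## Numerical choices and degenerate inputs

* Saturated distances (JC69 at $p \ge 3/4$, K80 log arguments $\le 0$) are
  errors naming the pair, never silent `NaN`s; in bootstrap replicates they
  skip the replicate and are counted.
* A community equal to its pool, or any null with zero standard deviation,
  is a degenerate-null error rather than an infinite or undefined index.
* An all-zero distance matrix (invariant alignment) is refused by NJ.
* Non-monophyletic outgroups fall back, with a warning, to rooting on the
  first listed outgroup tip.
* Newick round trips preserve topology, labels and branch lengths to
  1e-9 (12 significant digits are written).
* Centroid and NJ tie-breaks are lexicographic, so every pipeline output is
  reproducible bit-for-bit given the seed, which is recorded in results.

## Problem sizes used in the checks

The shipped tests and the acceptance script use a 100-tip pool with
communities of richness 20 for calibration (1000 neutral communities at
1000 randomizations each; SES mean within ±0.15 of 0, sd within ±0.15 of
1, type-I error in [.03, .07] at nominal .05), 100 filtering communities at
$\lambda = 5$ for power, 500 Brownian simulations on a fixed 16-tip
unit-branch-length tree for PGLS effect recovery (±10% of the planted
effect), and reduced-scale end-to-end runs (50-tip pools, 3 records per
BIN) for the full TSV-to-table pipeline. These sizes were chosen as the
smallest at which the distributional statements above are sharp.

## Known limitations

* Maximum-likelihood tree optimization, substitution-model selection and
  constrained searches are out of scope by design; import such trees as
  Newick.
* Abundance weighting is not implemented: communities are presence/absence
  sets of BINs, as the null model shuffles labels, not abundances.
* Only the tip-label shuffling null is provided (no independent-swap or
  frequency-preserving nulls).
* PGLS supports the Brownian correlation structure only (no Pagel's
  lambda or Ornstein-Uhlenbeck transformations), matching the backbone-tree
  use case with unit branch lengths.
* The aligner is external: within-BIN and within-group alignments of real
  data must be produced upstream and re-imported.
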