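---
title: "Hybrid growth-rate prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid growth-rate prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phygrow)
```

# The problem

Maximum growth rate — expressed throughout as its reciprocal, the minimal
doubling time in hours — is a central functional trait of bacteria and
archaea, yet it has been measured for only a tiny fraction of known
species. Two genome-scale routes to predicting it exist, with complementary
failure modes:

* **Codon usage bias (CUB).** Fast growers concentrate translation on
  preferred synonymous codons in their highly expressed genes (here:
  annotated ribosomal proteins). A regression of doubling time on a CUB
  summary extrapolates across the whole tree of life but carries
  irreducible noise, because growth is influenced by much more than
  translational optimization.
* **Phylogenetic prediction.** Related species grow at similar rates, so a
  query's doubling time can be predicted from its relatives' measured
  values. This is excellent when a close relative is available and
  near-useless for phylogenetically isolated queries.

phygrow implements both components, a logistic *gate* that scores, per
query, the probability that the CUB route outperforms the phylogenetic
route, and combination rules that weight the two estimates by that
probability. It also implements the evaluation machinery that motivates
the design — phylogenetically blocked cross-validation — and the
phylogenetic-signal statistics (Blomberg's K, Pagel's lambda) used to
characterize how heritable the trait is.

# Models

## CUB component

For each genome, every retained coding sequence contributes pooled codon
counts to a background usage; each annotated ribosomal protein is scored
with MILC (Measure Independent of Length and Composition) against that
background:

$$\mathrm{MILC}(g) = \frac{\sum_a M_a}{L} - C, \qquad
  M_a = 2 \sum_{c \in a} o_c \ln\frac{f_c}{g_c}, \qquad
  C = \sum_{a\ \mathrm{present}} \frac{r_a - 1}{L},$$

where $a$ indexes synonymous families of size $r_a \ge 2$ (stop codons,
Met and Trp excluded), $o_c$ are codon counts, $f_c$ observed and $g_c$
background within-family frequencies, and $L$ is the number of codons in
degenerate families. The genome-level summary `cub_he` is the median MILC
across ribosomal genes; a genome qualifies only with **at least 10
annotated ribosomal proteins**. The growth model is ordinary least squares
of $\ln d$ (doubling time) on `cub_he`, optionally with optimal growth
temperature (OGT, °C) as a second covariate. This deliberately compact
regression stands where a richer CUB predictor could: the package's
contribution is the gated combination and its evaluation, and the
regression is re-fit on every training fold, so any CUB predictor exposing
"fit / predict" semantics could be substituted.

Two numerical choices: background frequencies receive a pseudocount of 0.5
per codon (no $\ln 0$ for rare codons), and for contaminated assemblies
(contamination score $\Psi > 0.6$) the background switches to
family-uniform usage ("metagenome mode") because a mixed assembly's pooled
codon usage is not that of the target organism.

## Phylogenetic component

Two predictors, both averaging on the $\ln$ scale (rate-like traits are
multiplicative; geometric averaging keeps estimates inside the training
range):

* **NNM** — geometric mean of the $k = 5$ nearest training species by
  patristic distance, ties at the $k$-th distance all included.
* **BM BLUP** (the default phylogenetic component) — the best linear
  unbiased prediction under Brownian motion,
  $\hat y_q = \hat\mu + c_q^\top C^{-1}(y - \hat\mu 1)$, with $C$ the BM
  tip covariance (shared root-to-MRCA path lengths), $c_q$ the
  query-training covariances and $\hat\mu$ the GLS mean. This equals the
  ancestral-state estimate at the query's attachment point produced by
  Felsenstein's contrasts pruning recursion; the test suite verifies both
  this equivalence and agreement with picante's `phyEstimate` to 1e-8.

## The gate and the combination

The per-query weight is

$$\mathrm{logit}(P) = \beta_0 + \beta_y \ln \tilde y_{\mathrm{cub}}
  + \beta_d D_p + \beta_{yd}\, \ln \tilde y_{\mathrm{cub}} \cdot D_p,$$

with $D_p$ the mean patristic distance from the query to its 5 nearest
training species, and $\ln \tilde y_{\mathrm{cub}}$ standing in for the
unknown true growth rate (the relative accuracy of the two components
varies with growth rate as well as with distance). Natural logarithms are
used throughout. $P$ is trained by maximum-likelihood logistic regression
on binary labels — "the CUB estimate beat the phylogenetic estimate for
this species" — where *beat* means a smaller squared error on $\ln d$,
ties favouring CUB as the globally stabler component.

Labels must be produced **out of sample**: each training species receives
its two predictions from an inner blocked cross-validation (below) run on
the training set only. The package pools inner label records across
several inner cutting depths (default clade counts 10, 20 and 40, clipped
to the training size). A single inner depth yields labels confined to one
band of $D_p$, and a gate fit on them extrapolates wherever deployment
distances differ; pooling depths covers the distance range on which the
gate will actually be evaluated. This pooling is a deliberate design
choice of this package.

Three combination modes (`y` = CUB estimate, `y'` = phylogenetic
estimate):

* arithmetic (default): $yP + y'(1-P)$,
* geometric: $y^P {y'}^{1-P}$,
* binary: $y$ if $P > 0.5$, else $y'$.

The binary mode discards one information source entirely and behaves like
a piecewise regression with an estimated change point: unstable near the
threshold. The continuous modes average over that uncertainty, which is
why arithmetic is the default; the test suite checks that continuous
arithmetic does not lose to binary on average across seeded benchmark
replicates.

Perfect separation can arise in the logistic fit (e.g. in strongly
CUB-dominant training data); the fit then switches to a ridge-stabilized
Newton solver (penalty 1e-4, intercept unpenalized) and flags the result,
so coefficients are always finite.

Fallback rules at prediction time: a genome failing the 10-ribosomal
quality filter gets the pure phylogenetic estimate with $P$ forced to 0;
a query absent from the tree gets the pure CUB estimate with $P$ forced
to 1. Both are flagged in the output, and batch prediction emits exactly
one row per input genome.

# Phylogenetically blocked cross-validation

Random CV folds overestimate performance for trait prediction, because
close relatives of every test species sit in the training data. Blocked
CV instead cuts the tree at a uniform depth into $n$ clades and holds out
one clade at a time. Sweeping $n$ over 10, 20, …, 410 (41 scenarios on a
411-tip tree) sweeps the phylogenetic distance between training and test
sets: few clades mean deep cuts and distant training data; many clades
mean shallow cuts and close relatives.

Design details:

* Cuts are made at a uniform distance from the **root** (equivalent to
  distance from the present on ultrametric trees, and well defined
  otherwise); the reported `cut_depth` is the midpoint of the depth band
  in which exactly $n$ lineages cross, given as distance from the present
  for ultrametric trees.
* When a multifurcation makes the lineage count jump past $n$, the
  smallest achievable $m \ge n$ is used and flagged — the sweep stays
  totally ordered.
* Errors are mean squared errors on $\ln d$ (hours). The log scale is the
  scale of every model in the package and makes errors on fast and slow
  growers commensurable.
* Folds are weighted equally in per-depth averages (configurable by
  aggregating the per-fold records differently).
* The fold-level distance `fold_dp` is the minimum over test species of
  the per-species $D_p$; the per-depth summary reports its minimum over
  folds, which is provably non-increasing as $n$ grows (partitions are
  nested in $n$).
* Growth strata: *slow* means doubling time $> 5$ h, *fast* $\le 5$ h
  (the boundary species is fast), and a *fast inset* stratum collects
  doubling times under 0.5 h.
* Folds leaving fewer than 2 training species for the BM BLUP are
  recorded as missing for that predictor, never silently dropped.

# The synthetic benchmark

Real evaluation data (published trait compilations, reference trees,
tens of thousands of genomes) cannot ship with a package, so phygrow
includes a generator whose bundles exercise every pipeline stage:

* **Trees**: pure-birth (Yule) trees — ultrametric by construction, one
  rate parameter. Default 120 species, birth rate 1.
* **Traits**: $\ln d$ drawn from a multivariate normal with covariance
  $\sigma^2 C(\lambda)$, where $C(\lambda)$ scales the off-diagonal BM
  covariance by $\lambda$. `lambda_true` = 1 gives pure BM, 0 independent
  tips. Default $\sigma^2 = 0.5$ per unit depth around a root state of
  4.5 h — the geometric midpoint of the 0.2–100 h range the defaults span,
  mirroring observed doubling times from minutes to days.
* **Genomes**: background genes draw codons uniformly within synonymous
  families; ribosomal genes draw one designated preferred codon per
  family (alphabetically first, configurable) with probability
  $b = \mathrm{clip}(b_{\min} + s\,(\ln d_{\max} - \ln d),\ b_{\min},
  b_{\max})$, so faster growers carry stronger ribosomal codon bias. The
  genome is generated from a noisy copy of the trait
  ($\ln d + N(0, \texttt{cub\_noise\_sd}^2)$), decoupling CUB quality
  from phylogenetic signal. Amino acids are uniform, genes start with ATG
  and end with TAA, and no internal stops occur.

Every operation is deterministic under its seed; bundles round-trip
byte-identically.

What the generator does **not** emulate: realistic GC content or
amino-acid composition, operon structure, sequence evolution along the
tree (genomes are conditionally independent given the trait), horizontal
transfer, and rate variation across lineages. Passing benchmarks
therefore demonstrates internal correctness and the qualitative regime
structure, not field accuracy on real genomes.

## Benchmark regimes

Three named regimes probe the ensemble's behaviour
(`regime_config()`):

* **cub_dominant** — no phylogenetic signal (`lambda_true = 0`),
  noise-free genomes, long genes (600 codons), 20 ribosomal against 120
  background genes (a clean background pool; with too few background
  genes the biased ribosomal genes contaminate the reference usage), and
  a bias range (0.3–0.9) anchored to a narrow doubling-time window
  (0.5–40 h) where the bias-to-MILC map is closest to linear. Here the
  CUB regression is sharp and relatives are uninformative, so the CUB
  predictor must win at every cutting depth.
* **phylo_dominant** — pure BM trait with large variance
  (`bm_sigma2 = 2`) and severely noisy genomes (`cub_noise_sd = 4`):
  the phylogenetic predictor must win once clades are cut finely enough.
* **mixed** — heritable trait, moderate CUB noise and a denser tree, so
  the two error curves genuinely cross within the sweep, as in the
  evaluation the package is designed around. On this regime the gated
  ensemble is required to track (within 5%) or beat the better component
  over most cutting depths, and continuous arithmetic weighting must not
  lose to binary switching on average.

A note on what gating can and cannot do: the gate estimates the
*probability* that CUB wins, and a calibrated probability almost never
reaches 0 or 1 (even a terrible predictor lands close to the truth for
the ~10–15% of species that happen to sit near its predictions). A
probabilistic mixture therefore cannot track the better component within
a few percent when the components differ by an order of magnitude; it
shines when the curves are within a small factor of each other and cross
— which is the regime the mixed benchmark (and the real application)
occupies. For the same reason the fraction of cutting depths at which the
ensemble stays within a few percent of the better component fluctuates
between benchmark draws: tree draws in which one component runs away from
the other at either end of the sweep widen exactly the gap a
probability-weighted mixture cannot close.

# Numerical choices and degenerate inputs

* Pagel's lambda: bounded scalar maximization on [0, 1], tolerance 1e-8,
  two bracketing starts (0–0.5, 0.5–1) plus the endpoints; the
  likelihood can be flat or bimodal near the boundary. A star phylogeny
  makes lambda unidentifiable: the result is flagged (`flag = "star"`),
  not silently numeric. Significance is a likelihood-ratio test against
  lambda = 0 (chi-squared, 1 df).
* Blomberg's K: permutation test with 999 permutations under a caller
  seed, one-sided on the GLS mean squared error (observed signal
  stronger than permuted).
* Both statistics operate on any trait; for doubling times the package
  convention is the natural-log scale (`log_transform = TRUE`), matching
  the error metric of the cross-validation.
* Constant traits are a degenerate-input error; trees must carry branch
  lengths on every edge; duplicate or empty tip labels are validation
  errors; unknown tips are lookup errors. Error classes are distinct
  condition classes, and the command-line interface maps them to distinct
  exit codes.
* `cut_into_clades` with `n = 1` returns the trivial partition; `n`
  above the tip count is a domain error.
* Genome loading drops (with a message) coding sequences whose length is
  not a multiple of 3, that contain ambiguity codes, or that contain
  internal stop codons.

# Problem sizes

The shipped tests and the acceptance script run entirely on generated
data at sizes chosen to exercise the machinery while keeping a full run
comfortable on a single CPU: signal-recovery loops use 100–200 trees of
200 tips; the structural sweep uses the full 411-tip, 41-scenario design
with the nearest-neighbour predictor; regime benchmarks use 60–120
species with genomes of 100–140 genes. Larger problems change runtimes,
not code paths.

# Known limitations

* The CUB component is a two-parameter regression on one MILC summary;
  it does not model codon-pair effects, growth-temperature interactions
  beyond a linear OGT term, or the consistency-across-genes features of
  richer CUB predictors.
* Queries must already be tips of the reference tree for phylogenetic
  prediction; placing foreign genomes into a tree is out of scope (the
  CUB fallback covers such queries).
* Only Brownian-motion trait evolution is supported; models requiring
  extra information (selection regimes, eco-evolutionary timescales) are
  deliberately excluded.
* Predictions are point estimates; no uncertainty intervals are
  reported.
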