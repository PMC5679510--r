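---
title: "Information-theoretic sequence features for gene essentiality prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-theoretic sequence features for gene essentiality prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itess)
```

## The problem

Essential genes are those whose disruption is lethal or blocks reproduction.
Knowing them matters for minimal-genome design and for drug-target discovery
in pathogens, but knock-out screens are slow and condition-dependent, and
most computational predictors lean on auxiliary data — protein-interaction
networks, expression profiles, orthology searches — that simply do not exist
for newly sequenced organisms. `itess` implements a predictor that uses
nothing but the coding DNA sequence of each gene: a fixed vector of 91
information-theoretic statistics feeds a Random Forest, and an evaluation
harness measures how well essentiality annotations transfer within an
organism, between organisms, and across taxonomic orders.

The working hypothesis is that essential and non-essential genes are
produced by detectably different sequence "sources": their local base
dependencies, entropy, thermodynamic stability and k-mer composition differ
enough to be exploited statistically, without any alignment or database
search.

## The feature vector

All probabilities below are plug-in estimates from overlapping windows
(step 1) of a single gene sequence over the alphabet
$\Omega = \{A, C, G, T\}$. The canonical order of the 91 features is given
by `feature_names()`.

**Mutual information (17 features).** With $P(x,y)$ the distribution of
ordered consecutive base pairs,

$$I(X;Y) = \sum_{x,y \in \Omega} P(x,y)\,\log_2 \frac{P(x,y)}{P(x)P(y)},$$

where the marginals are the row and column sums of the estimated joint —
not independently re-counted single-base frequencies. That convention makes
the plug-in MI nonnegative by construction and bounds it by
$\log_2 4 = 2$ bits. The total and each of the 16 summands are features.

**Conditional mutual information (65 features).** The three positions of
every overlapping triplet are treated as $X$ (first), $Z$ (middle), $Y$
(last), and

$$I(X;Y \mid Z) = \sum_{x,z,y} P(x,z,y)\,\log_2
\frac{P(z)\,P(x,z,y)}{P(x,z)\,P(z,y)}$$

measures what the outer bases share once the middle base is known. The
total and the 64 per-triplet summands are features. Triplets are sliding
windows, not codon-frame triplets, for uniformity with the pair statistics
and maximal use of the data; a codon-frame variant was considered and
rejected because it would make the pair and triplet estimators use
different amounts of the sequence.

**Shannon and Gibbs entropies (4 features).** The Shannon block entropy
$H_N = -\sum_i P^{(N)}(i) \log_2 P^{(N)}(i)$ is computed for block sizes
$N = 2, 3$. The Gibbs entropy replaces the frequency distribution with a
Boltzmann distribution that couples frequency to thermodynamic stability:

$$P_G(i) = \frac{n_i\, e^{-E(i)/k_B T}}{\sum_j n_j\, e^{-E(j)/k_B T}},
\qquad S_G = -\sum_i P_G(i) \ln P_G(i),$$

where $n_i$ is the count of word $i$ and $E(i)$ its nearest-neighbor free
energy — for $N = 3$ the sum of the two constituent overlapping
dinucleotide energies. The bundled energy table is the unified
nearest-neighbor DNA/DNA set of SantaLucia (1998) ($\Delta G^\circ_{37}$,
kcal/mol); any 16-entry TSV can be substituted. Because the table is in
kcal/mol, the exponent uses $k_B N_A / 4184 = 1.9872 \times 10^{-3}$
kcal/(mol·K). Two choices are deliberate: the stored feature drops the
$k_B$ prefactor (so values are $O(1)$, in units of $k_B$; any monotone
rescaling is invisible to a tree ensemble), and the default temperature is
310.15 K (37 °C), the growth temperature of most of the bacteria this kind
of study targets. With a constant-energy table $S_G$ reduces exactly to
$\ln 2 \times H_N$, which the tests exploit.

**Kullback-Leibler divergences (3 features).** For $k = 1, 2, 3$,

$$\mathrm{KLD}_k = \sum_i P(i) \log_2 \frac{P(i)}{Q(i)}$$

compares the gene's k-mer distribution $P$ to the background $Q$ of the
*training* organism. $Q$ comes from the genome sequence when one is
supplied, otherwise from the pooled k-mer counts of the training genes
(counted per gene, never across gene boundaries); the active choice is
logged. Zero background cells under observed gene mass are floored at
$\varepsilon = 10^{-6}$ and $Q$ renormalized — a rare event on real-size
backgrounds, logged when it triggers.

**Markov scores (2 features).** Essential and non-essential training genes
are modeled as two separate order-$m$ Markov sources. Transition
probabilities use the Lidstone estimator

$$P_{v,a} = \frac{N(va) + \delta}{N(v) + 4\delta}, \qquad \delta = 0.001,$$

with $N(va)$ the pooled count of the $(m{+}1)$-word $va$ and $N(v)$ the
count of occurrences of context $v$ that have a successor — the successor
convention is what makes every row sum to exactly one. A gene
$b_1 \dots b_L$ is then scored against each chain as

$$\mathrm{Score} = \sum_{i=1}^{L-m} P(b_i \dots b_{i+m})\,
\log_2 \frac{P(b_{i+m} \mid b_i \dots b_{i+m-1})}{P(b_{i+m})}.$$

The unconditional word and base probabilities are estimated from the same
training pool with the same $\delta$ convention. This was a genuinely open
design point — they could also have been taken from the scored gene
itself — and the training-pool choice was made for self-consistency (all
probabilities describe one source) and strict positivity. An order-0 chain
makes the conditional equal the marginal, so every score is exactly 0, a
useful degenerate check.

The chain order is fixed at $m = 1$ by default, which is what
cross-organism runs use. For intra-organism work an order-estimation mode
is available: `estimate_order()` returns the smallest $m$ at which
$I(X_t; X_{t-m-1} \mid X_{t-1..t-m})$ stops being significant, assessed by
a seeded permutation test (199 within-context permutations of the lagged
symbol, $\alpha = 0.05$). This is a self-contained surrogate for
CMI-based order estimation; its $\alpha$, permutation count and seed are
configuration.

**Leakage guard.** When features are extracted for the training genes
themselves (to train the forest), each gene's own window counts are
subtracted from its class chain before scoring — numerically identical to
refitting the chain without that gene, at a fraction of the cost. Chains,
backgrounds and feature rankings are always derived from training-side
genes only; every evaluation result carries the train/test gene-id sets so
tests can audit this.

## Classification and evaluation

Non-essential genes outnumber essential ones several-fold in annotated
bacteria, so every training set is first balanced by random under-sampling
of non-essentials (all essentials kept; never over-samples). The
classifier is a 100-tree probability Random Forest
(`ranger`, Gini impurity splits, $\lfloor\sqrt{91}\rfloor$ candidate
features per split, unlimited depth); a gene's essentiality score is the
fraction of trees voting essential. All of these are configuration with
logged defaults.

Five evaluation regimes are provided, all reporting AUC (computed by the
rank/Mann-Whitney formulation, ties counting one half — exact, no
trapezoid approximation) plus accuracy and F-measure at threshold 0.5,
which are reported but secondary since they depend on the threshold:

* `monte_carlo_cv()` — within one organism: repeated (default 100×)
  balance, stratified 80/20 split, per-fold refit of chains and (when no
  genome is given) background, train, score. Stratification on the
  balanced set stabilizes small organisms; under-sampling is redrawn
  fresh each repetition so the fold AUC spread reflects sampling variance.
* `pairwise_cross()` — train on one organism (balanced), score every
  labeled gene of another; the KLD background is the training organism's.
* `leave_one_species_out()` — pool all other organisms, balance, score
  the held-out organism.
* `pooled_cv()` — k-fold (default 5) over the union of all organisms,
  folds stratified by organism × label.
* `taxon_eval()` — the same protocols at the taxonomic-order level:
  every ordered taxon pair (cross-taxon) or each taxon held out against
  the pooled rest.

`rank_features()` scores each feature by information gain — label entropy
minus the best single-threshold conditional entropy, all midpoints between
distinct values examined — and `select_top_k()` slices the ranking for
feature-selection experiments.

## The synthetic-data generator

Real essentiality studies need curated knock-out labels and genome
downloads; the package instead ships a generator whose premise mirrors the
Markov-feature assumption: each class is an order-1 Markov source.
`synth_config()` takes a positive-class matrix $M_{\text{pos}}$ and an
alternative matrix $M_{\text{alt}}$ and draws non-essential genes from the
linear mixture $(1-d)\,M_{\text{pos}} + d\,M_{\text{alt}}$; the divergence
knob $d \in [0,1]$ moves the classes from exchangeable ($d = 0$) to
maximally distinct ($d = 1$). The genome is drawn from the 50/50 matrix
mixture, so the background is class-neutral.

Three frozen presets define the study conditions (`preset()`): 60
essential and 240 non-essential genes (the ~1:4 imbalance typical of
annotated bacteria, scaled down), gene lengths uniform on [300, 1500] nt
(the span of typical bacterial CDS lengths), a 50 kb genome, and the
bundled matrix pair with a 0.4/0.2 preferred-successor contrast —
`separable` ($d = 1$), `weak` ($d = 0.3$), `null` ($d = 0$). Everything is
a deterministic function of the seed.

What passing tests on this generator do show: the full pipeline —
ingestion, all 91 features, balancing, training, every evaluation regime —
recovers a real class difference when one exists, reports chance when none
does, and is monotone in the divergence knob, all without information
leakage. What they do not show: performance on real genes. Real coding
sequences have codon structure, operons, GC skew, length–essentiality
correlations and label noise that an order-1 source does not emulate;
absolute AUCs on the presets (near 1.0 for `separable`) say nothing about
the AUCs achievable on curated bacterial annotations.

## Numerical choices and degenerate inputs

* $0 \log 0 := 0$ throughout; MI/CMI marginals derive from the joint, so
  a positive joint with zero marginal product cannot occur.
* Logarithms: base 2 for Shannon/MI/CMI/KLD and Markov scores (bits);
  natural log for the Gibbs entropy.
* Sequence cleaning strips non-ACGT symbols (ambiguity codes) rather than
  substituting them, preserving k-mer statistics; genes with more than 10%
  stripped, or fewer than 3 surviving bases, are rejected with a reason.
  Cleaning is idempotent.
* Homopolymers give zero MI/CMI/entropy; sequences shorter than the window
  error out of the single-sequence operations and are dropped (logged)
  by the batch extractor.
* Any non-finite feature aborts extraction naming the gene and feature —
  fail fast, no imputation. No feature scaling is done anywhere; forests
  are invariant to monotone per-feature transforms.
* Ties in feature ranking are kept in canonical feature order (stable
  sort); tied scores contribute one half to the AUC.
* Determinism: every stochastic step (balancing, splits, forest, order
  permutation test, generator) is governed by an explicit seed, and
  repeated runs are bit-identical.

## Problem sizes

The shipped tests and the acceptance script run the evaluation regimes at
deliberately modest sizes — preset organisms of 300 genes, 10-fold Monte
Carlo cross-validation, two- to four-organism pools — which exercise every
code path while keeping a full run in the minutes range on one CPU. The
same functions scale to organism collections of real size (thousands of
genes, 100 folds) unchanged; extraction cost is linear in total gene
length and evaluation cost linear in folds.

## Known limitations

* Gini impurity, not an entropy criterion, drives the forest splits
  (the two are near-interchangeable in practice and no split-level entropy
  option exists in the underlying engine); the *feature ranking* does use
  information gain exactly.
* The order estimator is a permutation-test formulation of CMI-based
  order selection, not a reimplementation of any specific published
  estimator.
* Eukaryotic gene models are supported only insofar as the user supplies
  already-spliced CDS sequences; no GFF handling, no reverse
  complementing.
* The synthetic sources are order-1 only; higher-order generation is out
  of scope, so order-estimation behavior above $m = 1$ is tested only on
  hand-built sequences.
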