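# itess — information-theoretic sequence features for gene essentiality prediction

Essential genes are the genes an organism cannot live or reproduce
without; finding them matters for minimal-genome engineering and for
picking drug targets in pathogens. Most computational predictors need
auxiliary data — interaction networks, expression profiles, orthology
databases — that are unavailable for newly sequenced or under-studied
organisms. `itess` predicts essentiality **from the coding DNA sequence
alone**: it turns each gene into a fixed 91-dimensional vector of
information-theoretic statistics and classifies it with a Random Forest.

The feature vector comprises, per gene (probabilities are plug-in
estimates over overlapping windows, alphabet Ω = {A,C,G,T}):

- **Mutual information** between consecutive bases,
  I(X;Y) = Σ P(x,y) log₂ P(x,y)/(P(x)P(y)), total + 16 per-pair terms;
- **Conditional mutual information** between the outer bases of a triplet
  given the middle one, I(X;Y|Z) = Σ P(x,z,y) log₂ P(z)P(x,z,y)/(P(x,z)P(z,y)),
  total + 64 per-triplet terms;
- **Shannon entropies** H₂, H₃ and **Gibbs entropies** G₂, G₃, the latter
  over Boltzmann distributions P_G(i) ∝ nᵢ e^(−E(i)/k_BT) with
  nearest-neighbor dinucleotide free energies (SantaLucia 1998 bundled,
  user-overridable);
- **Kullback-Leibler divergences** of the gene's k-mer distributions
  (k = 1, 2, 3) from the training organism's genome background;
- **Markov scores** of the gene under class-conditional order-m chains
  fitted with Lidstone smoothing P_{v,a} = (N(va)+δ)/(N(v)+4δ), δ = 0.001,
  scored as Σ P(word) log₂(P(a|v)/P(a)).

Around the extractor sits a full evaluation harness — Monte Carlo
cross-validation within an organism, pairwise cross-organism prediction,
leave-one-species-out, pooled k-fold, cross-taxon and leave-one-taxon-out
— with exact rank-based ROC/AUC, class balancing by under-sampling,
information-gain feature ranking, and a seeded synthetic-organism
generator (parameterized class-conditional Markov sources) so the whole
pipeline runs and is testable without any downloads.

## Worked example

Generate a synthetic organism whose essential and non-essential genes come
from weakly diverged Markov sources, extract features, and cross-validate:

```r
library(itess)

org <- generate_organism(preset("weak", seed = 42))
org$dataset
#> <organism_dataset> WEAK: 300 genes (60 essential, 240 non-essential, 0 unknown)

g   <- org$dataset$genes
pos <- fit_markov(g$sequence[g$label == "essential"],     m = 1)
neg <- fit_markov(g$sequence[g$label == "non_essential"], m = 1)
bg  <- background_distribution("WEAK", genome = org$genome)
f   <- extract_features(org$dataset, bg, pos, neg, loo_ids = g$gene_id)

round(f[1, c("MI_total", "H2", "G2", "KLD1", "MSCORE_POS", "MSCORE_NEG")], 4)
#>   MI_total     H2     G2   KLD1 MSCORE_POS MSCORE_NEG
#> 1   0.0824 3.9113 2.4247 0.0034    14.4277      7.819

res <- monte_carlo_cv(org$dataset, genome = org$genome, n_folds = 10, seed = 7)
res
#> <eval_result> intra_cv  train=WEAK test=WEAK
#>   mean AUC 0.992 over 10 fold(s)  (accuracy 0.950, F 0.951)

head(rank_features(under_sample(f, seed = 1)), 5)
#>    feature      gain
#> 1    MI_AG 0.5685316
#> 2       H2 0.5684738
#> 3 MI_total 0.5535072
#> 4    MI_CG 0.5346296
#> 5    MI_AC 0.5327878
```

Reading the output: the first gene's consecutive bases share 0.082 bits of
mutual information; its dinucleotide Shannon entropy is 3.91 of the
maximal 4 bits (gene sequences are close to random at block size 2); its
k = 1 composition sits 0.003 bits from the genome background; and it
scores 14.4 vs. 7.8 bits under the essential vs. non-essential chain — the
Markov features alone lean essential, correctly (gene 1 is labeled
essential). The 10-fold Monte Carlo AUC of 0.992 says the forest separates
the two weakly diverged sources almost perfectly at this sample size; on
the `null` preset (identical sources) the same pipeline reports AUC ≈ 0.5,
and mutual-information and entropy features dominate the information-gain
ranking.

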