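Package: itess
Title: Information-Theoretic Sequence Features for Gene Essentiality
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts bacterial gene essentiality from coding sequences
    alone. Extracts a fixed 91-dimensional vector of information-theoretic
    features per gene (mutual information and conditional mutual
    information over consecutive bases, Shannon and Gibbs entropies for
    block sizes 2 and 3, Kullback-Leibler divergences of k-mer
    distributions against a genome background, and log-likelihood scores
    under class-conditional Lidstone-smoothed Markov chains), trains
    Random Forest classifiers on balanced data, and evaluates them by
    Monte Carlo cross-validation, pairwise cross-organism prediction,
    leave-one-species-out, pooled cross-validation, and cross-taxon
    protocols with ROC/AUC metrics and information-gain feature ranking.
    A seeded synthetic-organism generator built on parameterized Markov
    sources makes the full pipeline testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
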