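# Small synthetic organisms for unit tests: same source structure as the
# shipped presets but fewer, shorter genes so individual tests stay fast.

test_matrix_pos <- function() {
  m <- matrix(0.2, 4, 4, dimnames = list(BASES, BASES))
  succ <- c(A = "C", C = "G", G = "T", T = "A")
  for (b in BASES) m[b, succ[[b]]] <- 0.4
  m
}

test_matrix_alt <- function() {
  m <- matrix(0.2, 4, 4, dimnames = list(BASES, BASES))
  succ <- c(A = "G", C = "T", G = "A", T = "C")
  for (b in BASES) m[b, succ[[b]]] <- 0.4
  m
}

make_test_config <- function(divergence, seed, n_essential = 15,
                             n_non_essential = 40, min_len = 120,
                             max_len = 240, genome_length = 3000,
                             organism = "TST") {
  synth_config(n_essential = n_essential, n_non_essential = n_non_essential,
               pos_source = source_spec(test_matrix_pos(),
                                        min_len = min_len, max_len = max_len),
               neg_source = source_spec(test_matrix_alt(),
                                        min_len = min_len, max_len = max_len),
               divergence = divergence, genome_length = genome_length,
               seed = seed, organism = organism)
}

make_test_org <- function(divergence, seed, ...) {
  generate_organism(make_test_config(divergence, seed, ...))
}

# A uniform background distribution (exact) for composition tests.
uniform_background <- function() {
  pmf <- lapply(1:3, function(k) {
    w <- BASES
    for (i in seq_len(k - 1)) w <- c(t(outer(w, BASES, paste0)))
    setNames(rep(1 / 4^k, 4^k), w)
  })
  names(pmf) <- as.character(1:3)
  structure(list(organism = "UNIF", pmf = pmf),
            class = "background_distribution")
}

# A 91-column feature frame where a single named feature carries the signal
# and every other feature is constant.
toy_feature_frame <- function(signal_feature, values, labels) {
  stopifnot(length(values) == length(labels))
  fmat <- matrix(0, nrow = length(values), ncol = 91,
                 dimnames = list(NULL, feature_names()))
  fmat[, signal_feature] <- values
  cbind(data.frame(gene_id = sprintf("t%03d", seq_along(values)),
                   organism = "TOY", label = labels,
                   stringsAsFactors = FALSE),
        as.data.frame(fmat))
}

# Extract features for an organism with chains fitted on its own labeled
# genes (leave-one-out guarded) and background from its genome.
features_of_org <- function(org, m = 1) {
  g <- org$dataset$genes
  pos <- fit_markov(g$sequence[g$label == "essential"], m = m,
                    class_tag = "positive")
  neg <- fit_markov(g$sequence[g$label == "non_essential"], m = m,
                    class_tag = "negative")
  bg <- suppressMessages(
    background_distribution(org$dataset$organism, genome = org$genome))
  suppressMessages(
    extract_features(org$dataset, bg, pos, neg, loo_ids = g$gene_id))
}

no_fold_leakage <- function(res) {
  all(mapply(function(tr, te) length(intersect(tr, te)) == 0,
             res$fold_train_ids, res$fold_test_ids))
}
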