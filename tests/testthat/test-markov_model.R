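test_that("Lidstone estimator reproduces hand-computed probabilities", {
  ch <- fit_markov("AAAA", m = 1, delta = 0.001)
  tr <- markov_transitions(ch)
  # contexts with a successor: AA observed 3 times
  expect_equal(tr["A", "A"], 3.001 / 3.004, tolerance = 1e-15)
  expect_equal(tr["A", "C"], 0.001 / 3.004, tolerance = 1e-15)
  expect_equal(tr["A", "G"], 0.001 / 3.004, tolerance = 1e-15)
  expect_equal(tr["A", "T"], 0.001 / 3.004, tolerance = 1e-15)
  # unseen contexts fall back to the uniform smoothed estimate
  for (ctx in c("C", "G", "T")) {
    expect_equal(unname(tr[ctx, ]), rep(0.25, 4), tolerance = 1e-15)
  }
})

test_that("transition rows sum to one and stay strictly positive", {
  set.seed(51)
  for (i in 1:8) {
    seqs <- replicate(sample(1:4, 1), random_seq(sample(10:80, 1)))
    m <- sample(0:2, 1)
    ch <- fit_markov(seqs, m = m, delta = 0.001)
    tr <- markov_transitions(ch)
    expect_equal(unname(rowSums(tr)), rep(1, nrow(tr)), tolerance = 1e-12)
    expect_true(all(tr > 0))
  }
})

test_that("huge pseudo-counts drive all transitions to uniform", {
  ch <- fit_markov(c("ACGTACGT", "GGGTTTAA"), m = 1, delta = 1e6)
  expect_equal(unname(as.vector(markov_transitions(ch))),
               rep(0.25, 16), tolerance = 1e-4)
})

test_that("scoring: i.i.d. chain scores zero, hand value, additivity", {
  # order-0 chain: conditional equals marginal for every sequence
  ch0 <- fit_markov(c("ACGGTA", "TTACG"), m = 0)
  expect_equal(score_sequence(ch0, "ACGTACGTAC"), 0, tolerance = 1e-12)
  expect_equal(score_sequence(ch0, "GGGG"), 0, tolerance = 1e-12)

  # hand substitution of the fitted probabilities, chain on "AAAA", m = 1
  ch <- fit_markov("AAAA", m = 1, delta = 0.001)
  p_word_AA <- 3.001 / (3 + 0.001 * 16)
  p_cond_AA <- 3.001 / 3.004
  p_base_A <- 4.001 / 4.004
  expect_equal(score_sequence(ch, "AAA"),
               2 * p_word_AA * log2(p_cond_AA / p_base_A), tolerance = 1e-12)

  # additivity: total equals the sum of independent per-position summands
  set.seed(52)
  ch2 <- fit_markov(replicate(3, random_seq(60)), m = 1)
  s <- random_seq(25)
  per_pos <- sapply(1:(nchar(s) - 1), function(i) {
    score_sequence(ch2, substr(s, i, i + 1))
  })
  expect_equal(score_sequence(ch2, s), sum(per_pos), tolerance = 1e-9)

  expect_error(score_sequence(ch, "A"), "shorter")
})

test_that("class score pair separates genes from a strong positive source", {
  cfg <- make_test_config(1.0, seed = 7, n_essential = 60,
                          n_non_essential = 60, min_len = 200, max_len = 400)
  org <- generate_organism(cfg)
  g <- org$dataset$genes
  pos_train <- g$sequence[g$label == "essential"]
  neg_train <- g$sequence[g$label == "non_essential"]
  # 200 fresh genes from the positive source
  fresh <- generate_organism(make_test_config(1.0, seed = 8,
                                              n_essential = 200,
                                              n_non_essential = 5,
                                              min_len = 200, max_len = 400))
  fresh_pos <- fresh$dataset$genes$sequence[
    fresh$dataset$genes$label == "essential"]
  wins <- vapply(fresh_pos, function(s) {
    sc <- markov_feature_pair(pos_train, neg_train, s)
    sc[["MSCORE_POS"]] > sc[["MSCORE_NEG"]]
  }, logical(1))
  expect_gte(mean(wins), 0.90)

  # held-out same-source mean score exceeds the other chain's (aggregate)
  chp <- fit_markov(pos_train, m = 1)
  chn <- fit_markov(neg_train, m = 1)
  mp <- mean(vapply(fresh_pos, function(s) score_sequence(chp, s), numeric(1)))
  mn <- mean(vapply(fresh_pos, function(s) score_sequence(chn, s), numeric(1)))
  expect_gt(mp, mn)
})

test_that("identical pools and order-0 chains give degenerate score pairs", {
  pool <- c("ACGTACGTAA", "GGTTACGGTA", "CCATAGGACT")
  sc <- markov_feature_pair(pool, pool, "ACGTACGT")
  expect_equal(sc[["MSCORE_POS"]], sc[["MSCORE_NEG"]])
  sc0 <- markov_feature_pair(pool, pool, "ACGTACGT", m = 0)
  expect_equal(unname(sc0), c(0, 0), tolerance = 1e-12)
  expect_error(markov_feature_pair(character(0), pool, "ACGT"), "non-empty")
})

test_that("scored training members are excluded from their own pool", {
  pool_pos <- c("ACGTACGTAA", "GGTTACGGTA")
  pool_neg <- c("CCATAGGACT", "TTGGCCAATT")
  sc <- markov_feature_pair(pool_pos, pool_neg, "ACGTACGTAA")
  ref <- score_sequence(fit_markov("GGTTACGGTA", m = 1), "ACGTACGTAA")
  expect_equal(sc[["MSCORE_POS"]], ref, tolerance = 1e-12)
  # leave-one-out count subtraction matches refitting without the sequence
  ch_all <- fit_markov(pool_pos, m = 1)
  ch_drop <- itess:::markov_drop_sequence(ch_all, "ACGTACGTAA")
  ch_refit <- fit_markov("GGTTACGGTA", m = 1)
  expect_equal(markov_transitions(ch_drop), markov_transitions(ch_refit),
               tolerance = 1e-12)
})

test_that("order estimation finds i.i.d. and order-1 sources", {
  set.seed(53)
  iid <- random_seq(200000)
  expect_identical(estimate_order(iid, max_order = 2, seed = 5), 0L)

  strong <- matrix(0.04, 4, 4, dimnames = list(BASES, BASES))
  succ <- c(A = "C", C = "G", G = "T", T = "A")
  for (b in BASES) strong[b, succ[[b]]] <- 0.88
  sp <- source_spec(strong, min_len = 30, max_len = 30)
  set.seed(54)
  chain_seq <- itess:::.gen_markov_seq(strong, rep(0.25, 4), 200000)
  expect_identical(estimate_order(chain_seq, max_order = 2, seed = 5), 1L)

  expect_identical(estimate_order("ACGTACGT", max_order = 0), 0L)
  expect_error(estimate_order(character(0), max_order = 2), "empty")
})

test_that("fit and score are deterministic and order-insensitive in the pool", {
  seqs <- c("ACGTACGGTT", "GGATCCATGA", "TTTACGGA")
  a <- fit_markov(seqs, m = 1)
  b <- fit_markov(rev(seqs), m = 1)
  expect_identical(a$counts_word, b$counts_word)
  expect_identical(score_sequence(a, "ACGTTACG"), score_sequence(b, "ACGTTACG"))
})
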