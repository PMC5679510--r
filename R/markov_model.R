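# Pooled word counts over a set of sequences; windows never span sequence
# boundaries (each sequence is counted separately and the counts summed).
pooled_word_counts <- function(sequences, k) {
  ok <- nchar(sequences) >= k
  if (!any(ok)) return(setNames(numeric(4^k), all_kmers(k)))
  colSums(kmer_count_matrix(sequences[ok], k))
}

#' Fit a Lidstone-smoothed Markov chain of order m
#'
#' Counts context and word occurrences pooled over the training sequences
#' (never across sequence boundaries) and forms transition probabilities
#' P(a | v) = (N(va) + delta) / (N(v) + 4 delta), where N(va) is the count
#' of the (m+1)-word va and N(v) the count of contexts v that have a
#' successor, so that every context's outgoing probabilities sum to exactly
#' one. The empirical word distributions over (m+1)-words and single bases
#' needed by \code{\link{score_sequence}} are estimated from the same pool
#' with the same pseudo-count convention,
#' (count + delta) / (total + delta 4^len).
#'
#' @param sequences Character vector of training DNA sequences.
#' @param m Chain order (nonnegative integer; 0 gives an i.i.d. model).
#' @param delta Lidstone pseudo-count, > 0 (default 0.001).
#' @param class_tag Optional tag ("positive"/"negative") recorded on the
#'   chain.
#' @return A \code{markov_chain} object holding the raw counts; transition
#'   and word probabilities are derived views (see
#'   \code{\link{markov_transitions}}).
#' @export
fit_markov <- function(sequences, m = 1, delta = 0.001, class_tag = NULL) {
  stopifnot(m >= 0, delta > 0)
  sequences <- as.character(sequences)
  if (length(sequences) == 0L) stop("empty training pool")
  if (sum(nchar(sequences)) <= m) stop("pooled sequence length must exceed m")
  structure(list(order = as.integer(m), delta = delta,
                 counts_word = pooled_word_counts(sequences, m + 1),
                 counts_base = pooled_word_counts(sequences, 1),
                 class_tag = class_tag),
            class = "markov_chain")
}

#' Transition matrix of a fitted chain
#'
#' @param chain A \code{markov_chain}.
#' @return Matrix of transition probabilities, one row per context in
#'   Omega^m (a single row for m = 0), columns A/C/G/T; every row sums to 1
#'   and every entry is > 0.
#' @export
markov_transitions <- function(chain) {
  m <- chain$order
  cw <- matrix(chain$counts_word, ncol = 4, byrow = TRUE,
               dimnames = list(all_kmers(m), DNA_BASES))
  (cw + chain$delta) / (rowSums(cw) + 4 * chain$delta)
}

# Lidstone-smoothed pmf over (m+1)-words from the training pool.
markov_word_pmf <- function(chain) {
  cw <- chain$counts_word
  (cw + chain$delta) / (sum(cw) + chain$delta * length(cw))
}

# Lidstone-smoothed single-base pmf from the training pool.
markov_base_pmf <- function(chain) {
  cb <- chain$counts_base
  (cb + chain$delta) / (sum(cb) + chain$delta * 4)
}

# Per-word summand weights of the scoring sum: for each (m+1)-word va,
# P(va) * log2( P(a | v) / P(a) ). A sequence's score is the inner product
# of these weights with its (m+1)-word counts.
markov_word_weights <- function(chain) {
  words <- names(chain$counts_word)
  trans <- markov_transitions(chain)
  wp <- markov_word_pmf(chain)
  bp <- markov_base_pmf(chain)
  last <- substr(words, chain$order + 1, chain$order + 1)
  cond <- if (chain$order == 0) {
    trans[1, last]  # single (empty) context
  } else {
    trans[cbind(substr(words, 1, chain$order), last)]
  }
  unname(wp * log2(cond / bp[last]))
}

#' Score a sequence under a fitted Markov chain
#'
#' Sums, over every position i = 1 .. L-m, the weighted log-likelihood
#' ratio P(b_i..b_{i+m}) log2( P(b_{i+m} | b_i..b_{i+m-1}) / P(b_{i+m}) ),
#' with the unconditional word and base probabilities taken from the
#' chain's training pool. The score measures how much better the chain's
#' transition structure explains the sequence than an i.i.d. model with the
#' pool's base composition; an order-0 chain scores every sequence 0.
#'
#' @param chain A \code{markov_chain}.
#' @param seq DNA string of length >= m + 1.
#' @return Score in bits.
#' @export
score_sequence <- function(chain, seq) {
  if (nchar(seq) < chain$order + 1) {
    stop("sequence shorter than m + 1 = ", chain$order + 1)
  }
  sum(kmer_counts(seq, chain$order + 1) * markov_word_weights(chain))
}

# Subtract one sequence's window counts from a chain (exact leave-one-out:
# identical to refitting the pool without that sequence).
markov_drop_sequence <- function(chain, seq) {
  k <- chain$order + 1
  if (nchar(seq) >= k) {
    chain$counts_word <- chain$counts_word - kmer_counts(seq, k)
  }
  chain$counts_base <- chain$counts_base - kmer_counts(seq, 1)
  if (any(chain$counts_word < 0) || any(chain$counts_base < 0)) {
    stop("sequence was not part of the chain's training pool")
  }
  chain
}

#' Class-conditional Markov score pair for one gene
#'
#' Fits chains on the essential (positive) and non-essential (negative)
#' training pools and scores the gene on both. If the gene's exact sequence
#' occurs in a pool it is excluded from that fit (leakage guard), so a
#' training-set member is never scored by a chain trained on itself.
#'
#' @param train_pos,train_neg Character vectors of training sequences.
#' @param gene DNA string to score.
#' @param m Chain order (default 1) or \code{"estimate"} to pick the order
#'   per class with \code{\link{estimate_order}}.
#' @param delta Lidstone pseudo-count.
#' @param max_order Cap used when \code{m = "estimate"}.
#' @param seed Seed for the order-estimation permutation test.
#' @return Named numeric vector \code{c(MSCORE_POS, MSCORE_NEG)} (bits).
#' @export
markov_feature_pair <- function(train_pos, train_neg, gene, m = 1,
                                delta = 0.001, max_order = 3, seed = 1) {
  if (length(train_pos) == 0L || length(train_neg) == 0L) {
    stop("both training pools must be non-empty")
  }
  pools <- list(positive = train_pos[train_pos != gene],
                negative = train_neg[train_neg != gene])
  if (any(lengths(pools) == 0L)) {
    stop("training pool empty after excluding the scored gene")
  }
  scores <- vapply(names(pools), function(tag) {
    mm <- if (identical(m, "estimate")) {
      estimate_order(pools[[tag]], max_order = max_order, seed = seed)
    } else m
    score_sequence(fit_markov(pools[[tag]], m = mm, delta = delta,
                              class_tag = tag), gene)
  }, numeric(1))
  setNames(unname(scores), c("MSCORE_POS", "MSCORE_NEG"))
}

# Conditional mutual information I(lag; cur | ctx) from parallel vectors of
# integer-coded lag/cur symbols (1..4) and a context grouping factor.
.cmi_of_triples <- function(lag, cur, ctx_split) {
  n <- length(lag)
  total <- 0
  for (idx in ctx_split) {
    jc <- tabulate((lag[idx] - 1L) * 4L + cur[idx], nbins = 16L)
    pj <- matrix(jc / length(idx), 4, 4, byrow = TRUE)
    pr <- rowSums(pj); pc <- colSums(pj)
    nz <- pj > 0
    mi <- sum(pj[nz] * log2(pj[nz] / outer(pr, pc)[nz]))
    total <- total + (length(idx) / n) * mi
  }
  total
}

#' Estimate the Markov order of a sequence pool
#'
#' Returns the smallest order m in 0..max_order at which the conditional
#' mutual information I(X_t; X_{t-m-1} | X_{t-1..t-m}) is no longer
#' significant, i.e. the symbol m+1 steps back carries no extra information
#' once the intervening m symbols are known. Significance is assessed by a
#' seeded permutation test: the lagged symbol is permuted within each
#' context group and the CMI recomputed (\code{n_perm} times); the observed
#' CMI is significant when its permutation p-value is below \code{alpha}.
#' If every tested order is significant, \code{max_order} is returned.
#'
#' @param sequences Character vector of DNA sequences (pooled).
#' @param max_order Largest order to test (>= 0).
#' @param alpha Significance level (default 0.05).
#' @param n_perm Number of permutations (default 199).
#' @param seed RNG seed for the permutations.
#' @return Estimated order, an integer in 0..max_order.
#' @export
estimate_order <- function(sequences, max_order, alpha = 0.05,
                           n_perm = 199, seed = 1) {
  stopifnot(max_order >= 0)
  sequences <- as.character(sequences)
  if (length(sequences) == 0L || sum(nchar(sequences)) == 0L) {
    stop("empty sequence pool")
  }
  if (max_order == 0L) return(0L)
  set.seed(seed)
  base_code <- setNames(1:4, DNA_BASES)
  for (m in 0:max_order) {
    win <- m + 2L
    if (sum(pmax(nchar(sequences) - win + 1L, 0)) < 4^(m + 1)) {
      warning("few windows for order ", m, " (< 4^(m+1)); estimate unstable")
    }
    lag <- integer(0); cur <- integer(0); ctx <- character(0)
    for (s in sequences) {
      L <- nchar(s)
      if (L < win) next
      starts <- seq_len(L - win + 1L)
      lag <- c(lag, base_code[substring(s, starts, starts)])
      cur <- c(cur, base_code[substring(s, starts + win - 1L, starts + win - 1L)])
      ctx <- c(ctx, if (m == 0) rep("", length(starts)) else
        substring(s, starts + 1L, starts + m))
    }
    if (length(lag) < 2L) return(as.integer(max(m - 1L, 0L)))
    split_idx <- split(seq_along(ctx), ctx)
    obs <- .cmi_of_triples(lag, cur, split_idx)
    perm <- vapply(seq_len(n_perm), function(i) {
      lag_p <- lag
      for (idx in split_idx) lag_p[idx] <- lag_p[idx][sample.int(length(idx))]
      .cmi_of_triples(lag_p, cur, split_idx)
    }, numeric(1))
    p_val <- (1 + sum(perm >= obs)) / (1 + n_perm)
    if (p_val >= alpha) return(as.integer(m))
  }
  as.integer(max_order)
}
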