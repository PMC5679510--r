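# Independent brute-force oracles: direct summation over the defining
# formulas, using substring extraction and explicit loops. They share no
# code with the package internals.

BASES <- c("A", "C", "G", "T")

chop <- function(seq, k) {
  n <- nchar(seq)
  substring(seq, 1:(n - k + 1), k:n)
}

oracle_mi <- function(seq) {
  pairs <- chop(seq, 2)
  terms <- c()
  for (x in BASES) for (y in BASES) {
    pxy <- mean(pairs == paste0(x, y))
    px <- mean(substr(pairs, 1, 1) == x)
    py <- mean(substr(pairs, 2, 2) == y)
    terms[paste0(x, y)] <- if (pxy > 0) pxy * log2(pxy / (px * py)) else 0
  }
  list(total = sum(terms), terms = terms[sort(names(terms))])
}

oracle_cmi <- function(seq) {
  tri <- chop(seq, 3)
  terms <- c()
  for (x in BASES) for (z in BASES) for (y in BASES) {
    pxzy <- mean(tri == paste0(x, z, y))
    pz <- mean(substr(tri, 2, 2) == z)
    pxz <- mean(substr(tri, 1, 2) == paste0(x, z))
    pzy <- mean(substr(tri, 2, 3) == paste0(z, y))
    terms[paste0(x, z, y)] <-
      if (pxzy > 0) pxzy * log2(pz * pxzy / (pxz * pzy)) else 0
  }
  list(total = sum(terms), terms = terms[sort(names(terms))])
}

oracle_shannon <- function(seq, N) {
  p <- table(chop(seq, N))
  p <- p / sum(p)
  -sum(p * log2(p))
}

oracle_kmer_pmf <- function(seq, k) {
  words <- chop(seq, k)
  words <- words[!grepl("[^ACGT]", words)]
  all_words <- BASES
  for (i in seq_len(k - 1)) all_words <- c(t(outer(all_words, BASES, paste0)))
  cnt <- sapply(all_words, function(w) sum(words == w))
  cnt / sum(cnt)
}

oracle_kld <- function(seq, genome, k, eps = 1e-6) {
  p <- oracle_kmer_pmf(seq, k)
  q <- oracle_kmer_pmf(genome, k)
  if (any(p > 0 & q == 0)) {
    q <- pmax(q, eps)
    q <- q / sum(q)
  }
  s <- 0
  for (i in seq_along(p)) if (p[i] > 0) s <- s + p[i] * log2(p[i] / q[i])
  s
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "essential"]
  neg <- scores[labels == "non_essential"]
  tot <- 0
  for (sp in pos) for (sn in neg) {
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  }
  tot / (length(pos) * length(neg))
}

oracle_info_gain <- function(x, essential) {
  ent <- function(labels) {
    if (length(labels) == 0) return(0)
    p <- mean(labels)
    if (p == 0 || p == 1) return(0)
    -p * log2(p) - (1 - p) * log2(1 - p)
  }
  h0 <- ent(essential)
  vals <- sort(unique(x))
  if (length(vals) < 2) return(0)
  thr <- (vals[-1] + vals[-length(vals)]) / 2
  best <- 0
  for (t in thr) {
    left <- essential[x <= t]; right <- essential[x > t]
    cond <- length(left) / length(x) * ent(left) +
      length(right) / length(x) * ent(right)
    best <- max(best, h0 - cond)
  }
  best
}

# Random test sequence from the current RNG stream.
random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
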