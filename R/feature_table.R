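#' Canonical names of the 91 features
#'
#' The frozen column order of every feature matrix: total mutual
#' information and its 16 per-pair terms (lexicographic), total conditional
#' mutual information and its 64 per-triplet terms (lexicographic), Shannon
#' and Gibbs entropies for block sizes 2 and 3, the three Kullback-Leibler
#' divergences (k = 1, 2, 3), and the two class-conditional Markov scores.
#'
#' @return Character vector of length 91.
#' @export
feature_names <- function() {
  c("MI_total", paste0("MI_", all_kmers(2)),
    "CMI_total", paste0("CMI_", all_kmers(3)),
    "H2", "H3", "G2", "G3",
    "KLD1", "KLD2", "KLD3",
    "MSCORE_POS", "MSCORE_NEG")
}

#' Extract the 91-feature matrix for an organism dataset
#'
#' Computes, for every gene, the full feature vector: MI and CMI totals and
#' per-term features, Shannon and Gibbs entropies (block sizes 2 and 3),
#' KLD against the supplied background, and the scores under the positive
#' (essential) and negative (non-essential) Markov chains. Chains and
#' background must be fitted on designated training material only; for
#' genes listed in \code{loo_ids} whose sequences contributed to a chain's
#' pool, that gene's own window counts are subtracted from its class chain
#' before scoring (exact leave-one-out), so no gene is scored by a chain
#' trained on itself.
#'
#' Genes shorter than 3 nt are dropped with a message; any non-finite
#' feature value aborts with the offending gene and feature named.
#'
#' @param dataset An \code{organism_dataset}.
#' @param background A \code{\link{background_distribution}}.
#' @param pos_chain,neg_chain \code{markov_chain}s for the essential and
#'   non-essential classes.
#' @param table An \code{\link{energy_table}}.
#' @param loo_ids Gene ids whose sequences are in their own class chain's
#'   training pool (typically the training split itself).
#' @param kld_epsilon Zero-background floor for the KLD features.
#' @return A data frame with columns \code{gene_id}, \code{organism},
#'   \code{label}, then the 91 canonical feature columns.
#' @export
extract_features <- function(dataset, background, pos_chain, neg_chain,
                             table = energy_table(), loo_ids = NULL,
                             kld_epsilon = 1e-6) {
  stopifnot(inherits(dataset, "organism_dataset"),
            inherits(background, "background_distribution"),
            inherits(pos_chain, "markov_chain"),
            inherits(neg_chain, "markov_chain"))
  genes <- dataset$genes
  min_len <- max(3L, pos_chain$order + 1L, neg_chain$order + 1L)
  short <- nchar(genes$sequence) < min_len
  if (any(short)) {
    message("dropping ", sum(short), " gene(s) shorter than ", min_len, " nt: ",
            paste(head(genes$gene_id[short], 5), collapse = ", "))
    genes <- genes[!short, , drop = FALSE]
  }
  if (nrow(genes) == 0L) stop("no genes left to extract features from")

  cnt1 <- kmer_count_matrix(genes$sequence, 1)
  cnt2 <- kmer_count_matrix(genes$sequence, 2)
  cnt3 <- kmer_count_matrix(genes$sequence, 3)
  we2 <- .word_energies(2, table$energies)
  we3 <- .word_energies(3, table$energies)
  w_pos <- markov_word_weights(pos_chain)
  w_neg <- markov_word_weights(neg_chain)
  cnt_pos <- if (pos_chain$order == 1) cnt2 else
    kmer_count_matrix(genes$sequence, pos_chain$order + 1)
  cnt_neg <- if (neg_chain$order == 1) cnt2 else
    kmer_count_matrix(genes$sequence, neg_chain$order + 1)

  fmat <- matrix(NA_real_, nrow = nrow(genes), ncol = 91,
                 dimnames = list(NULL, feature_names()))
  for (i in seq_len(nrow(genes))) {
    mi <- .mi_from_counts(cnt2[i, ])
    cmi <- .cmi_from_counts(cnt3[i, ])
    kld <- vapply(1:3, function(k) {
      .kld_from_counts(list(cnt1, cnt2, cnt3)[[k]][i, ],
                       background$pmf[[as.character(k)]],
                       epsilon = kld_epsilon, label = k)
    }, numeric(1))
    loo <- genes$gene_id[i] %in% loo_ids
    sp <- if (loo && genes$label[i] == "essential") {
      ch <- markov_drop_sequence(pos_chain, genes$sequence[i])
      sum(cnt_pos[i, ] * markov_word_weights(ch))
    } else sum(cnt_pos[i, ] * w_pos)
    sn <- if (loo && genes$label[i] == "non_essential") {
      ch <- markov_drop_sequence(neg_chain, genes$sequence[i])
      sum(cnt_neg[i, ] * markov_word_weights(ch))
    } else sum(cnt_neg[i, ] * w_neg)
    fmat[i, ] <- c(mi$total, mi$terms, cmi$total, cmi$terms,
                   .shannon_from_counts(cnt2[i, ]),
                   .shannon_from_counts(cnt3[i, ]),
                   .gibbs_from_counts(cnt2[i, ], we2, table$temperature_K),
                   .gibbs_from_counts(cnt3[i, ], we3, table$temperature_K),
                   kld, sp, sn)
  }
  bad <- which(!is.finite(fmat), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-finite feature value: gene ", genes$gene_id[bad[1, 1]],
         ", feature ", feature_names()[bad[1, 2]])
  }
  org <- if (!is.null(genes$organism)) genes$organism else dataset$organism
  cbind(data.frame(gene_id = genes$gene_id, organism = org,
                   label = genes$label, stringsAsFactors = FALSE),
        as.data.frame(fmat))
}

#' Write / read a feature matrix as CSV
#'
#' The CSV header is \code{gene_id, organism, label} followed by the 91
#' canonical feature names; \code{read_feature_matrix} rejects any file
#' whose header deviates, naming the first offending column.
#'
#' @param features Feature data frame from \code{\link{extract_features}}.
#' @param path Output (input) CSV path.
#' @return \code{write_feature_matrix}: invisibly, \code{path};
#'   \code{read_feature_matrix}: the feature data frame.
#' @export
write_feature_matrix <- function(features, path) {
  expected <- c("gene_id", "organism", "label", feature_names())
  if (!is.data.frame(features) || nrow(features) == 0L) {
    stop("empty feature collection; nothing written")
  }
  if (!identical(names(features), expected)) {
    stop("feature columns do not match the canonical layout")
  }
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  expected <- c("gene_id", "organism", "label", feature_names())
  if (!identical(names(df), expected)) {
    missing <- setdiff(expected, names(df))
    extra <- setdiff(names(df), expected)
    off <- if (length(missing)) missing[1] else if (length(extra)) extra[1] else
      names(df)[which(names(df) != expected)[1]]
    stop("feature matrix header mismatch at column: ", off)
  }
  df
}
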