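# ---- class balancing ------------------------------------------------------

# Balance using the current RNG stream (callers manage seeding).
.balance <- function(df) {
  ess <- which(df$label == "essential")
  non <- which(df$label == "non_essential")
  if (length(ess) == 0L || length(non) == 0L) {
    stop("both classes must be present to balance")
  }
  if (length(non) <= length(ess)) {
    message("non-essential class not larger than essential; no under-sampling")
    return(df[c(ess, non), , drop = FALSE])
  }
  keep <- sort(c(ess, sample(non, length(ess))))
  df[keep, , drop = FALSE]
}

#' Balance classes by random under-sampling of non-essentials
#'
#' Keeps every essential row and a uniform random subset of non-essential
#' rows of equal size. When non-essentials are not in the majority the
#' input is returned unchanged (the method never over-samples).
#'
#' @param df Data frame with a \code{label} column
#'   (\code{essential}/\code{non_essential}); feature matrices and gene
#'   tables both work.
#' @param seed RNG seed; the same seed always selects the same subset.
#' @return The balanced data frame.
#' @export
under_sample <- function(df, seed = 1) {
  set.seed(seed)
  .balance(df)
}

# ---- Random Forest --------------------------------------------------------

#' Train a Random Forest on a balanced feature matrix
#'
#' Probability forest over the 91 canonical features; the essentiality
#' score of a gene is the fraction of trees voting essential. Defaults:
#' 100 trees, unlimited depth, sqrt(91) candidate features per split.
#'
#' @param train Feature data frame (see \code{\link{extract_features}})
#'   with both classes present, typically balanced.
#' @param n_trees Number of trees.
#' @param max_depth Maximal tree depth; \code{NULL} = unlimited.
#' @param mtry Features tried per split; \code{NULL} = floor(sqrt(91)).
#' @param seed RNG seed; training is deterministic given the seed.
#' @return An \code{itess_rf} model.
#' @export
train_rf <- function(train, n_trees = 100, max_depth = NULL, mtry = NULL,
                     seed = 1) {
  fn <- feature_names()
  if (!all(fn %in% names(train))) {
    stop("training data missing feature column(s): ",
         paste(head(setdiff(fn, names(train)), 3), collapse = ", "))
  }
  if (nrow(train) == 0L) stop("empty training set")
  dat <- data.frame(label = factor(train$label,
                                   levels = c("essential", "non_essential")),
                    train[fn], check.names = FALSE)
  rf <- ranger::ranger(dependent.variable.name = "label", data = dat,
                       num.trees = n_trees,
                       mtry = if (is.null(mtry)) floor(sqrt(length(fn))) else mtry,
                       max.depth = if (is.null(max_depth)) 0 else max_depth,
                       probability = TRUE, seed = seed, num.threads = 1)
  structure(list(forest = rf, feature_names = fn), class = "itess_rf")
}

#' Score genes with a trained forest
#'
#' @param model An \code{itess_rf} from \code{\link{train_rf}}.
#' @param test Feature data frame with the canonical feature columns.
#' @return Numeric vector of essentiality scores in [0, 1].
#' @export
predict_scores <- function(model, test) {
  stopifnot(inherits(model, "itess_rf"))
  if (!all(model$feature_names %in% names(test))) {
    stop("test data missing feature column(s): ",
         paste(head(setdiff(model$feature_names, names(test)), 3), collapse = ", "))
  }
  pr <- predict(model$forest, data = test[model$feature_names],
                num.threads = 1)$predictions
  unname(pr[, "essential"])
}

# ---- metrics --------------------------------------------------------------

.as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("essential", "non_essential"))
  if (length(bad)) stop("unknown label value(s): ", paste(bad, collapse = ", "))
  labels == "essential"
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' The AUC is the probability that a random essential gene scores above a
#' random non-essential one, with tied scores counting one half --
#' computed from rank sums, equivalent to counting concordant pairs.
#'
#' @param scores Numeric scores (larger = more essential).
#' @param labels Labels (\code{essential}/\code{non_essential}, factor, or
#'   logical with \code{TRUE} = essential); both classes must be present.
#' @return List with \code{auc} and \code{roc_points}, a data frame of
#'   (fpr, tpr) starting at (0, 0) and ending at (1, 1), nondecreasing in
#'   both coordinates.
#' @export
roc_auc <- function(scores, labels) {
  pos <- .as_positive(labels)
  stopifnot(length(scores) == length(pos))
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) stop("both classes required for ROC/AUC")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  last_of_tie <- c(diff(scores[ord]) != 0, TRUE)
  pts <- data.frame(fpr = c(0, fp[last_of_tie] / n_neg),
                    tpr = c(0, tp[last_of_tie] / n_pos))
  list(auc = auc, roc_points = pts)
}

#' Accuracy and F-measure at a fixed score threshold
#'
#' @param scores Numeric scores in [0, 1].
#' @param labels Labels as in \code{\link{roc_auc}}.
#' @param threshold Genes with score >= threshold are called essential
#'   (default 0.5).
#' @return Named vector \code{c(accuracy, f_measure)}; an undefined F
#'   (no predicted or no actual positives) is reported as 0 with a warning.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  pos <- .as_positive(labels)
  pred <- scores >= threshold
  tp <- sum(pred & pos); fp <- sum(pred & !pos); fn <- sum(!pred & pos)
  accuracy <- mean(pred == pos)
  if (2 * tp + fp + fn == 0) {
    warning("F-measure undefined (no predicted or actual positives); reporting 0")
    f <- 0
  } else {
    f <- 2 * tp / (2 * tp + fp + fn)
    if (tp == 0 && (fp == 0 || fn == 0)) {
      warning("degenerate confusion matrix; F-measure is 0")
    }
  }
  c(accuracy = accuracy, f_measure = f)
}

# ---- evaluation harness ---------------------------------------------------

new_eval_result <- function(mode, train_id, test_id, fold_aucs, roc_points,
                            f_measure, accuracy, seed, fold_train_ids,
                            fold_test_ids) {
  structure(list(mode = mode, train_id = train_id, test_id = test_id,
                 fold_aucs = fold_aucs, mean_auc = mean(fold_aucs),
                 roc_points = roc_points, f_measure = f_measure,
                 accuracy = accuracy, n_folds = length(fold_aucs),
                 seed = seed, fold_train_ids = fold_train_ids,
                 fold_test_ids = fold_test_ids),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s  train=%s test=%s\n", x$mode, x$train_id,
              x$test_id))
  cat(sprintf("  mean AUC %.3f over %d fold(s)  (accuracy %.3f, F %.3f)\n",
              x$mean_auc, x$n_folds, x$accuracy, x$f_measure))
  invisible(x)
}

.eval_params <- function(n_trees = 100, max_depth = NULL, mtry = NULL,
                         markov_order = 1, delta = 0.001,
                         table = energy_table(), kld_epsilon = 1e-6,
                         max_order = 3) {
  list(n_trees = n_trees, max_depth = max_depth, mtry = mtry,
       markov_order = markov_order, delta = delta, table = table,
       kld_epsilon = kld_epsilon, max_order = max_order)
}

# Fit chains + background on the training side, extract features for both
# sides, train and score. Uses the current RNG stream for the forest seed.
.run_split <- function(train_genes, test_genes, genome, train_tag, test_tag,
                       params) {
  pos <- train_genes$sequence[train_genes$label == "essential"]
  neg <- train_genes$sequence[train_genes$label == "non_essential"]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("training side must contain both classes")
  }
  m <- params$markov_order
  fit_class <- function(seqs, tag) {
    mm <- if (identical(m, "estimate")) {
      estimate_order(seqs, max_order = params$max_order,
                     seed = sample.int(1e9, 1))
    } else m
    fit_markov(seqs, m = mm, delta = params$delta, class_tag = tag)
  }
  pos_chain <- fit_class(pos, "positive")
  neg_chain <- fit_class(neg, "negative")
  bg <- suppressMessages(background_distribution(
    train_tag, genome = genome,
    sequences = if (is.null(genome)) train_genes$sequence else NULL))
  train_ds <- new_organism_dataset(train_tag, train_genes)
  test_ds <- new_organism_dataset(test_tag, test_genes)
  ftr <- extract_features(train_ds, bg, pos_chain, neg_chain,
                          table = params$table,
                          loo_ids = train_genes$gene_id,
                          kld_epsilon = params$kld_epsilon)
  fte <- extract_features(test_ds, bg, pos_chain, neg_chain,
                          table = params$table,
                          kld_epsilon = params$kld_epsilon)
  model <- train_rf(ftr, n_trees = params$n_trees,
                    max_depth = params$max_depth, mtry = params$mtry,
                    seed = sample.int(1e9, 1))
  scores <- predict_scores(model, fte)
  list(scores = scores, labels = fte$label,
       train_ids = ftr$gene_id, test_ids = fte$gene_id)
}

.labeled_genes <- function(dataset) {
  g <- dataset$genes[dataset$genes$label != "unknown", , drop = FALSE]
  if (nrow(g) == 0L) stop("dataset ", dataset$organism, " has no labeled genes")
  g
}

# Pool labeled genes of several datasets; gene ids are prefixed with the
# organism tag to stay unique, and a per-gene organism column is kept.
.pool_datasets <- function(datasets) {
  parts <- lapply(datasets, function(d) {
    g <- .labeled_genes(d)
    data.frame(gene_id = paste(d$organism, g$gene_id, sep = ":"),
               organism = d$organism, sequence = g$sequence,
               label = g$label, stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Monte Carlo cross-validation within one organism
#'
#' Repeats, \code{n_folds} times: under-sample non-essentials to balance,
#' split the balanced set 80/20 stratified by class, refit the
#' class-conditional Markov chains (and, when no genome is supplied, the
#' KLD background) on the training side only, extract features on both
#' sides, train a Random Forest, and score the held-out 20\%. Reports the
#' per-fold AUCs, their mean, mean accuracy/F at threshold 0.5 and the ROC
#' of the pooled fold scores.
#'
#' @param dataset A labeled \code{organism_dataset}.
#' @param genome Optional genome string for the KLD background; when
#'   \code{NULL} the background is refit per fold from training-side genes.
#' @param n_folds Number of Monte Carlo repetitions (default 100).
#' @param train_frac Training fraction in (0, 1) (default 0.8).
#' @param seed Master RNG seed; fixes the balancing, the splits and the
#'   forests.
#' @param ... Further parameters passed to the internal harness:
#'   \code{n_trees}, \code{max_depth}, \code{mtry}, \code{markov_order}
#'   (an order or \code{"estimate"}), \code{delta}, \code{table},
#'   \code{kld_epsilon}, \code{max_order}.
#' @return An \code{eval_result} with mode \code{"intra_cv"}.
#' @export
monte_carlo_cv <- function(dataset, genome = NULL, n_folds = 100,
                           train_frac = 0.8, seed = 1, ...) {
  params <- .eval_params(...)
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must lie strictly between 0 and 1")
  }
  genes <- .labeled_genes(dataset)
  set.seed(seed)
  aucs <- numeric(n_folds)
  acc <- numeric(n_folds); fm <- numeric(n_folds)
  all_scores <- numeric(0); all_labels <- character(0)
  tr_ids <- vector("list", n_folds); te_ids <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    bal <- .balance(genes)
    tr_idx <- integer(0)
    for (cl in c("essential", "non_essential")) {
      cl_idx <- which(bal$label == cl)
      n_tr <- floor(train_frac * length(cl_idx))
      if (n_tr < 1L || n_tr >= length(cl_idx)) {
        stop("class ", cl, " too small to split at train_frac = ", train_frac)
      }
      tr_idx <- c(tr_idx, sample(cl_idx, n_tr))
    }
    res <- .run_split(bal[tr_idx, , drop = FALSE],
                      bal[-tr_idx, , drop = FALSE],
                      genome, dataset$organism, dataset$organism, params)
    ra <- roc_auc(res$scores, res$labels)
    tm <- threshold_metrics(res$scores, res$labels)
    aucs[f] <- ra$auc; acc[f] <- tm[["accuracy"]]; fm[f] <- tm[["f_measure"]]
    all_scores <- c(all_scores, res$scores)
    all_labels <- c(all_labels, res$labels)
    tr_ids[[f]] <- res$train_ids; te_ids[[f]] <- res$test_ids
  }
  new_eval_result("intra_cv", dataset$organism, dataset$organism, aucs,
                  roc_auc(all_scores, all_labels)$roc_points,
                  mean(fm), mean(acc), seed, tr_ids, te_ids)
}

#' Pairwise cross-organism prediction
#'
#' Balances the training organism's labeled genes, fits chains, background
#' and forest on them, and scores every labeled gene of the distinct test
#' organism. The KLD background is the training organism's (its genome
#' when supplied, else its balanced training genes).
#'
#' @param train_org,test_org Labeled \code{organism_dataset}s with
#'   different organism tags.
#' @param train_genome Optional training-organism genome string.
#' @param seed Master RNG seed.
#' @param ... Harness parameters (see \code{\link{monte_carlo_cv}}).
#' @return An \code{eval_result} with mode \code{"pairwise"}.
#' @export
pairwise_cross <- function(train_org, test_org, train_genome = NULL,
                           seed = 1, ...) {
  params <- .eval_params(...)
  if (identical(train_org$organism, test_org$organism)) {
    stop("train and test organism are identical; use monte_carlo_cv")
  }
  set.seed(seed)
  bal <- .balance(.labeled_genes(train_org))
  res <- .run_split(bal, .labeled_genes(test_org), train_genome,
                    train_org$organism, test_org$organism, params)
  ra <- roc_auc(res$scores, res$labels)
  tm <- threshold_metrics(res$scores, res$labels)
  new_eval_result("pairwise", train_org$organism, test_org$organism, ra$auc,
                  ra$roc_points, tm[["f_measure"]], tm[["accuracy"]], seed,
                  list(res$train_ids), list(res$test_ids))
}

#' Leave-one-species-out prediction
#'
#' Pools the labeled genes of every organism except the held-out one,
#' balances the pool, fits chains, background and forest on it, and scores
#' the held-out organism's labeled genes.
#'
#' @param all_orgs List of labeled \code{organism_dataset}s (>= 2).
#' @param held_out Organism tag to hold out.
#' @param seed Master RNG seed.
#' @param ... Harness parameters (see \code{\link{monte_carlo_cv}}).
#' @return An \code{eval_result} with mode \code{"loso"}.
#' @export
leave_one_species_out <- function(all_orgs, held_out, seed = 1, ...) {
  params <- .eval_params(...)
  tags <- vapply(all_orgs, function(d) d$organism, character(1))
  if (!held_out %in% tags) stop("held-out organism not found: ", held_out)
  if (length(all_orgs) < 2L) stop("need at least 2 organisms")
  set.seed(seed)
  train_pool <- .pool_datasets(all_orgs[tags != held_out])
  bal <- .balance(train_pool)
  test_genes <- .labeled_genes(all_orgs[[which(tags == held_out)]])
  res <- .run_split(bal, test_genes, NULL,
                    paste(sort(tags[tags != held_out]), collapse = "+"),
                    held_out, params)
  ra <- roc_auc(res$scores, res$labels)
  tm <- threshold_metrics(res$scores, res$labels)
  new_eval_result("loso", paste(sort(tags[tags != held_out]), collapse = "+"),
                  held_out, ra$auc, ra$roc_points, tm[["f_measure"]],
                  tm[["accuracy"]], seed, list(res$train_ids),
                  list(res$test_ids))
}

#' Pooled k-fold cross-validation over all organisms
#'
#' Assigns every labeled gene of every organism to one of \code{n_folds}
#' folds, stratified by organism and label, then tests each fold against a
#' model trained on the balanced union of the other folds.
#'
#' @param all_orgs List of labeled \code{organism_dataset}s.
#' @param n_folds Number of folds (default 5).
#' @param seed Master RNG seed.
#' @param ... Harness parameters (see \code{\link{monte_carlo_cv}}).
#' @return An \code{eval_result} with mode \code{"pooled_cv"}.
#' @export
pooled_cv <- function(all_orgs, n_folds = 5, seed = 1, ...) {
  params <- .eval_params(...)
  set.seed(seed)
  pool <- .pool_datasets(all_orgs)
  fold <- integer(nrow(pool))
  for (s in split(seq_len(nrow(pool)), paste(pool$organism, pool$label))) {
    fold[s[sample.int(length(s))]] <- rep_len(seq_len(n_folds), length(s))
  }
  aucs <- numeric(n_folds); acc <- numeric(n_folds); fm <- numeric(n_folds)
  all_scores <- numeric(0); all_labels <- character(0)
  tr_ids <- vector("list", n_folds); te_ids <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    bal <- .balance(pool[fold != f, , drop = FALSE])
    res <- .run_split(bal, pool[fold == f, , drop = FALSE], NULL,
                      "pool", "pool", params)
    ra <- roc_auc(res$scores, res$labels)
    tm <- threshold_metrics(res$scores, res$labels)
    aucs[f] <- ra$auc; acc[f] <- tm[["accuracy"]]; fm[f] <- tm[["f_measure"]]
    all_scores <- c(all_scores, res$scores)
    all_labels <- c(all_labels, res$labels)
    tr_ids[[f]] <- res$train_ids; te_ids[[f]] <- res$test_ids
  }
  new_eval_result("pooled_cv", "pool", "pool", aucs,
                  roc_auc(all_scores, all_labels)$roc_points,
                  mean(fm), mean(acc), seed, tr_ids, te_ids)
}

#' Cross-taxon and leave-one-taxon-out prediction
#'
#' Groups organisms into taxonomic orders and repeats the cross-organism
#' protocols at the taxon level: \code{cross_taxon} trains on each taxon's
#' pooled organisms and tests on every other taxon (all ordered pairs);
#' \code{leave_taxon_out} trains on all other taxa pooled and tests each
#' held-out taxon.
#'
#' @param all_orgs List of labeled \code{organism_dataset}s.
#' @param taxa Named list mapping taxon name to a character vector of
#'   organism tags; an organism may appear in at most one taxon.
#' @param mode \code{"cross_taxon"} or \code{"leave_taxon_out"}.
#' @param seed Master RNG seed.
#' @param ... Harness parameters (see \code{\link{monte_carlo_cv}}).
#' @return List of \code{eval_result}s (one per ordered taxon pair, or one
#'   per held-out taxon).
#' @export
taxon_eval <- function(all_orgs, taxa, mode = c("cross_taxon",
                                                "leave_taxon_out"),
                       seed = 1, ...) {
  mode <- match.arg(mode)
  params <- .eval_params(...)
  tags <- vapply(all_orgs, function(d) d$organism, character(1))
  all_members <- unlist(taxa, use.names = FALSE)
  missing <- setdiff(all_members, tags)
  if (length(missing)) {
    stop("organism(s) in taxon config absent from data: ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(all_members)) {
    stop("organism(s) assigned to more than one taxon: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  }
  if (length(taxa) < 2L) stop("need at least 2 taxa")
  set.seed(seed)
  taxon_pool <- lapply(taxa, function(members) {
    .pool_datasets(all_orgs[tags %in% members])
  })
  run_one <- function(train_genes, test_genes, train_id, test_id) {
    bal <- .balance(train_genes)
    res <- .run_split(bal, test_genes, NULL, train_id, test_id, params)
    ra <- roc_auc(res$scores, res$labels)
    tm <- threshold_metrics(res$scores, res$labels)
    new_eval_result(mode, train_id, test_id, ra$auc, ra$roc_points,
                    tm[["f_measure"]], tm[["accuracy"]], seed,
                    list(res$train_ids), list(res$test_ids))
  }
  out <- list()
  if (mode == "cross_taxon") {
    for (tr in names(taxa)) {
      for (te in names(taxa)) {
        if (tr == te) next
        out[[paste(tr, te, sep = "->")]] <-
          run_one(taxon_pool[[tr]], taxon_pool[[te]], tr, te)
      }
    }
  } else {
    for (te in names(taxa)) {
      train_genes <- do.call(rbind, taxon_pool[setdiff(names(taxa), te)])
      out[[te]] <- run_one(train_genes, taxon_pool[[te]],
                           paste(sort(setdiff(names(taxa), te)),
                                 collapse = "+"), te)
    }
  }
  out
}

# ---- information-gain feature ranking -------------------------------------

.binary_entropy <- function(p) {
  h <- numeric(length(p))
  in01 <- p > 0 & p < 1
  h[in01] <- -p[in01] * log2(p[in01]) - (1 - p[in01]) * log2(1 - p[in01])
  h
}

# Information gain of the best single-threshold split on one feature.
.info_gain <- function(x, pos) {
  n <- length(x)
  h0 <- .binary_entropy(mean(pos))
  ord <- order(x)
  xs <- x[ord]; ys <- pos[ord]
  i <- which(diff(xs) > 0)  # split between positions i and i+1
  if (length(i) == 0L) return(0)
  cp <- cumsum(ys)
  cond <- (i / n) * .binary_entropy(cp[i] / i) +
    ((n - i) / n) * .binary_entropy((sum(ys) - cp[i]) / (n - i))
  max(h0 - cond)
}

#' Rank the 91 features by information gain
#'
#' For each feature, the gain is the label entropy minus the weighted
#' class entropy of the best single-threshold split on that feature
#' (all midpoints between distinct sorted values are examined).
#'
#' @param train Feature data frame with both classes present.
#' @return A \code{feature_ranking}: data frame (feature, gain) sorted by
#'   nonincreasing gain, 91 rows.
#' @export
rank_features <- function(train) {
  pos <- .as_positive(train$label)
  if (all(pos) || !any(pos)) stop("both classes required to rank features")
  fn <- feature_names()
  gains <- vapply(fn, function(f) .info_gain(train[[f]], pos), numeric(1))
  out <- data.frame(feature = fn, gain = unname(gains),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$gain), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("feature_ranking", "data.frame"))
}

#' Top-k features of a ranking
#'
#' @param ranking A \code{feature_ranking} from \code{\link{rank_features}}.
#' @param k Number of features to keep (<= number ranked).
#' @return Character vector of the k top feature names.
#' @export
select_top_k <- function(ranking, k) {
  if (k > nrow(ranking)) {
    stop("k = ", k, " exceeds the ", nrow(ranking), " ranked features")
  }
  ranking$feature[seq_len(k)]
}
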