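test_that("under-sampling balances classes, never over-samples, reproducible", {
  df <- data.frame(gene_id = sprintf("g%03d", 1:330),
                   label = rep(c("essential", "non_essential"), c(30, 300)),
                   stringsAsFactors = FALSE)
  bal <- under_sample(df, seed = 3)
  expect_equal(sum(bal$label == "essential"), 30)
  expect_equal(sum(bal$label == "non_essential"), 30)
  expect_true(all(df$gene_id[df$label == "essential"] %in% bal$gene_id))

  df2 <- data.frame(label = rep(c("essential", "non_essential"), c(30, 20)))
  expect_message(bal2 <- under_sample(df2, seed = 3), "no under-sampling")
  expect_equal(nrow(bal2), 50)

  expect_identical(under_sample(df, seed = 7), under_sample(df, seed = 7))
  expect_error(under_sample(df[df$label == "essential", , drop = FALSE]),
               "both classes")
})

test_that("forest separates the training set of a separable organism", {
  org <- make_test_org(1.0, seed = 14)
  f <- features_of_org(org)
  bal <- under_sample(f, seed = 1)
  model <- train_rf(bal, seed = 5)
  auc <- roc_auc(predict_scores(model, bal), bal$label)$auc
  expect_gte(auc, 0.99)
})

test_that("a depth-1 single tree on one separating feature yields 0/1 scores", {
  labels <- rep(c("essential", "non_essential"), each = 10)
  toy <- toy_feature_frame("H2", rep(c(1, 0), each = 10), labels)
  model <- train_rf(toy, n_trees = 1, max_depth = 1, mtry = 91, seed = 2)
  sc <- predict_scores(model, toy)
  expect_true(all(sc %in% c(0, 1)))
  expect_equal(sc, as.numeric(labels == "essential"))
})

test_that("held-out AUC under permuted labels hovers around chance", {
  org <- make_test_org(1.0, seed = 15, n_essential = 30, n_non_essential = 30)
  f <- features_of_org(org)
  set.seed(16)
  aucs <- replicate(20, {
    f$label <- sample(f$label)
    tr <- unlist(lapply(split(seq_len(nrow(f)), f$label),
                        function(i) sample(i, floor(0.8 * length(i)))))
    model <- train_rf(f[tr, ], seed = sample.int(1e6, 1))
    roc_auc(predict_scores(model, f[-tr, ]), f$label[-tr])$auc
  })
  expect_gte(mean(aucs), 0.35)
  expect_lte(mean(aucs), 0.65)
})

test_that("rank-based AUC matches exhaustive pair concordance", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("essential", "essential",
                         "non_essential", "non_essential"))$auc, 1.0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.8, 0.1),
                       c("essential", "essential",
                         "non_essential", "non_essential"))$auc, 0.875)
  expect_equal(roc_auc(rep(0.4, 6),
                       rep(c("essential", "non_essential"), 3))$auc, 0.5)
  set.seed(61)
  for (i in 1:10) {
    n <- sample(4:50, 1)
    labels <- sample(rep(c("essential", "non_essential"), each = 2))
    labels <- c(labels, sample(c("essential", "non_essential"), n - 4,
                               replace = TRUE))
    scores <- round(runif(n), 2)  # rounding forces ties
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
  }
  expect_error(roc_auc(c(.1, .2), c("essential", "essential")), "both classes")
})

test_that("rank-based AUC agrees with an independent ROC library", {
  set.seed(62)
  scores <- round(runif(40), 2)
  labels <- sample(c("essential", "non_essential"), 40, replace = TRUE,
                   prob = c(0.4, 0.6))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("non_essential",
                                                      "essential"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("ROC points are monotone from (0,0) to (1,1)", {
  set.seed(63)
  pts <- roc_auc(runif(30), sample(c("essential", "non_essential"), 30,
                                   replace = TRUE))$roc_points
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("threshold metrics reproduce hand confusion matrices", {
  lab <- rep(c("essential", "non_essential"), each = 4)
  perfect <- threshold_metrics(c(rep(.9, 4), rep(.1, 4)), lab)
  expect_equal(unname(perfect), c(1, 1))
  all_pos <- threshold_metrics(rep(0.9, 8), lab)
  expect_equal(all_pos[["accuracy"]], 0.5)
  expect_equal(all_pos[["f_measure"]], 2 / 3, tolerance = 1e-12)
  expect_warning(none <- threshold_metrics(rep(0.1, 8), lab), "F-measure")
  expect_equal(none[["f_measure"]], 0)
})

test_that("Monte Carlo CV recovers a separable organism and is seeded", {
  org <- make_test_org(1.0, seed = 17, n_essential = 25, n_non_essential = 60)
  res <- suppressMessages(monte_carlo_cv(org$dataset, genome = org$genome,
                                         n_folds = 5, seed = 19))
  expect_s3_class(res, "eval_result")
  expect_length(res$fold_aucs, 5)
  expect_gte(res$mean_auc, 0.9)
  expect_equal(res$mean_auc, mean(res$fold_aucs), tolerance = 1e-12)
  expect_true(no_fold_leakage(res))

  res2 <- suppressMessages(monte_carlo_cv(org$dataset, genome = org$genome,
                                          n_folds = 5, seed = 19))
  expect_identical(res, res2)

  expect_error(monte_carlo_cv(org$dataset, n_folds = 2, train_frac = 1.0),
               "train_frac")
})

test_that("pairwise cross-organism prediction transfers between same-source organisms", {
  a <- make_test_org(1.0, seed = 20, organism = "ORG_A")
  b <- make_test_org(1.0, seed = 21, organism = "ORG_B")
  res <- suppressMessages(pairwise_cross(a$dataset, b$dataset,
                                         train_genome = a$genome, seed = 22))
  expect_gt(res$mean_auc, 0.8)
  expect_true(no_fold_leakage(res))

  expect_error(suppressMessages(pairwise_cross(a$dataset, a$dataset)),
               "identical")

  # relabeling the test organism cannot change the result
  c_org <- b
  c_org$dataset$organism <- "ORG_C"
  res_c <- suppressMessages(pairwise_cross(a$dataset, c_org$dataset,
                                           train_genome = a$genome, seed = 22))
  expect_equal(res_c$mean_auc, res$mean_auc, tolerance = 1e-12)
})

test_that("leave-one-species-out never trains on the held-out organism", {
  orgs <- lapply(1:3, function(i) {
    make_test_org(1.0, seed = 22 + i, n_essential = 12, n_non_essential = 30,
                  organism = paste0("ORG", i))$dataset
  })
  for (tag in c("ORG1", "ORG2", "ORG3")) {
    res <- suppressMessages(leave_one_species_out(orgs, tag, seed = 30))
    held_ids <- paste(tag, orgs[[which(sapply(orgs, `[[`, "organism") == tag)
    ]]$genes$gene_id, sep = ":")
    expect_length(intersect(unlist(res$fold_train_ids), held_ids), 0)
    expect_false(any(grepl(paste0("^", tag, ":"),
                           unlist(res$fold_train_ids))))
    expect_gt(res$mean_auc, 0.8)
  }
  expect_error(leave_one_species_out(orgs, "NOPE"), "not found")
})

test_that("pooled cross-validation stratifies and reports per-fold AUCs", {
  orgs <- lapply(1:2, function(i) {
    make_test_org(1.0, seed = 26 + i, n_essential = 15, n_non_essential = 35,
                  organism = paste0("P", i))$dataset
  })
  res <- suppressMessages(pooled_cv(orgs, n_folds = 3, seed = 31))
  expect_length(res$fold_aucs, 3)
  expect_gte(res$mean_auc, 0.9)
  expect_true(no_fold_leakage(res))
})

test_that("taxon evaluation enumerates ordered pairs and held-out taxa", {
  orgs <- lapply(1:4, function(i) {
    make_test_org(1.0, seed = 32 + i, n_essential = 10, n_non_essential = 25,
                  organism = paste0("T", i))$dataset
  })
  taxa <- list(tax1 = c("T1", "T2"), tax2 = "T3", tax3 = "T4")
  cross <- suppressMessages(taxon_eval(orgs, taxa, "cross_taxon", seed = 40))
  expect_length(cross, 6)  # 3 taxa -> 6 ordered pairs
  loto <- suppressMessages(taxon_eval(orgs, taxa, "leave_taxon_out",
                                      seed = 40))
  expect_length(loto, 3)
  expect_true(all(vapply(c(cross, loto), no_fold_leakage, logical(1))))
  expect_gt(mean(vapply(cross, `[[`, numeric(1), "mean_auc")), 0.8)

  expect_error(taxon_eval(orgs, list(a = "T1", b = "MISSING"), "cross_taxon"),
               "MISSING")
  expect_error(taxon_eval(orgs, list(a = "T1", b = c("T1", "T2")),
                          "cross_taxon"), "more than one")
})

test_that("information gain ranking matches exhaustive threshold enumeration", {
  labels <- rep(c("essential", "non_essential"), each = 10)
  perfect <- toy_feature_frame("KLD1", rep(c(1, 0), each = 10), labels)
  rk <- rank_features(perfect)
  expect_equal(rk$feature[1], "KLD1")
  expect_equal(rk$gain[1], 1.0, tolerance = 1e-12)
  expect_true(all(rk$gain[-1] == 0))  # constant features carry no gain
  expect_true(all(diff(rk$gain) <= 0))
  expect_equal(nrow(rk), 91)

  set.seed(64)
  toy <- toy_feature_frame("H2", runif(30), sample(labels, 30, replace = TRUE))
  toy$H3 <- round(runif(30), 1)
  toy$G2 <- rep(c(0.3, 0.9), 15)
  rk2 <- rank_features(toy)
  pos <- toy$label == "essential"
  for (f in c("H2", "H3", "G2")) {
    expect_equal(rk2$gain[rk2$feature == f], oracle_info_gain(toy[[f]], pos),
                 tolerance = 1e-9)
  }

  expect_equal(select_top_k(rk, 3), rk$feature[1:3])
  expect_error(select_top_k(rk, 92), "exceeds")
  expect_error(rank_features(perfect[perfect$label == "essential", ]),
               "both classes")
})
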