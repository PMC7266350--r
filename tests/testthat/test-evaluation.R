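test_that("confusion metrics match their closed forms", {
  m <- classification_metrics(list(tp = 2, tn = 2, fp = 1, fn = 1))
  expect_equal(unname(m), c(4 / 6, 2 / 3, 2 / 3, 2 / 3, 1 / 3))

  perfect <- classification_metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(unname(perfect), rep(1, 5))

  # degenerate denominators fall back to 0 by convention
  degen <- classification_metrics(list(tp = 0, tn = 4, fp = 0, fn = 0))
  expect_equal(degen[["mcc"]], 0)
  expect_equal(degen[["precision"]], 0)
})

test_that("confusion counting respects the threshold", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1),
                         threshold = 0.5)
  expect_equal(cc, list(tp = 1L, tn = 1L, fp = 1L, fn = 1L))
  cc2 <- confusion_counts(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1),
                          threshold = 0.95)
  expect_equal(cc2$tp + cc2$fp, 0L)
})

test_that("AUC equals the pairwise-comparison probability", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(.9, .8, .7, .1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(.9, .8, .2, .1))$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(.2, .3)), "both classes")

  set.seed(71)
  for (rep in 1:6) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)  # rounding forces ties
    expect_equal(roc_auc(labels, scores)$auc, oracle_auc(labels, scores))
  }
})

test_that("ROC points start at (0,0), end at (1,1), and are monotone", {
  set.seed(72)
  labels <- rbinom(60, 1, 0.5); labels[1:2] <- c(0, 1)
  scores <- runif(60)
  roc <- roc_auc(labels, scores)$roc
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("metrics are invariant to sample order", {
  set.seed(73)
  labels <- rbinom(50, 1, 0.5); labels[1:2] <- c(0, 1)
  scores <- runif(50)
  perm <- sample(50)
  expect_equal(roc_auc(labels, scores)$auc,
               roc_auc(labels[perm], scores[perm])$auc)
  expect_equal(classification_metrics(confusion_counts(labels, scores)),
               classification_metrics(confusion_counts(labels[perm],
                                                       scores[perm])))
})

quick_config <- function() {
  cda_config(knn_k = 6,
             gcn = gcn_config(hidden_dim = 16, sample_sizes = c(64L, 64L),
                              batch_size = 64L, epochs = 40L),
             n_trees = 15L)
}

test_that("cross-validation produces disjoint exhaustive folds and a report", {
  ds <- gen_dataset(synthetic_spec(n_circ = 40, n_dis = 12, n_blocks = 2,
                                   seed = 5))
  rep <- cross_validate(ds$am, ds$hierarchy, quick_config(), seed = 3)
  expect_s3_class(rep, "cv_report")
  expect_equal(nrow(rep$per_fold), 5L)
  expect_named(rep$mean, c("accuracy", "sensitivity", "precision", "f1",
                           "mcc", "auc"))
  # every sample scored exactly once, out of fold
  expect_false(anyNA(rep$scores$score))
  expect_equal(sort(unique(rep$scores$fold)), 0:4)
  expect_true(all(rep$per_fold$auc >= 0 & rep$per_fold$auc <= 1))

  paths <- c(json = withr::local_tempfile(),
             roc = withr::local_tempfile())
  write_cv_report(rep, paths["json"], paths["roc"])
  back <- jsonlite::read_json(paths["json"], simplifyVector = TRUE)
  expect_equal(back$mean$auc, unname(rep$mean["auc"]))
  roc <- utils::read.delim(paths["roc"])
  expect_equal(names(roc), c("fpr", "tpr", "threshold"))
})

test_that("candidate ranking screens exactly the unlinked circRNAs", {
  ds <- gen_dataset(synthetic_spec(n_circ = 40, n_dis = 12, n_blocks = 2,
                                   seed = 6))
  d <- colnames(ds$am)[1]
  rk <- rank_candidates(ds$am, ds$hierarchy, d, quick_config(), seed = 4)
  expect_equal(nrow(rk), sum(ds$am[, 1] == 0L))
  expect_true(all(diff(rk$score) <= 0))       # descending
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_false(any(rk$circ_id %in% rownames(ds$am)[ds$am[, 1] == 1L]))

  # a disease linked to every circRNA leaves nothing to rank
  full <- ds$am
  full[, 2] <- 1L
  rk0 <- rank_candidates(full, ds$hierarchy, colnames(full)[2],
                         quick_config(), seed = 4)
  expect_equal(nrow(rk0), 0L)

  expect_error(rank_candidates(ds$am, ds$hierarchy, "nope"), "unknown")
})

test_that("held-out within-block circRNAs outrank the out-of-block median", {
  spec <- synthetic_spec(n_circ = 48, n_dis = 12, n_blocks = 2,
                         within_density = 0.6,
                         background_density = 0.02, seed = 7)
  ds <- gen_dataset(spec)
  d <- colnames(ds$am)[1]     # block-1 disease
  rk <- rank_candidates(ds$am, ds$hierarchy, d, quick_config(), seed = 5)
  blk <- ds$circ_block[match(rk$circ_id, rownames(ds$am))]
  in_block <- rk$score[blk == ds$dis_block[1]]
  out_block <- rk$score[blk != ds$dis_block[1]]
  expect_gt(mean(in_block), stats::median(out_block))
})
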