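#' Confusion counts at a threshold
#'
#' @param labels true 0/1 labels.
#' @param scores predicted positive-class scores.
#' @param threshold scores >= threshold predict class 1 (default 0.5).
#' @return list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  list(tp = sum(pred == 1L & labels == 1L),
       tn = sum(pred == 0L & labels == 0L),
       fp = sum(pred == 1L & labels == 0L),
       fn = sum(pred == 0L & labels == 1L))
}

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity (recall), precision, F1 and the Matthews
#' correlation coefficient from raw counts. Degenerate denominators fall
#' back to 0 (a convention, stated rather than silent).
#'
#' @param c list with `tp`, `tn`, `fp`, `fn` (see [confusion_counts()]).
#' @return named numeric vector `accuracy`, `sensitivity`, `precision`,
#'   `f1`, `mcc`.
#' @export
classification_metrics <- function(c) {
  with(c, {
    n <- tp + tn + fp + fn
    acc <- if (n > 0) (tp + tn) / n else 0
    sen <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
    c(accuracy = acc, sensitivity = sen, precision = prec, f1 = f1,
      mcc = mcc)
  })
}

#' ROC curve and AUC
#'
#' AUC by the Mann-Whitney statistic with rank-averaged ties (equivalently,
#' the trapezoidal area under the ROC curve over all score thresholds).
#'
#' @param labels true 0/1 labels (both classes required).
#' @param scores numeric scores, larger = more positive.
#' @return list with `auc` and `roc` (data.frame of `fpr`, `tpr`,
#'   `threshold` points, one per distinct score plus the endpoints).
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs both classes present (got ", n_pos, " positives, ",
         n_neg, " negatives)")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(labels == 1L & scores >= t), 0)
  fp <- vapply(thr, function(t) sum(labels == 0L & scores >= t), 0)
  roc <- data.frame(fpr = c(0, fp / n_neg, 1), tpr = c(0, tp / n_pos, 1),
                    threshold = c(Inf, thr, -Inf))
  list(auc = auc, roc = roc)
}

#' Pipeline configuration
#'
#' Bundles every tunable stage parameter of the prediction pipeline.
#'
#' @param folds cross-validation folds.
#' @param knn_k neighbours for the sample graph.
#' @param gcn a [gcn_config()].
#' @param n_trees,rho,min_leaf,max_depth forest parameters
#'   (see [train_forest()]).
#' @param threshold classification threshold on forest scores.
#' @param semantic a [semantic_config()].
#' @param transductive_gip if TRUE, compute GIP kernels once from the full
#'   association matrix (test-fold associations leak into the features);
#'   default FALSE recomputes them per fold from training positives only.
#' @param paper_literal_width see [gip_similarities()].
#' @return a `cda_config` list.
#' @export
cda_config <- function(folds = 5L, knn_k = 10L, gcn = gcn_config(),
                       n_trees = 100L, rho = 0.01, min_leaf = 2L,
                       max_depth = Inf, threshold = 0.5,
                       semantic = semantic_config(),
                       transductive_gip = FALSE,
                       paper_literal_width = FALSE) {
  structure(list(folds = as.integer(folds), knn_k = as.integer(knn_k),
                 gcn = gcn, n_trees = as.integer(n_trees), rho = rho,
                 min_leaf = as.integer(min_leaf), max_depth = max_depth,
                 threshold = threshold, semantic = semantic,
                 transductive_gip = transductive_gip,
                 paper_literal_width = paper_literal_width),
            class = "cda_config")
}

# Similarity construction shared by the CV harness and the ranking mode:
# GIP kernels from (possibly masked) associations, semantic fall-through.
build_similarities <- function(am, sem, config) {
  gip <- gip_similarities(am, paper_literal_width = config$paper_literal_width)
  dsim <- build_dsim(sem$sv1, sem$sv2, gip$gd$matrix, sem$mask)
  list(rsim = gip$gc$matrix, dsim = dsim)
}

# Train GCN + forest on the training rows of a feature table and score the
# requested rows. Returns positive-class scores for `score_rows`.
fit_and_score <- function(features, labels, train_rows, score_rows, config,
                          seed) {
  graph <- build_sample_graph(features, k = min(config$knn_k,
                                                nrow(features) - 1L))
  graph$labels <- ifelse(seq_len(graph$n) %in% train_rows, labels, NA)
  graph$train_mask <- seq_len(graph$n) %in% train_rows
  gcfg <- config$gcn
  gcfg$seed <- seed
  model <- train_fastgcn(graph, gcfg)
  emb <- extract_features(model, graph)
  forest <- train_forest(emb[train_rows, , drop = FALSE],
                         labels[train_rows], n_trees = config$n_trees,
                         seed = seed + 1L, rho = config$rho,
                         min_leaf = config$min_leaf,
                         max_depth = config$max_depth)
  predict_forest(forest, emb[score_rows, , drop = FALSE])[, 2L]
}

#' Cross-validated evaluation of the full pipeline
#'
#' Builds the balanced dataset, splits it into stratified folds, and for
#' each fold: recomputes the GIP kernels from training-fold associations
#' (test pairs zeroed, unless `transductive_gip`), fuses similarities into
#' descriptors, builds the sample graph, trains the sampled GCN
#' transductively, extracts hidden-layer features, trains the
#' penalized-attribute forest on training rows and scores the held-out
#' rows. Reports per-fold metrics and their mean +/- sd.
#'
#' @param am an `assoc_matrix`.
#' @param hierarchy a `disease_hierarchy` (or NULL: GIP-only disease
#'   similarity).
#' @param config a [cda_config()].
#' @param seed master seed; negatives, folds and per-fold model seeds derive
#'   from it.
#' @param shuffle_labels permute sample labels before splitting (null
#'   control: scores should carry no information).
#' @return a `cv_report`: list with `per_fold` (data.frame), `mean`, `sd`,
#'   `scores` (data.frame of per-sample out-of-fold scores), `samples`.
#' @export
cross_validate <- function(am, hierarchy = NULL, config = cda_config(),
                           seed = 1L, shuffle_labels = FALSE) {
  samples <- make_balanced_dataset(am, seed = seed)
  if (shuffle_labels) {
    set.seed(seed + 17L)
    samples$label <- sample(samples$label)
  }
  fold <- kfold_split(samples, k = config$folds, seed = seed + 1L)
  sem <- disease_semantics(am, hierarchy, config)
  per_fold <- NULL
  scores_all <- rep(NA_real_, nrow(samples))
  for (f in sort(unique(fold))) {
    test_rows <- which(fold == f)
    train_rows <- which(fold != f)
    am_fold <- am
    if (!config$transductive_gip) {
      # hide test-fold positive associations from the similarity features
      pos_test <- test_rows[samples$label[test_rows] == 1L]
      am_fold[cbind(samples$circ_index[pos_test],
                    samples$disease_index[pos_test])] <- 0L
    }
    sims <- build_similarities(am_fold, sem, config)
    ft <- assemble_feature_table(sims$rsim, sims$dsim, samples)
    sc <- fit_and_score(ft$x, ft$y, train_rows,
                        score_rows = seq_len(nrow(samples)),
                        config, seed = seed + 100L + f)
    scores_all[test_rows] <- sc[test_rows]
    cc <- confusion_counts(samples$label[test_rows], sc[test_rows],
                           config$threshold)
    met <- classification_metrics(cc)
    auc <- roc_auc(samples$label[test_rows], sc[test_rows])$auc
    per_fold <- rbind(per_fold,
                      data.frame(fold = f, t(met), auc = auc))
  }
  metric_cols <- setdiff(names(per_fold), "fold")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[metric_cols]),
                 sd = apply(per_fold[metric_cols], 2L, stats::sd),
                 scores = data.frame(samples, fold = fold,
                                     score = scores_all),
                 samples = samples),
            class = "cv_report")
}

disease_semantics <- function(am, hierarchy, config) {
  if (is.null(hierarchy)) {
    n <- ncol(am)
    list(sv1 = matrix(NA_real_, n, n), sv2 = matrix(NA_real_, n, n),
         mask = matrix(FALSE, n, n))
  } else {
    semantic_similarity_matrices(colnames(am), hierarchy, config$semantic)
  }
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cross-validation report (", nrow(x$per_fold), " folds)\n", sep = "")
  tab <- x$per_fold
  tab[-1L] <- round(tab[-1L] * 100, 2)
  print(tab, row.names = FALSE)
  cat("mean +/- sd (%):\n")
  for (m in names(x$mean)) {
    cat(sprintf("  %-12s %6.2f +/- %.2f\n", m, 100 * x$mean[[m]],
                100 * x$sd[[m]]))
  }
  invisible(x)
}

#' Rank candidate circRNAs for one disease
#'
#' Trains the pipeline on every known association (plus a fresh balanced
#' negative sample) and scores all circRNAs not yet linked to the disease,
#' returning them in descending score order — the screening mode used to
#' propose novel disease-associated circRNAs for experimental follow-up.
#'
#' @param am an `assoc_matrix`.
#' @param hierarchy a `disease_hierarchy` or NULL.
#' @param disease_id the disease to screen (must be a column of `am`).
#' @param config a [cda_config()].
#' @param seed RNG seed.
#' @return data.frame with `rank`, `circ_id`, `score`.
#' @export
rank_candidates <- function(am, hierarchy = NULL, disease_id,
                            config = cda_config(), seed = 1L) {
  j <- match(disease_id, colnames(am))
  if (is.na(j)) stop("unknown disease: ", disease_id)
  if (is.null(hierarchy) || !(disease_id %in% hierarchy$diseases)) {
    if (sum(am[, j]) == 0L) {
      warning("disease '", disease_id, "' has no known associations and no ",
              "hierarchy coverage; scores rest on the kernel of an empty ",
              "interaction profile")
    }
  }
  cand_i <- which(am[, j] == 0L)
  if (length(cand_i) == 0L) {
    return(data.frame(rank = integer(0), circ_id = character(0),
                      score = numeric(0)))
  }
  samples <- make_balanced_dataset(am, seed = seed)
  sem <- disease_semantics(am, hierarchy, config)
  sims <- build_similarities(am, sem, config)
  cand <- pair_samples(am, cand_i, rep(j, length(cand_i)), label = NA)
  all_rows <- rbind(samples, cand)
  ft <- assemble_feature_table(sims$rsim, sims$dsim, all_rows)
  sc <- fit_and_score(ft$x, ft$y, train_rows = seq_len(nrow(samples)),
                      score_rows = nrow(samples) + seq_len(nrow(cand)),
                      config, seed = seed + 1000L)
  ord <- order(sc, decreasing = TRUE)
  data.frame(rank = seq_along(ord), circ_id = cand$circ_id[ord],
             score = sc[ord])
}

#' Export a cross-validation report
#'
#' Writes the per-fold metric table as JSON and the pooled out-of-fold ROC
#' points as TSV.
#'
#' @param report a `cv_report`.
#' @param json_path,roc_path output paths (NULL to skip either).
#' @export
write_cv_report <- function(report, json_path = NULL, roc_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(per_fold = report$per_fold,
                              mean = as.list(report$mean),
                              sd = as.list(report$sd)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(roc_path)) {
    ok <- !is.na(report$scores$score)
    roc <- roc_auc(report$scores$label[ok], report$scores$score[ok])$roc
    utils::write.table(roc, roc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report)
}
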