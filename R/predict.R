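as_params <- function(x) {
  if (inherits(x, "prd_model")) x$params else x
}

#' Predict the relation embedding between two drugs
#'
#' Translation-based link prediction: the candidate DDI relation embedding
#' between drugs `u` and `v` is `v M_l - u M_l`, the difference of the
#' projected drug embeddings. Antisymmetric in its arguments.
#'
#' @param model A `prd_model` (or `prd_params`).
#' @param u,v Drug entity ids.
#' @return Numeric vector of length `d`.
#' @export
predict_relation_embedding <- function(model, u, v) {
  params <- as_params(model)
  uu <- lookup_entity(params, u)
  vv <- lookup_entity(params, v)
  drop((vv - uu) %*% params$proj_ddi)
}

#' Decode a relation embedding into ranked labels
#'
#' Decodes the embedding with the trained decoder and returns labels ranked
#' by reconstruction score, either the best `top_n` or all labels above a
#' `threshold`.
#'
#' @param model A `prd_model` (or `prd_params`).
#' @param l_emb Relation embedding of length `d`.
#' @param top_n Keep this many top labels (mutually exclusive with
#'   `threshold`).
#' @param threshold Keep labels with score above this value in `(0, 1)`.
#' @return A tibble with columns `label`, `score`, ordered best-first (ties
#'   broken by vocabulary order).
#' @export
predict_labels <- function(model, l_emb, top_n = NULL, threshold = NULL) {
  params <- as_params(model)
  if (is.null(top_n) && is.null(threshold)) top_n <- 5L
  if (!is.null(top_n) && (!is.numeric(top_n) || top_n < 1)) {
    abort_typed("top_n must be >= 1", "prddi_domain_error")
  }
  if (!is.null(threshold) &&
      (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)) {
    abort_typed("threshold must lie in (0, 1)", "prddi_domain_error")
  }
  shat <- decode_labels(params$ae, l_emb)
  out <- tibble::tibble(label = params$vocabulary, score = shat)
  out <- out[order(-out$score, out$label), ]
  if (!is.null(top_n)) {
    out <- utils::head(out, top_n)
  } else {
    out <- out[out$score > threshold, ]
  }
  out
}

#' Predict ranked DDI labels for a drug pair
#'
#' Convenience composition of [predict_relation_embedding()] and
#' [predict_labels()].
#'
#' @inheritParams predict_relation_embedding
#' @inheritParams predict_labels
#' @return A tibble with columns `label`, `score`.
#' @export
predict_ddi_labels <- function(model, u, v, top_n = 5, threshold = NULL) {
  l <- predict_relation_embedding(model, u, v)
  predict_labels(model, l, top_n = top_n, threshold = threshold)
}

# Pessimistic competition rank: each correct label gets the worst rank of
# its tie group among the candidate scores.
pessimistic_rank <- function(score_i, candidate_scores) {
  sum(candidate_scores > score_i) + sum(candidate_scores == score_i)
}

#' Rank the correct labels of a test DDI triple
#'
#' Scores every vocabulary label by decoding the predicted relation
#' embedding of the test pair, then ranks each correct label among all
#' candidates (raw) and after removing the triple's other correct labels
#' from the candidate list (filtered). Ties are resolved pessimistically:
#' a correct label receives the worst rank within its tie group.
#'
#' @param model A `prd_model`.
#' @param test One test triple: named list / one-row tibble with `drug_u`,
#'   `drug_v` and `labels` (character vector, or list-column holding one).
#' @return A tibble with one row per correct label: `label`, `raw_rank`,
#'   `filtered_rank`.
#' @export
rank_labels <- function(model, test) {
  params <- as_params(model)
  labels <- test$labels
  if (is.list(labels)) labels <- labels[[1]]
  l <- predict_relation_embedding(model, test$drug_u, test$drug_v)
  shat <- decode_labels(params$ae, l)
  vocab <- params$vocabulary
  correct_idx <- match(labels, vocab)
  if (anyNA(correct_idx)) {
    abort_typed("test labels outside the vocabulary",
                "prddi_vocabulary_error")
  }
  raw <- vapply(correct_idx, function(i) pessimistic_rank(shat[i], shat),
                numeric(1))
  filt <- vapply(correct_idx, function(i) {
    others <- setdiff(correct_idx, i)
    cand <- if (length(others) > 0) shat[-others] else shat
    pessimistic_rank(shat[i], cand)
  }, numeric(1))
  tibble::tibble(label = vocab[correct_idx], raw_rank = raw,
                 filtered_rank = filt)
}

#' Rank labels for a whole set of test triples
#'
#' @param model A `prd_model`.
#' @param test_positives Tibble of test triples (`drug_u`, `drug_v`,
#'   list-column `labels`), e.g. `split$test_positives`.
#' @return A tibble with columns `drug_u`, `drug_v`, `label`, `raw_rank`,
#'   `filtered_rank` (one row per correct label of each triple).
#' @export
rank_test_triples <- function(model, test_positives) {
  purrr::map_dfr(seq_len(nrow(test_positives)), function(i) {
    tr <- test_positives[i, ]
    rk <- rank_labels(model, tr)
    dplyr::mutate(rk, drug_u = tr$drug_u, drug_v = tr$drug_v,
                  .before = "label")
  })
}

#' Aggregate ranking results into MeanRank and Hits@k
#'
#' MeanRank is the arithmetic mean over all correct-label ranks; Hits@k is
#' 100 times the proportion of correct-label ranks at or below k. Both are
#' computed for the raw and the filtered setting.
#'
#' @param results Ranking tibble with columns `raw_rank`, `filtered_rank`
#'   (as from [rank_test_triples()]).
#' @param ks Integer vector of cut-offs for Hits@k.
#' @return A `prd_eval_report`: tibble with columns `setting`
#'   (`"raw"`/`"filtered"`), `metric` (`"mean_rank"`, `"hits_at_<k>"`),
#'   `value`.
#' @export
aggregate_metrics <- function(results, ks = c(1, 5, 10)) {
  if (is.null(results) || nrow(results) == 0) {
    abort_typed("no ranking results to aggregate", "prddi_domain_error")
  }
  one <- function(ranks, setting) {
    tibble::tibble(
      setting = setting,
      metric = c("mean_rank", paste0("hits_at_", ks)),
      value = c(sum(ranks) / length(ranks),
                vapply(ks, function(k) {
                  100 * sum(ranks <= k) / length(ranks)
                }, numeric(1)))
    )
  }
  out <- dplyr::bind_rows(one(results$raw_rank, "raw"),
                          one(results$filtered_rank, "filtered"))
  class(out) <- c("prd_eval_report", class(out))
  out
}

#' Look up one metric in an evaluation report
#' @param report A `prd_eval_report`.
#' @param metric Metric name (e.g. `"hits_at_5"`).
#' @param setting `"filtered"` or `"raw"`.
#' @return A single numeric value.
#' @export
report_metric <- function(report, metric, setting = "filtered") {
  v <- report$value[report$metric == metric & report$setting == setting]
  if (length(v) != 1) abort_typed("metric not found", "prddi_domain_error")
  v
}

#' Concatenated embedding features of a drug pair
#'
#' @param model A `prd_model` (or `prd_params`).
#' @param u,v Drug entity ids.
#' @return Numeric vector of length `2k`: the `u` embedding followed by the
#'   `v` embedding.
#' @export
binary_features <- function(model, u, v) {
  params <- as_params(model)
  c(lookup_entity(params, u), lookup_entity(params, v))
}

# Threshold-sweep ROC curve and trapezoidal area.
roc_curve_points <- function(scores, labels) {
  ord <- order(-scores)
  scores <- scores[ord]; labels <- labels[ord]
  ths <- unique(scores)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  tp <- cumsum(labels == 1); fp <- cumsum(labels == 0)
  last <- !duplicated(scores, fromLast = TRUE)
  tibble::tibble(
    threshold = c(Inf, scores[last]),
    tpr = c(0, tp[last] / n_pos),
    fpr = c(0, fp[last] / n_neg)
  )
}

auc_trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Precision-recall points and step-wise interpolated area. Points are
# computed per unique threshold (all tied scores enter together), and the
# area sums precision times the recall increment of each threshold step.
pr_curve_points <- function(scores, labels) {
  ord <- order(-scores)
  labels <- labels[ord]; scores <- scores[ord]
  n_pos <- sum(labels == 1)
  tp <- cumsum(labels == 1)
  last <- !duplicated(scores, fromLast = TRUE)
  precision <- (tp / seq_along(labels))[last]
  recall <- (tp / n_pos)[last]
  d_recall <- diff(c(0, recall))
  list(
    points = tibble::tibble(threshold = scores[last], recall = recall,
                            precision = precision),
    aupr = sum(precision * d_recall)
  )
}

#' Binary DDI classification from concatenated embeddings
#'
#' Trains a logistic-regression classifier on the concatenated embeddings
#' of the training DDI pairs (positives) and an equal number of drug pairs
#' with no DDI (sampled disjointly from the test negatives), then computes
#' the ROC and precision-recall curves with their areas on the held-out
#' test positives and negatives. Because DDI relations are unordered while
#' the concatenation is ordered, both orientations of every training pair
#' are used as training rows, and a test pair's score is the average of
#' its two orientation scores.
#'
#' @param model A `prd_model`.
#' @param split A `ddi_split` from [split_ddi()].
#' @param classifier_seed Seed for the training-negative sampling.
#' @return A `prd_binary_eval`: list with `auroc`, `aupr`, `roc` and `pr`
#'   point tibbles, and the per-test-pair `scores` tibble.
#' @export
binary_evaluate <- function(model, split, classifier_seed = 1L) {
  params <- as_params(model)
  train_pairs <- ddi_pairs(split$train_kg)
  if (nrow(train_pairs) < 2 || nrow(split$test_positives) == 0 ||
      nrow(split$test_negatives) == 0) {
    abort_typed("binary evaluation needs both classes in train and test",
                "prddi_degenerate_error")
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(classifier_seed)

  drugs <- intersect(model$drugs, rownames(params$entity))
  ddi_key <- c(canonical_pair(split$train_kg$ddi$drug_u,
                              split$train_kg$ddi$drug_v),
               canonical_pair(split$test_positives$drug_u,
                              split$test_positives$drug_v))
  test_neg_key <- canonical_pair(split$test_negatives$drug_u,
                                 split$test_negatives$drug_v)
  n_need <- nrow(train_pairs)
  neg_u <- character(0); neg_v <- character(0)
  tries <- 0
  while (length(neg_u) < n_need) {
    tries <- tries + 1
    if (tries > 200) {
      abort_typed("could not sample enough training negatives",
                  "prddi_sampling_error")
    }
    cu <- sample(drugs, n_need, replace = TRUE)
    cv <- sample(drugs, n_need, replace = TRUE)
    key <- canonical_pair(cu, cv)
    ok <- cu != cv & !(key %in% ddi_key) & !(key %in% test_neg_key) &
      !(key %in% canonical_pair(neg_u, neg_v))
    ok <- ok & !duplicated(key)
    neg_u <- c(neg_u, cu[ok]); neg_v <- c(neg_v, cv[ok])
  }
  neg_u <- neg_u[seq_len(n_need)]; neg_v <- neg_v[seq_len(n_need)]

  feat <- function(us, vs) {
    t(mapply(function(u, v) binary_features(params, u, v), us, vs))
  }
  both <- function(us, vs) rbind(feat(us, vs), feat(vs, us))
  x_train <- rbind(both(train_pairs$drug_u, train_pairs$drug_v),
                   both(neg_u, neg_v))
  y_train <- c(rep(1, 2 * nrow(train_pairs)), rep(0, 2 * n_need))
  df_train <- as.data.frame(x_train)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = cbind(df_train, y = y_train),
               family = stats::binomial())
  )

  test_pairs <- ddi_pairs_of(split$test_positives)
  te_u <- c(test_pairs$drug_u, split$test_negatives$drug_u)
  te_v <- c(test_pairs$drug_v, split$test_negatives$drug_v)
  y_test <- c(rep(1, nrow(test_pairs)), rep(0, nrow(split$test_negatives)))
  score_orient <- function(us, vs) {
    suppressWarnings(stats::predict(fit, newdata = as.data.frame(feat(us, vs)),
                                    type = "response"))
  }
  scores <- (score_orient(te_u, te_v) + score_orient(te_v, te_u)) / 2

  roc <- roc_curve_points(scores, y_test)
  pr <- pr_curve_points(scores, y_test)
  structure(
    list(auroc = auc_trapezoid(roc$fpr, roc$tpr), aupr = pr$aupr,
         roc = roc, pr = pr$points,
         scores = tibble::tibble(drug_u = c(test_pairs$drug_u,
                                            split$test_negatives$drug_u),
                                 drug_v = c(test_pairs$drug_v,
                                            split$test_negatives$drug_v),
                                 truth = y_test, score = unname(scores))),
    class = "prd_binary_eval"
  )
}

# Collapse directed test triples to unordered unique pairs.
ddi_pairs_of <- function(ddi) {
  keep <- ddi$drug_u < ddi$drug_v
  ddi[keep, ]
}

#' @export
print.prd_binary_eval <- function(x, ...) {
  cat("<prd_binary_eval>  AUROC:", round(x$auroc, 4),
      " AUPR:", round(x$aupr, 4), "\n")
  invisible(x)
}

#' Full rich-DDI evaluation of a fitted model on a split
#'
#' Runs label ranking over all held-out test triples, aggregates raw and
#' filtered MeanRank / Hits@k, and performs the binary classification
#' evaluation.
#'
#' @param model A `prd_model`.
#' @param split A `ddi_split`.
#' @param ks Hits@k cut-offs.
#' @param classifier_seed Seed for [binary_evaluate()].
#' @return A list with `ranks` (per-label rank tibble), `report`
#'   (a `prd_eval_report`) and `binary` (a `prd_binary_eval`).
#' @export
evaluate_model <- function(model, split, ks = c(1, 5, 10),
                           classifier_seed = 1L) {
  ranks <- rank_test_triples(model, split$test_positives)
  report <- aggregate_metrics(ranks, ks = ks)
  binary <- binary_evaluate(model, split, classifier_seed = classifier_seed)
  list(ranks = ranks, report = report, binary = binary)
}
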