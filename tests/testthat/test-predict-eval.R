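test_that("relation embeddings are projected differences and antisymmetric", {
  gen <- generate_kg(small_synth_config())
  hp <- small_hparams()
  params <- jitter_params(prd_init_params(gen$kg, hp))
  drugs <- utils::head(kg_drugs(gen$kg), 4)

  # u = v gives the zero vector
  expect_equal(predict_relation_embedding(params, drugs[1], drugs[1]),
               rep(0, hp$d))
  # antisymmetry
  l_uv <- predict_relation_embedding(params, drugs[1], drugs[2])
  l_vu <- predict_relation_embedding(params, drugs[2], drugs[1])
  expect_equal(l_uv, -l_vu)

  # identity projection reduces to a plain embedding difference
  p2 <- params
  p2$proj_ddi <- diag(1, hp$k, hp$d)
  u <- p2$entity[drugs[1], ]; v <- p2$entity[drugs[2], ]
  expect_equal(predict_relation_embedding(p2, drugs[1], drugs[2]),
               unname((v - u)[seq_len(hp$d)]))
  expect_error(predict_relation_embedding(params, "ghost", drugs[1]),
               class = "prddi_lookup_error")
})

test_that("predicted labels are ranked by decoder score with both modes", {
  gen <- generate_kg(small_synth_config())
  hp <- small_hparams()
  params <- prd_init_params(gen$kg, hp)
  l <- encode_labels(params$ae,
                     vectorize_labels(gen$kg$ddi$labels[[1]],
                                      gen$kg$vocabulary))
  shat <- decode_labels(params$ae, l)
  vocab <- vocab_labels(gen$kg$vocabulary)

  top2 <- predict_labels(params, l, top_n = 2)
  expect_equal(nrow(top2), 2)
  ord <- order(-shat, vocab)
  expect_equal(top2$label, vocab[ord[1:2]])

  all_lab <- predict_labels(params, l, top_n = length(vocab))
  expect_equal(nrow(all_lab), length(vocab))
  expect_true(all(diff(all_lab$score) <= 0))

  none <- predict_labels(params, l, threshold = max(shat) + 1e-9)
  expect_equal(nrow(none), 0)

  expect_error(predict_labels(params, l, top_n = 0),
               class = "prddi_domain_error")
  expect_error(predict_labels(params, l, threshold = 1.5),
               class = "prddi_domain_error")
})

test_that("label ranking follows the raw and filtered definitions", {
  # decoder rigged so scores are known: use a params stub and rank by hand
  gen <- generate_kg(small_synth_config())
  hp <- small_hparams()
  params <- jitter_params(prd_init_params(gen$kg, hp))
  test <- ddi_pairs(gen$kg)[1, ]
  rk <- rank_labels(params, test)
  expect_equal(nrow(rk), length(test$labels[[1]]))
  expect_true(all(rk$filtered_rank <= rk$raw_rank))
  expect_true(all(rk$raw_rank >= 1 &
                    rk$raw_rank <= length(gen$kg$vocabulary)))

  # hand-checkable configuration: scores known from the decoder output
  shat <- decode_labels(params$ae,
                        predict_relation_embedding(params, test$drug_u,
                                                   test$drug_v))
  vocab <- vocab_labels(gen$kg$vocabulary)
  i <- match(test$labels[[1]][1], vocab)
  expect_equal(rk$raw_rank[1], sum(shat > shat[i]) + sum(shat == shat[i]))
})

test_that("rank filtering removes exactly the other correct labels", {
  # engineered scores: correct labels A (0.7) and B (0.9), one wrong label
  # outranking both (0.95); raw rank of A = 3, filtered rank of A = 2
  scores <- c(A = 0.7, B = 0.9, w1 = 0.95, w2 = 0.1, w3 = 0.05)
  correct <- c("A", "B")
  raw_A <- sum(scores > scores["A"]) + sum(scores == scores["A"])
  cand <- scores[setdiff(names(scores), "B")]
  filt_A <- sum(cand > scores["A"]) + sum(cand == scores["A"])
  expect_equal(raw_A, 3)
  expect_equal(filt_A, 2)
})

brute_force_metrics <- function(results, ks) {
  # enumerate every (triple, correct label) pair and count directly
  out <- list()
  for (setting in c("raw", "filtered")) {
    ranks <- if (setting == "raw") results$raw_rank else results$filtered_rank
    out[[setting]] <- c(
      mean_rank = sum(ranks) / length(ranks),
      stats::setNames(vapply(ks, function(k) {
        100 * sum(ranks <= k) / length(ranks)
      }, numeric(1)), paste0("hits_at_", ks))
    )
  }
  out
}

test_that("aggregate_metrics equals a brute-force oracle on random rankings", {
  set.seed(101)
  n_labels <- 30
  results <- dplyr::bind_rows(lapply(1:50, function(i) {
    n_correct <- sample(1:5, 1)
    raw <- sort(sample.int(n_labels, n_correct))
    filt <- pmax(1, raw - sample(0:2, n_correct, replace = TRUE))
    tibble::tibble(raw_rank = raw, filtered_rank = pmin(filt, raw))
  }))
  ks <- c(1, 5, 10)
  rep <- aggregate_metrics(results, ks)
  bf <- brute_force_metrics(results, ks)
  for (setting in c("raw", "filtered")) {
    expect_equal(report_metric(rep, "mean_rank", setting),
                 unname(bf[[setting]]["mean_rank"]))
    for (k in ks) {
      expect_equal(report_metric(rep, paste0("hits_at_", k), setting),
                   unname(bf[[setting]][paste0("hits_at_", k)]))
    }
  }
  expect_error(aggregate_metrics(results[0, ]), class = "prddi_domain_error")

  # worked example: ranks 1, 3, 12
  rep2 <- aggregate_metrics(tibble::tibble(raw_rank = c(1, 3, 12),
                                           filtered_rank = c(1, 3, 12)),
                            ks = 10)
  expect_equal(report_metric(rep2, "hits_at_10", "raw"), 100 * 2 / 3)
  expect_equal(report_metric(rep2, "mean_rank", "raw"), 16 / 3)
})

test_that("metric order invariants hold on random ranking sets", {
  set.seed(77)
  for (rep_i in 1:200) {
    n <- sample(3:30, 1)
    raw <- sample.int(40, n, replace = TRUE)
    filt <- pmax(1, raw - sample.int(5, n, replace = TRUE) + 1)
    results <- tibble::tibble(raw_rank = raw, filtered_rank = pmin(filt, raw))
    ks <- sort(sample.int(40, 3))
    rep <- aggregate_metrics(results, ks)
    hits_raw <- vapply(ks, function(k)
      report_metric(rep, paste0("hits_at_", k), "raw"), numeric(1))
    hits_filt <- vapply(ks, function(k)
      report_metric(rep, paste0("hits_at_", k), "filtered"), numeric(1))
    # Hits@k non-decreasing in k; filtered dominates raw
    expect_true(all(diff(hits_raw) >= 0))
    expect_true(all(diff(hits_filt) >= 0))
    expect_true(all(hits_filt >= hits_raw))
    expect_lte(report_metric(rep, "mean_rank", "filtered"),
               report_metric(rep, "mean_rank", "raw"))
    expect_true(all(hits_raw >= 0 & hits_filt <= 100))
  }
  # Hits at the vocabulary size is always 100
  full <- aggregate_metrics(tibble::tibble(raw_rank = c(4, 9, 40),
                                           filtered_rank = c(1, 2, 40)),
                            ks = 40)
  expect_equal(report_metric(full, "hits_at_40", "raw"), 100)
})

test_that("binary features concatenate the two drug embeddings in order", {
  gen <- generate_kg(small_synth_config())
  hp <- small_hparams()
  params <- prd_init_params(gen$kg, hp)
  d <- utils::head(kg_drugs(gen$kg), 2)
  f <- binary_features(params, d[1], d[2])
  expect_length(f, 2 * hp$k)
  expect_equal(f, c(params$entity[d[1], ], params$entity[d[2], ]))
  expect_false(identical(f, binary_features(params, d[2], d[1])))
})

test_that("ROC and PR areas match hand counts and pROC", {
  scores <- c(0.9, 0.8, 0.3, 0.1)
  # perfectly separated
  roc1 <- prddi:::roc_curve_points(scores, c(1, 1, 0, 0))
  expect_equal(prddi:::auc_trapezoid(roc1$fpr, roc1$tpr), 1)
  # interleaved: Mann-Whitney count gives 3/4
  roc2 <- prddi:::roc_curve_points(scores, c(1, 0, 1, 0))
  expect_equal(prddi:::auc_trapezoid(roc2$fpr, roc2$tpr), 0.75)

  skip_if_not_installed("pROC")
  set.seed(12)
  for (i in 1:5) {
    y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- rnorm(60) + y
    roc <- prddi:::roc_curve_points(s, y)
    ours <- prddi:::auc_trapezoid(roc$fpr, roc$tpr)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("label-shuffled classification scores give chance-level AUROC", {
  set.seed(5)
  s <- runif(1000)
  y <- rbinom(1000, 1, 0.5)
  roc <- prddi:::roc_curve_points(s, y)
  auc <- prddi:::auc_trapezoid(roc$fpr, roc$tpr)
  expect_gt(auc, 0.44)
  expect_lt(auc, 0.56)
})

test_that("binary evaluation runs end-to-end on a trained model", {
  gen <- generate_kg(small_synth_config())
  sp <- split_ddi(gen$kg, 0.3, seed = 2)
  m <- prd_train(sp$train_kg, small_hparams(iterations = 40))
  ev <- binary_evaluate(m, sp, classifier_seed = 1)
  expect_gte(ev$auroc, 0); expect_lte(ev$auroc, 1)
  expect_gte(ev$aupr, 0); expect_lte(ev$aupr, 1)
  expect_true(all(diff(ev$roc$fpr) >= 0))
  expect_true(all(diff(ev$roc$tpr) >= 0))
  expect_equal(nrow(ev$scores),
               nrow(sp$test_negatives) + nrow(sp$test_positives) / 2)
  # same classifier seed reproduces the result
  ev2 <- binary_evaluate(m, sp, classifier_seed = 1)
  expect_identical(ev$scores, ev2$scores)
})
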