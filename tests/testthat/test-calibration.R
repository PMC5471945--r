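test_that("relation labeling folds substrates to enzyme scores", {
  m <- structure(matrix(c(0.9, 0.3), 2, 1,
                        dimnames = list(c("dPos", "dNeg"), "s1")),
                 class = c("sim_matrix", "matrix"))
  gsp <- data.frame(enzyme_label = "E1", substrate_id = "s1",
                    drug_id = "dPos", similarity = 0.9)
  ls <- label_relations(m, gsp)
  expect_equal(nrow(ls), 2)                      # 2 drugs x 1 enzyme
  expect_equal(ls$score[ls$drug_id == "dPos"], 0.9)
  expect_true(ls$label[ls$drug_id == "dPos"])
  expect_false(ls$label[ls$drug_id == "dNeg"])
  expect_equal(ls$score, sort(ls$score, decreasing = TRUE))
  expect_error(label_relations(m, transform(gsp, substrate_id = "ghost")),
               class = "metalike_unknown_id")
})

test_that("GSP drugs carry their GSP similarity into the labeled set", {
  fx <- fixture_pipeline()
  ls <- label_relations(fx$m, fx$gsp)
  expect_equal(nrow(ls), nrow(fx$m) * length(unique(fx$gsp$enzyme_label)))
  for (i in sample(nrow(fx$gsp), 5)) {
    r <- fx$gsp[i, ]
    got <- ls$score[ls$drug_id == r$drug_id &
                    ls$enzyme_label == r$enzyme_label]
    expect_equal(got, r$similarity)
  }
})

test_that("ROC worked examples: separation, degeneracy, hand-counted AUC", {
  expect_equal(roc_curve(labeled_df(c(0.9, 0.8, 0.2, 0.1),
                                    c(TRUE, TRUE, FALSE, FALSE)))$auc, 1)
  # constant score: one threshold step, chance-level AUC
  expect_equal(roc_curve(labeled_df(rep(0.5, 6),
                                    rep(c(TRUE, FALSE), 3)))$auc, 0.5)
  # 3 of 4 concordant (positive, negative) pairs
  expect_equal(roc_curve(labeled_df(c(0.9, 0.8, 0.7, 0.6),
                                    c(TRUE, FALSE, TRUE, FALSE)))$auc, 0.75)
  expect_error(roc_curve(labeled_df(c(0.9, 0.1), c(TRUE, TRUE))),
               class = "metalike_single_class")
})

test_that("ROC endpoints and monotonicity hold; AUC equals the rank statistic", {
  set.seed(21)
  concordance <- function(scores, labels) {
    pos <- scores[labels]; neg <- scores[!labels]
    mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  }
  for (i in 1:25) {
    n <- sample(10:200, 1)
    # discrete grid forces ties between and within classes
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    labels <- runif(n) < plogis(6 * (scores - 0.5))
    if (!any(labels) || all(labels)) next
    roc <- roc_curve(labeled_df(scores, labels))
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[length(roc$fpr)], 1)
    expect_equal(roc$tpr[length(roc$tpr)], 1)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(roc$auc, concordance(scores, labels))
  }
})

test_that("ROC agrees with an independent implementation on the fixture set", {
  fx <- fixture_pipeline()
  ls <- label_relations(fx$m, fx$gsp)
  roc <- roc_curve(ls)
  ref <- pROC::roc(response = ls$label, predictor = ls$score,
                   direction = "<", quiet = TRUE)
  expect_equal(roc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("Youden profile: identities, ties toward specificity, degenerate cases", {
  # J at the reported operating point of a high-sensitivity classifier
  expect_equal(round(youden_j(1, 1 - 0.021), 3), 0.979)
  # perfect classifier attains J = 1 at a separating threshold
  roc <- roc_curve(labeled_df(c(0.9, 0.8, 0.2, 0.1),
                              c(TRUE, TRUE, FALSE, FALSE)))
  yj <- youden_optimal(roc)
  expect_equal(yj$j_max, 1)
  expect_gt(yj$optimal_threshold, 0.2)
  expect_lte(yj$optimal_threshold, 0.8)
  # useless classifier: J never leaves 0
  yj0 <- youden_optimal(roc_curve(labeled_df(rep(0.5, 6),
                                             rep(c(TRUE, FALSE), 3))))
  expect_equal(yj0$j_max, 0)
  # j profile is tpr - fpr at every threshold
  expect_equal(yj$j, roc$tpr - roc$fpr)
})

test_that("planted separation thresholds are recovered with J = 1", {
  set.seed(22)
  for (i in 1:10) {
    t0 <- runif(1, 0.3, 0.8); delta <- 0.05
    pos <- runif(200, t0 + delta, 1)
    neg <- runif(200, 0, t0 - delta)
    yj <- youden_optimal(roc_curve(labeled_df(c(pos, neg),
                                              rep(c(TRUE, FALSE), each = 200))))
    expect_equal(yj$j_max, 1)
    # threshold grid = observed scores, so the optimum is the smallest
    # positive score, just above t0 + delta
    expect_gt(yj$optimal_threshold, t0 - delta)
    expect_lte(yj$optimal_threshold, t0 + delta + 0.03)
    expect_gt(yj$optimal_threshold, max(neg))
    expect_lte(yj$optimal_threshold, min(pos))
  }
})

test_that("J profile is invariant under strictly monotone score transforms", {
  set.seed(23)
  scores <- runif(60); labels <- runif(60) < scores
  if (any(labels) && !all(labels)) {
    j1 <- youden_optimal(roc_curve(labeled_df(scores, labels)))
    j2 <- youden_optimal(roc_curve(labeled_df(plogis(5 * scores), labels)))
    expect_equal(j1$j, j2$j)
    expect_equal(j1$j_max, j2$j_max)
  }
})
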