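test_that("confusion counts tally per element with Pre as positive", {
  cc <- confusion(rep(c("pre", "post"), each = 50), rep(c("pre", "post"), each = 50))
  expect_equal(cc, list(tp = 50L, tn = 50L, fp = 0L, fn = 0L))
  # inverting the predictions swaps tp<->fn and tn<->fp
  truth <- c(rep("pre", 30), rep("post", 20))
  set.seed(1)
  pred <- sample(c("pre", "post"), 50, replace = TRUE)
  inv <- ifelse(pred == "pre", "post", "pre")
  a <- confusion(truth, pred); b <- confusion(truth, inv)
  expect_equal(a$tp, b$fn); expect_equal(a$tn, b$fp)
  # brute-force tally oracle on a large random draw
  set.seed(2)
  truth <- sample(c("pre", "post"), 1000, replace = TRUE)
  pred <- sample(c("pre", "post"), 1000, replace = TRUE)
  cc <- confusion(truth, pred)
  tally <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (i in 1:1000) {
    k <- if (truth[i] == "pre" && pred[i] == "pre") "tp"
         else if (truth[i] == "post" && pred[i] == "post") "tn"
         else if (pred[i] == "pre") "fp" else "fn"
    tally[k] <- tally[k] + 1
  }
  expect_equal(unlist(cc), tally[c("tp", "tn", "fp", "fn")], ignore_attr = TRUE)
  expect_error(confusion(c("pre", "on"), c("pre", "post")), "labels")
})

test_that("percent metrics follow the count formulas, with undefined flags", {
  m <- classification_metrics(tp = 50, tn = 50, fp = 0, fn = 0)
  expect_equal(m$accuracy_pct, 100)
  expect_equal(m$f1_pct, 100)
  expect_false(m$undefined)
  # no positive predictions -> precision undefined
  m2 <- classification_metrics(tp = 0, tn = 50, fp = 0, fn = 10)
  expect_true(is.nan(m2$precision_pct))
  expect_true(m2$undefined)
  expect_error(classification_metrics(0, 0, 0, 0), "zero")
  # F1 from counts equals 2PR/(P+R)
  set.seed(3)
  for (i in 1:20) {
    cc <- as.list(setNames(sample(1:200, 4), c("tp", "tn", "fp", "fn")))
    m <- classification_metrics(cc)
    expect_equal(m$f1_pct,
                 f1_from_precision_recall(m$precision_pct, m$recall_pct),
                 tolerance = 1e-10)
  }
})

test_that("with balanced classes accuracy is the mean of recall and specificity", {
  set.seed(4)
  for (i in 1:20) {
    n <- 500
    tp <- sample(0:n, 1); fn <- n - tp
    tn <- sample(0:n, 1); fp <- n - tn
    m <- classification_metrics(tp = tp, tn = tn, fp = fp, fn = fn)
    expect_equal(m$accuracy_pct,
                 accuracy_from_recall_specificity(m$recall_pct, m$specificity_pct),
                 tolerance = 1e-10)
  }
})

test_that("ROC spans (0,0) to (1,1); perfect separation gives AUC 1 at (0,1)", {
  truth <- c(rep("pre", 20), rep("post", 20))
  scores <- c(runif(20, 0.6, 1), runif(20, 0, 0.4))
  r <- roc_auc(scores, truth)
  expect_equal(r$auc, 1)
  expect_equal(r$operating_point$fpr, 0)
  expect_equal(r$operating_point$tpr, 1)
  expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
  expect_equal(r$roc$fpr[nrow(r$roc)], 1)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_error(roc_auc(runif(5), rep("pre", 5)), "each class")
})

test_that("label-independent scores give AUC near 1/2", {
  set.seed(5)
  truth <- sample(c("pre", "post"), 4000, replace = TRUE)
  scores <- runif(4000)
  expect_equal(roc_auc(scores, truth)$auc, 0.5, tolerance = 0.05)
})

test_that("AUC equals the normalized Mann-Whitney statistic, ties included", {
  set.seed(6)
  for (i in 1:10) {
    n1 <- sample(20:60, 1); n0 <- sample(20:60, 1)
    # coarse scores force ties
    s1 <- round(rnorm(n1, 0.6, 0.3), 1)
    s0 <- round(rnorm(n0, 0.4, 0.3), 1)
    scores <- c(s1, s0)
    truth <- c(rep("pre", n1), rep("post", n0))
    auc <- roc_auc(scores, truth)$auc
    rk <- rank(scores)  # midranks
    u <- sum(rk[truth == "pre"]) - n1 * (n1 + 1) / 2
    expect_equal(auc, u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(7)
  truth <- sample(c("pre", "post"), 300, replace = TRUE)
  scores <- rnorm(300)
  a <- roc_auc(scores, truth)$auc
  expect_equal(roc_auc(exp(scores), truth)$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(2 * scores - 5, truth)$auc, a, tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  truth <- sample(c("pre", "post"), 400, replace = TRUE)
  scores <- rnorm(400) + (truth == "pre")
  ours <- roc_auc(scores, truth)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(truth == "pre", scores,
                                              direction = "<", quiet = TRUE)))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-10)
})
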