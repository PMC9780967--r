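test_that("model specifications encode the published topologies", {
  d4 <- model_spec("dnn4")
  expect_equal(d4$hidden, 32L)
  expect_equal(d4$activations, "relu")
  expect_equal(d4$optimizer, "rmsprop")
  d1 <- model_spec("dnn1")
  expect_equal(d1$hidden, c(32L, 32L, 32L))
  expect_equal(d1$optimizer, "nadam")
  d3 <- model_spec("dnn3")
  expect_equal(d3$activations, c("tanh", "relu"))
  expect_equal(model_spec("knn")$k, 21L)
  expect_equal(model_spec("knn")$distance, "cityblock")
  expect_equal(model_spec("tree")$max_splits, 129L)
  expect_error(model_spec("mlp"))
})

test_that("a 7->32 dense layer holds 224 weights and 256 parameters", {
  net <- wotrack:::nn_init(c(32L, 1L), c("relu", "sigmoid"), n_in = 7L, seed = 1)
  expect_equal(dim(net$layers[[2]]$W), c(7L, 32L))
  expect_equal(length(net$layers[[2]]$W), 224L)
  expect_equal(length(net$layers[[2]]$W) + length(net$layers[[2]]$b), 256L)
})

test_that("complexity accounting follows the documented convention", {
  tabs <- fixture_tables()
  small <- tabs$train[sort(c(seq_len(150), nrow(tabs$train) - seq_len(150) + 1)), ]
  m4 <- wo_train(model_spec("dnn4"), small, seed = 1, epochs = 2)
  cx <- complexity(m4)
  expect_equal(cx$macc_dense, 7 * 32 + 32 * 1 + 33)  # weights + bias accumulates
  expect_equal(cx$n_params, 4 * 7 + (7 * 32 + 32) + (32 + 1))
  expect_equal(cx$rom_bytes, 4 * cx$n_params)
  m2 <- wo_train(model_spec("dnn2"), small, seed = 1, epochs = 2)
  m1 <- wo_train(model_spec("dnn1"), small, seed = 1, epochs = 2)
  m3 <- wo_train(model_spec("dnn3"), small, seed = 1, epochs = 2)
  # capacity ordering mirrors the published flash ordering
  expect_gt(complexity(m1)$n_params, complexity(m2)$n_params)
  expect_gt(complexity(m2)$n_params, complexity(m4)$n_params)
  expect_equal(complexity(m2)$n_params, complexity(m3)$n_params)
})

test_that("a linearly separable table is fit perfectly by the linear SVM", {
  set.seed(3)
  n <- 60
  tab <- data.frame(condition = rep(c("pre", "post"), each = n))
  for (f in muscular_features()) {
    tab[[f]] <- rnorm(2 * n, mean = ifelse(tab$condition == "pre", 10, 0), sd = 1)
  }
  m <- wo_train(model_spec("svm"), tab, seed = 1)
  pr <- predict_table(m, tab)
  expect_equal(pr$label, tab$condition)
})

test_that("knn enforces k <= n and k = 1 self-labels its reference set", {
  tabs <- fixture_tables()
  tiny <- tabs$train[c(1:5, (nrow(tabs$train) - 4):nrow(tabs$train)), ]
  expect_error(wo_train(model_spec("knn"), tiny, seed = 1), "exceeds")
  spec1 <- model_spec("knn")
  spec1$k <- 1L
  m <- wo_train(spec1, tabs$train[c(1:50, (nrow(tabs$train) - 49):nrow(tabs$train)), ],
                seed = 1)
  self <- predict_table(m, tabs$train[c(1:50, (nrow(tabs$train) - 49):nrow(tabs$train)), ])
  expect_equal(self$label,
               tabs$train$condition[c(1:50, (nrow(tabs$train) - 49):nrow(tabs$train))])
})

test_that("training is reproducible under a fixed seed", {
  tabs <- fixture_tables()
  sub <- tabs$train[seq(1, nrow(tabs$train), by = 4), ]
  for (fam in c("dnn4", "svm", "knn", "qd", "tree")) {
    a <- wo_train(model_spec(fam), sub, seed = 9, epochs = 3)
    b <- wo_train(model_spec(fam), sub, seed = 9, epochs = 3)
    expect_identical(predict_table(a, tabs$test)$score,
                     predict_table(b, tabs$test)$score,
                     info = fam)
  }
})

test_that("forward_dense agrees with predict_table row-wise and bounds scores", {
  tabs <- fixture_tables()
  sub <- tabs$train[seq(1, nrow(tabs$train), by = 6), ]
  m <- wo_train(model_spec("dnn4"), sub, seed = 2, epochs = 10)
  pr <- predict_table(m, tabs$test[1:50, ])
  direct <- forward_dense(m, as.matrix(tabs$test[1:50, m$features]))
  expect_equal(pr$score, direct, tolerance = 1e-12)
  expect_true(all(pr$score > 0 & pr$score < 1))
  expect_error(forward_dense(m, rnorm(5)), "expects")
  # empty table -> empty output
  empty <- predict_table(m, tabs$test[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("dense-NN models survive a JSON save/load round trip", {
  tabs <- fixture_tables()
  sub <- tabs$train[seq(1, nrow(tabs$train), by = 6), ]
  m <- wo_train(model_spec("dnn2"), sub, seed = 4, epochs = 5)
  f <- tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  x <- as.matrix(tabs$test[1:20, m$features])
  expect_equal(forward_dense(m, x), forward_dense(m2, x), tolerance = 1e-12)
  m_svm <- wo_train(model_spec("svm"), sub, seed = 4)
  expect_error(save_model(m_svm, f), "dense-NN")
  unlink(f)
})

test_that("single-class or malformed tables are rejected", {
  tabs <- fixture_tables()
  pre_only <- tabs$train[tabs$train$condition == "pre", ][1:50, ]
  expect_error(wo_train(model_spec("svm"), pre_only, seed = 1), "both classes")
  no_cond <- tabs$train[1:50, muscular_features()]
  expect_error(wo_train(model_spec("svm"), no_cond, seed = 1), "condition")
})
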