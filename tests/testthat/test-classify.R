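test_that("the network geometry follows the conv/pool contract", {
  m <- build_classifier(classifier_config(n_classes = 4), input_len = 112)
  expect_equal(m$cfg$n_conv_blocks, 2L)
  expect_equal(m$lens, c(56L, 28L))
  expect_equal(m$flat, 28L * 32L)
  m6 <- build_classifier(classifier_config(n_classes = 2), input_len = 2048)
  expect_equal(m6$cfg$n_conv_blocks, 6L)
  expect_equal(m6$lens[6], 32L)
  expect_error(build_classifier(classifier_config(n_conv_blocks = 6,
                                                  n_classes = 2), 48),
               "too short")
  expect_error(classifier_config(dropout = 1), "dropout")
  expect_error(classifier_config(n_classes = 1), "n_classes")
})

test_that("softmax outputs are probability rows", {
  m <- build_classifier(classifier_config(n_classes = 3, seed = 2), 16)
  X <- matrix(rnorm(80), 5, 16)
  pr <- predict(m, X, type = "prob")
  expect_equal(dim(pr), c(5L, 3L))
  expect_equal(rowSums(pr), rep(1, 5), tolerance = 1e-12)
  expect_true(all(pr >= 0))
})

test_that("analytic gradients match numeric differentiation", {
  cfg <- classifier_config(n_conv_blocks = 1L, filters = 3L,
                           dense_units = 5L, dropout = 0, n_classes = 3L,
                           seed = 4)
  m <- build_classifier(cfg, input_len = 8)
  set.seed(5)
  X <- matrix(rnorm(4 * 8), 4, 8)
  y <- c(1L, 2L, 3L, 2L)
  fw <- gcfe:::cnn_forward(m, X, training = FALSE)
  g <- gcfe:::cnn_backward(m, X, y, fw)
  loss_at <- function(model) {
    f <- gcfe:::cnn_forward(model, X, training = FALSE)
    gcfe:::cnn_loss(f$probs, y)
  }
  h <- 1e-5
  for (nm in c("convW1", "convb1", "W1", "Wo", "b2")) {
    w <- m$params[[nm]]
    picks <- sample(length(w), min(5L, length(w)))
    for (ix in picks) {
      mp <- m; mp$params[[nm]][ix] <- w[ix] + h
      mm <- m; mm$params[[nm]][ix] <- w[ix] - h
      num <- (loss_at(mp) - loss_at(mm)) / (2 * h)
      expect_equal(as.numeric(g[[nm]][ix]), num, tolerance = 1e-5)
    }
  }
})

test_that("confusion metrics reproduce a hand-computed binary case", {
  # TP=40, FN=10, FP=5, TN=45 for class 1
  truth <- rep(c(1L, 2L), each = 50L)
  pred <- c(rep(1L, 40), rep(2L, 10), rep(1L, 5), rep(2L, 45))
  met <- confusion_metrics(truth, pred, 2L)
  expect_equal(met$confusion_matrix,
               matrix(c(40L, 5L, 10L, 45L), 2, 2,
                      dimnames = dimnames(met$confusion_matrix)))
  expect_equal(met$accuracy, 85)
  # macro sensitivity = mean(40/50, 45/50); macro specificity mirrors it
  expect_equal(met$sensitivity, 100 * mean(c(40 / 50, 45 / 50)))
  expect_equal(met$specificity, 100 * mean(c(45 / 50, 40 / 50)))
  expect_equal(rowSums(met$confusion_matrix), c(`1` = 50, `2` = 50))
})

test_that("separable classes are learned to perfection with falling loss", {
  set.seed(41)
  n <- 80; p <- 24
  X <- rbind(matrix(rnorm(n * p, 0), n, p), matrix(rnorm(n * p, 4), n, p))
  df <- as.data.frame(X)
  df$label <- rep(1:2, each = n)
  rep_ <- train_eval(df, cfg = classifier_config(epochs = 8), seed = 13)
  expect_equal(rep_$accuracy, 100)
  expect_lt(rep_$history$train_loss[5], rep_$history$train_loss[1])
})

test_that("splits are stratified, seeded and guard absent classes", {
  set.seed(51)
  df <- as.data.frame(matrix(rnorm(200 * 8), 200, 8))
  df$label <- rep(1:4, each = 50)
  r1 <- train_eval(df, arch = "svm", seed = 3)
  r2 <- train_eval(df, arch = "svm", seed = 3)
  expect_identical(r1$split_index, r2$split_index)
  expect_equal(as.numeric(r1$split_sizes), c(140, 32, 28))
  for (part in r1$split_index) {
    expect_equal(sort(unique(df$label[part])), 1:4)
  }
  tiny <- df[c(1:3, 51:100, 101:150, 151:200), ]
  expect_error(train_eval(tiny, arch = "svm", seed = 1), "absent")
  expect_error(train_eval(df[1:8], seed = 1), "label")
})

test_that("the SVM alternative plugs into the same harness", {
  set.seed(61)
  n <- 60; p <- 10
  X <- rbind(matrix(rnorm(n * p, 0), n, p), matrix(rnorm(n * p, 3), n, p))
  df <- as.data.frame(X)
  df$label <- rep(c(2L, 7L), each = n)   # non-contiguous labels
  rep_ <- train_eval(df, arch = "svm", seed = 5)
  expect_s3_class(rep_, "eval_report")
  expect_gt(rep_$accuracy, 90)
  expect_equal(rep_$classes, c(2L, 7L))
})
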